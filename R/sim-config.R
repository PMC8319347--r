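#' Simulation configuration for the synthetic coculture evolution experiment
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' list. Defaults reproduce the design of the longitudinal coculture
#' experiment the package models: 13 evolution lines of a sulfate reducer /
#' methanogen coculture sampled at generations 100, 300, 500, 780 and 1000,
#' single-cell genotyping error rates fd = 6.04e-5 (false positive) and
#' ad = 0.21545 (allelic dropout), and a 1.5-fold dilution series for growth
#' plates.
#'
#' @param seed Integer master seed; all generators derive their streams from
#'   it deterministically.
#' @param n_lines Number of independently evolved coculture lines.
#' @param generations Strictly increasing integer vector of sampled
#'   generations.
#' @param n_genes Number of annotated genes per organism in the synthetic
#'   catalogs.
#' @param gene_length_range Length-2 numeric, bp range genes are drawn from
#'   (uniform).
#' @param mutation_rate Expected number of mutation events per line per
#'   organism (Poisson).
#' @param parallel_genes Optional named numeric vector mapping gene ids to
#'   enrichment factors (>= 1); enrichment multiplies the length-proportional
#'   hit probability of that gene.
#' @param p_selected Probability that a mutation event is under positive
#'   selection (rises logistically toward fixation) rather than drifting at
#'   low frequency.
#' @param fixation_threshold Frequency at or above which a mutation is called
#'   fixed (default 0.95).
#' @param detection_limit Bulk-sequencing detection limit; frequencies below
#'   it count as absent (default 0.05).
#' @param sweep_spec Optional list describing a cross-species selective sweep:
#'   `list(line =, interval = c(g1, g2), replaced =, novel =, n_replaced =,
#'   n_novel =)`. When `replaced` / `novel` gene sets are `NULL` they are
#'   drawn automatically (`n_replaced` / `n_novel` genes per organism).
#' @param fd Single-cell false-positive probability (observe 1 given true 0).
#' @param ad Single-cell allelic-dropout probability (observe 0 given true 1).
#' @param missing_rate Probability a single-cell entry is uncallable
#'   (state 3).
#' @param growth_params List with `mu` (maximum growth rate, OD/h), `lambda`
#'   (lag, h) and `A` (carrying capacity, OD) of the logistic growth model.
#' @param noise_sd Plate-reader OD noise standard deviation.
#' @param dilution_fold Dilution ratio between adjacent densities (> 1).
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 50, mutation_rate = 4)
#' cfg$generations
sim_config <- function(seed = 1L,
                       n_lines = 13L,
                       generations = c(100L, 300L, 500L, 780L, 1000L),
                       n_genes = 200L,
                       gene_length_range = c(300, 3000),
                       mutation_rate = 8,
                       parallel_genes = NULL,
                       p_selected = 0.5,
                       fixation_threshold = 0.95,
                       detection_limit = 0.05,
                       sweep_spec = NULL,
                       fd = 6.04e-5,
                       ad = 0.21545,
                       missing_rate = 0.02,
                       growth_params = list(mu = 0.03, lambda = 15, A = 0.4),
                       noise_sd = 0.005,
                       dilution_fold = 1.5) {
  generations <- as.integer(generations)
  if (length(generations) < 1 || any(diff(generations) <= 0)) {
    abort("`generations` must be a non-empty, strictly increasing integer vector.")
  }
  if (n_lines < 1) abort("`n_lines` must be >= 1.")
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      diff(gene_length_range) < 0) {
    abort("`gene_length_range` must be a positive, non-decreasing bp interval.")
  }
  if (mutation_rate < 0) abort("`mutation_rate` must be >= 0.")
  if (!is.null(parallel_genes)) {
    if (is.null(names(parallel_genes)) || any(parallel_genes < 1)) {
      abort("`parallel_genes` must be a named vector of enrichment factors >= 1.")
    }
  }
  check_probability(p_selected, "p_selected")
  check_probability(fixation_threshold, "fixation_threshold")
  check_probability(detection_limit, "detection_limit")
  check_probability(fd, "fd")
  check_probability(ad, "ad")
  check_probability(missing_rate, "missing_rate")
  if (!is.null(sweep_spec)) {
    if (is.null(sweep_spec$interval) || length(sweep_spec$interval) != 2 ||
        !all(sweep_spec$interval %in% generations)) {
      abort("`sweep_spec$interval` must be two sampled generations c(g1, g2).")
    }
    sweep_spec$n_replaced <- sweep_spec$n_replaced %||% 2L
    sweep_spec$n_novel <- sweep_spec$n_novel %||% 2L
  }
  stopifnot(is.list(growth_params))
  if (!all(c("mu", "lambda", "A") %in% names(growth_params))) {
    abort("`growth_params` must contain mu, lambda and A.")
  }
  if (growth_params$mu <= 0 || growth_params$A <= 0) {
    abort("`growth_params` mu and A must be positive.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (dilution_fold <= 1) abort("`dilution_fold` must be > 1.")

  structure(
    list(
      seed = as.integer(seed), n_lines = as.integer(n_lines),
      generations = generations, n_genes = as.integer(n_genes),
      gene_length_range = gene_length_range, mutation_rate = mutation_rate,
      parallel_genes = parallel_genes, p_selected = p_selected,
      fixation_threshold = fixation_threshold,
      detection_limit = detection_limit, sweep_spec = sweep_spec,
      fd = fd, ad = ad, missing_rate = missing_rate,
      growth_params = growth_params, noise_sd = noise_sd,
      dilution_fold = dilution_fold
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d lines, generations: %s\n", x$n_lines,
              paste(x$generations, collapse = ", ")))
  cat(sprintf("  %d genes/organism, mutation rate %.2f events/line\n",
              x$n_genes, x$mutation_rate))
  cat(sprintf("  fd = %g, ad = %g, missing = %g\n", x$fd, x$ad, x$missing_rate))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Build a synthetic gene catalog
#'
#' Draws `n_genes` gene lengths uniformly from `gene_length_range`. The
#' genome length defaults to the summed gene length (no intergenic space);
#' pass `intergenic_fraction > 0` to add unannotated sequence, which the
#' G-score randomization null can hit (contributing zero to the statistic).
#'
#' @param n_genes Number of genes.
#' @param gene_length_range bp interval, uniform draw.
#' @param organism Organism label stored in the catalog.
#' @param prefix Gene id prefix (ids are `<prefix><0001...>`).
#' @param intergenic_fraction Fraction of the genome that is unannotated.
#' @param seed Optional seed (when `NULL` the current RNG stream is used).
#'
#' @return Tibble with columns `organism`, `gene`, `length_bp`, and attribute
#'   `genome_length`.
#' @export
make_gene_catalog <- function(n_genes, gene_length_range = c(300, 3000),
                              organism = "Dv_like", prefix = "DVG",
                              intergenic_fraction = 0, seed = NULL) {
  check_probability(intergenic_fraction, "intergenic_fraction")
  draw <- function() {
    lengths <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    tibble(
      organism = organism,
      gene = sprintf("%s%04d", prefix, seq_len(n_genes)),
      length_bp = as.numeric(lengths)
    )
  }
  cat <- if (is.null(seed)) draw() else with_seed(seed, draw())
  attr(cat, "genome_length") <- sum(cat$length_bp) / (1 - intergenic_fraction)
  cat
}
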