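#' Per-gene G-score ("goodness of fit") for parallel evolution
#'
#' `G = 2 * O * ln(O / E)` for a gene with `O` observed mutations against a
#' length-proportional expectation `E`. `O = 0` returns 0 (the limit
#' convention); genes with `0 < O < E` contribute negative values, which is
#' the formula as written.
#'
#' @param observed Non-negative observed mutation count(s).
#' @param expected Positive expected count(s).
#' @return Numeric G value(s).
#' @export
#' @examples
#' gene_gscore(6, 2) # 2 * 6 * log(3)
gene_gscore <- function(observed, expected) {
  if (any(expected <= 0)) abort("`expected` must be > 0.")
  if (any(observed < 0)) abort("`observed` must be >= 0.")
  if_else(observed == 0, 0, 2 * observed * log(observed / expected))
}

#' Observed per-gene G-scores across evolution lines
#'
#' Counts mutations per gene (pooled across all lines, or as the number of
#' distinct lines hit), computes length-proportional expected counts
#' `E_i = N * L_i / sum(L)`, and scores each gene with [gene_gscore()].
#' Intergenic calls (genes absent from the catalog) are excluded and their
#' count recorded in the `excluded` attribute.
#'
#' @param mutations Tibble of mutation calls with a `gene` column; `line`,
#'   `position` and `annotation` are used when present (events are
#'   deduplicated on line/gene/position, and synonymous changes dropped when
#'   `nonsynonymous_only`).
#' @param catalog Gene catalog tibble (`gene`, `length_bp`), e.g. from
#'   [make_gene_catalog()].
#' @param count_mode `"pooled"` (every event counts) or `"per_line_unique"`
#'   (a gene counts once per line it is mutated in).
#' @param nonsynonymous_only Drop `synonymous_coding` events before counting
#'   (default TRUE, matching the parallelism analysis the score was built
#'   for).
#'
#' @return Tibble (gene, length_bp, observed, expected, gscore) sorted by
#'   descending G, with attributes `total` (sum of per-gene G), `n_total`
#'   (mutations scored) and `excluded` (intergenic/unknown-gene events).
#' @export
observed_gscores <- function(mutations, catalog,
                             count_mode = c("pooled", "per_line_unique"),
                             nonsynonymous_only = TRUE) {
  count_mode <- match.arg(count_mode)
  check_columns(mutations, "gene", "mutations")
  check_columns(catalog, c("gene", "length_bp"), "catalog")
  if (nrow(catalog) == 0) abort("empty gene catalog")

  mut <- as_tibble(mutations)
  if (nonsynonymous_only && "annotation" %in% names(mut)) {
    mut <- filter(mut, .data$annotation != "synonymous_coding")
  }
  key_cols <- intersect(c("line", "gene", "position"), names(mut))
  mut <- distinct(mut, across(all_of(key_cols)), .keep_all = TRUE)

  excluded <- sum(!mut$gene %in% catalog$gene)
  mut <- filter(mut, .data$gene %in% catalog$gene)

  counts <- if (count_mode == "per_line_unique" && "line" %in% names(mut)) {
    mut %>% distinct(.data$line, .data$gene) %>% count(.data$gene, name = "observed")
  } else {
    count(mut, .data$gene, name = "observed")
  }

  n_total <- sum(counts$observed)
  if (n_total == 0) abort("no mutations left to score (N_total = 0).")

  out <- catalog %>%
    select(all_of(intersect(c("organism", "gene", "length_bp"), names(catalog)))) %>%
    left_join(counts, by = "gene") %>%
    mutate(
      observed = if_else(is.na(.data$observed), 0L, as.integer(.data$observed)),
      expected = n_total * .data$length_bp / sum(.data$length_bp),
      gscore = gene_gscore(.data$observed, .data$expected)
    ) %>%
    arrange(desc(.data$gscore))

  attr(out, "total") <- sum(out$gscore)
  attr(out, "n_total") <- n_total
  attr(out, "excluded") <- excluded
  out
}

#' Null distribution of the total G-score under random mutation placement
#'
#' Randomizes the genomic locations of the observed number of mutations:
#' each simulation drops `n_total` mutations independently at uniform
#' positions, so a gene is hit with probability proportional to its length
#' and the remaining probability mass falls in intergenic sequence, which
#' contributes zero to the score. The total G of each simulation uses the
#' same length-proportional expectation as the observed statistic.
#'
#' @param catalog Gene catalog (`gene`, `length_bp`).
#' @param n_total Observed total mutation count to randomize (>= 1).
#' @param n_sims Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @param genome_length Total genome length in bp; defaults to the catalog's
#'   `genome_length` attribute, else the summed gene length (no intergenic
#'   space).
#'
#' @return List with `mu` (null mean), `sigma` (null sd), `totals`
#'   (simulated total G values) and `n_sims`.
#' @export
expected_gscore_null <- function(catalog, n_total, n_sims = 1000L, seed = 1L,
                                 genome_length = NULL) {
  check_columns(catalog, c("gene", "length_bp"), "catalog")
  if (n_total < 1) abort("`n_total` must be >= 1 (nothing to randomize).")
  if (n_sims < 2) abort("`n_sims` must be >= 2.")
  genome_length <- genome_length %||% attr(catalog, "genome_length") %||%
    sum(catalog$length_bp)
  if (genome_length < sum(catalog$length_bp)) {
    abort("`genome_length` is smaller than the summed gene length.")
  }

  p_gene <- catalog$length_bp / genome_length
  p_inter <- max(0, 1 - sum(p_gene))
  expected <- n_total * catalog$length_bp / sum(catalog$length_bp)

  totals <- with_seed(seed, {
    hits <- rmultinom(n_sims, n_total, c(p_gene, p_inter))
    o <- hits[seq_len(nrow(catalog)), , drop = FALSE]
    g <- 2 * o * log(o / expected)
    g[o == 0] <- 0
    colSums(g)
  })

  sigma <- sd(totals)
  if (sigma == 0) {
    warn("null sd of the total G-score is 0; the Z-score is undefined.")
  }
  list(mu = mean(totals), sigma = sigma, totals = totals,
       n_sims = as.integer(n_sims))
}

#' Z-score for genome-wide parallelism
#'
#' Standardizes the observed total G-score against the randomization null:
#' `Z = (G_obs - mu) / sigma`.
#'
#' @param g_obs Observed total G-score.
#' @param mu Null mean.
#' @param sigma Null standard deviation (> 0).
#' @return Numeric Z.
#' @export
#' @examples
#' parallelism_zscore(805.02, 564.83, 15.95) # ~ 15.06
parallelism_zscore <- function(g_obs, mu, sigma) {
  if (any(sigma <= 0)) abort("`sigma` must be > 0.")
  (g_obs - mu) / sigma
}

#' Genome-wide parallel-evolution test
#'
#' Convenience wrapper chaining [observed_gscores()],
#' [expected_gscore_null()] and [parallelism_zscore()] into one fitted
#' object with broom-style [tidy()] / [glance()] methods and an
#' [ggplot2::autoplot()] view of the top-ranked genes.
#'
#' @inheritParams observed_gscores
#' @inheritParams expected_gscore_null
#' @return Object of class `gscore_test`.
#' @export
gscore_test <- function(mutations, catalog, n_sims = 1000L, seed = 1L,
                        count_mode = c("pooled", "per_line_unique"),
                        nonsynonymous_only = TRUE, genome_length = NULL) {
  per_gene <- observed_gscores(mutations, catalog, count_mode = count_mode,
                               nonsynonymous_only = nonsynonymous_only)
  g_obs <- attr(per_gene, "total")
  n_total <- attr(per_gene, "n_total")
  null <- expected_gscore_null(catalog, n_total, n_sims = n_sims, seed = seed,
                               genome_length = genome_length)
  structure(
    list(per_gene = per_gene, g_obs = g_obs, null_mean = null$mu,
         null_sd = null$sigma, null_totals = null$totals,
         z = parallelism_zscore(g_obs, null$mu, null$sigma),
         n_total = n_total, n_sims = null$n_sims, seed = as.integer(seed)),
    class = "gscore_test"
  )
}

#' @export
print.gscore_test <- function(x, ...) {
  cat("<gscore_test>\n")
  cat(sprintf("  %d mutations over %d genes\n", x$n_total, nrow(x$per_gene)))
  cat(sprintf("  observed total G = %.3f; null %.2f +/- %.2f (%d sims)\n",
              x$g_obs, x$null_mean, x$null_sd, x$n_sims))
  cat(sprintf("  Z = %.2f\n", x$z))
  invisible(x)
}

#' @rdname gscore_test
#' @param x A `gscore_test` object.
#' @param ... Unused.
#' @export
tidy.gscore_test <- function(x, ...) {
  as_tibble(x$per_gene)
}

#' @rdname gscore_test
#' @export
glance.gscore_test <- function(x, ...) {
  tibble(g_obs = x$g_obs, null_mean = x$null_mean, null_sd = x$null_sd,
         z = x$z, n_total = x$n_total, n_sims = x$n_sims, seed = x$seed)
}

#' @rdname gscore_test
#' @param object A `gscore_test` object.
#' @param top_n Number of top-ranked genes to display.
#' @export
autoplot.gscore_test <- function(object, top_n = 20, ...) {
  df <- head(tidy(object), top_n)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot(df, aes(x = .data$gscore, y = .data$gene)) +
    geom_col(fill = "steelblue") +
    labs(x = "per-gene G-score", y = NULL,
         title = sprintf("Top parallel-evolution genes (Z = %.1f)", object$z))
}
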