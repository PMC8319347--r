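#' Simulate longitudinal mutation-frequency trajectories for coculture lines
#'
#' Generates, for each evolution line and each of the two partner organisms,
#' a set of mutation events and their per-generation population frequencies.
#' Gene assignment of events is multinomial with probability proportional to
#' gene length times the gene's enrichment factor (1 unless listed in
#' `config$parallel_genes`), so with all enrichments at 1 hit counts are
#' exactly length-proportional. Events under selection follow a logistic
#' frequency rise toward fixation; neutral events persist at low frequency.
#' An optional cross-species selective sweep replaces a dominant set of loci
#' with a previously undetected set in both organisms over one sampled
#' interval.
#'
#' @param config A [sim_config()].
#'
#' @return An object of class `evo_sim`: a list with
#'   * `trajectories` — tibble (line, organism, generation, gene, frequency,
#'     annotation), one row per event-bearing gene per sampled generation;
#'   * `events` — tibble of mutation events (line, organism, gene, position,
#'     ref, alt, annotation, frequency, selected, appearance_generation,
#'     role);
#'   * `catalog` — gene catalog for both organisms;
#'   * `truth` — ground-truth list (parallel genes, sweep sets, per-event
#'     selection flags).
#' @export
#' @examples
#' sim <- simulate_lines(sim_config(seed = 1, n_genes = 40, mutation_rate = 4))
#' head(sim$trajectories)
simulate_lines <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1) abort("empty gene catalog")
  if (length(config$generations) < 1) abort("zero generations")

  with_seed(derive_seed(config$seed, 101L), {
    catalog <- bind_rows(
      make_gene_catalog(config$n_genes, config$gene_length_range,
                        organism = "Dv_like", prefix = "DVG"),
      make_gene_catalog(config$n_genes, config$gene_length_range,
                        organism = "Mm_like", prefix = "MMG")
    )

    lines <- sprintf("L%02d", seq_len(config$n_lines))
    organisms <- c("Dv_like", "Mm_like")

    events <- list()
    for (ln in lines) {
      for (org in organisms) {
        events[[paste(ln, org)]] <- draw_line_events(ln, org, catalog, config)
      }
    }
    events <- bind_rows(events)

    sweep_truth <- NULL
    if (!is.null(config$sweep_spec)) {
      sw <- plant_sweep_events(events, catalog, config)
      events <- sw$events
      sweep_truth <- sw$truth
    }

    trajectories <- build_trajectories(events, config)

    structure(
      list(
        trajectories = trajectories,
        events = events,
        catalog = catalog,
        truth = list(
          parallel_genes = names(config$parallel_genes),
          sweep = sweep_truth,
          events = events
        ),
        config = config
      ),
      class = "evo_sim"
    )
  })
}

#' @export
print.evo_sim <- function(x, ...) {
  cat("<evo_sim>\n")
  cat(sprintf("  %d lines x 2 organisms, %d mutation events\n",
              x$config$n_lines, nrow(x$events)))
  cat(sprintf("  generations: %s\n", paste(x$config$generations, collapse = ", ")))
  if (!is.null(x$truth$sweep)) {
    cat(sprintf("  planted sweep in %s over (%d, %d]\n",
                x$truth$sweep$line, x$truth$sweep$interval[1],
                x$truth$sweep$interval[2]))
  }
  invisible(x)
}

# Annotation vocabulary and sampling weights used by the generator; mostly
# function-modulating terms, as selected mutations in the study were.
annotation_terms <- function() {
  c(frameshift = 0.15, stop_gained = 0.08, stop_lost = 0.02,
    start_lost = 0.02, start_gained = 0.01, codon_deletion = 0.04,
    codon_insertion_or_change = 0.05, nonsynonymous_coding = 0.45,
    synonymous_coding = 0.15, nonsynonymous_start = 0.03)
}

draw_line_events <- function(line, organism, catalog, config) {
  cat_org <- catalog[catalog$organism == organism, ]
  n_mut <- rpois(1, config$mutation_rate)
  if (n_mut == 0) return(NULL)

  enrich <- rep(1, nrow(cat_org))
  if (!is.null(config$parallel_genes)) {
    idx <- match(names(config$parallel_genes), cat_org$gene)
    enrich[idx[!is.na(idx)]] <- config$parallel_genes[!is.na(idx)]
  }
  prob <- cat_org$length_bp * enrich
  gi <- sample.int(nrow(cat_org), n_mut, replace = TRUE, prob = prob)

  terms <- annotation_terms()
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_mut, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  tibble(
    line = line,
    organism = organism,
    gene = cat_org$gene[gi],
    position = vapply(gi, function(i) sample.int(cat_org$length_bp[i], 1), 1L),
    ref = ref,
    alt = unname(alt),
    annotation = sample(names(terms), n_mut, replace = TRUE, prob = terms),
    selected = runif(n_mut) < config$p_selected,
    appearance_generation = sample(config$generations, n_mut, replace = TRUE),
    role = "background"
  )
}

# Replace/add events so that, in the sweep line, a dominant locus set in each
# organism crashes below the detection limit over sweep interval (g1, g2]
# while a disjoint novel set rises to dominance.
plant_sweep_events <- function(events, catalog, config) {
  sp <- config$sweep_spec
  line <- sp$line %||% "L01"
  gens <- config$generations
  g1 <- sp$interval[1]
  g2 <- sp$interval[2]

  pick <- function(org, exclude, n) {
    pool <- setdiff(catalog$gene[catalog$organism == org], exclude)
    sample(pool, n)
  }
  replaced <- sp$replaced
  novel <- sp$novel
  if (is.null(replaced)) {
    replaced <- c(pick("Dv_like", NULL, sp$n_replaced),
                  pick("Mm_like", NULL, sp$n_replaced))
  }
  if (is.null(novel)) {
    novel <- c(pick("Dv_like", replaced, sp$n_novel),
               pick("Mm_like", replaced, sp$n_novel))
  }

  org_of <- function(g) catalog$organism[match(g, catalog$gene)]
  terms <- annotation_terms()
  mk <- function(genes, role) {
    n <- length(genes)
    tibble(
      line = line,
      organism = org_of(genes),
      gene = genes,
      position = vapply(genes, function(g) {
        sample.int(catalog$length_bp[match(g, catalog$gene)], 1)
      }, 1L),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      annotation = sample(names(terms), n, replace = TRUE, prob = terms),
      selected = TRUE,
      appearance_generation = if (role == "sweep_replaced") min(gens) else
        min(gens[gens > g1]),
      role = role
    )
  }

  # Drop background events colliding with the planted loci, and demote the
  # sweep line's remaining background events to non-selected so no
  # coincidental below-detection-to-dominance crossing shadows the planted
  # sweep; then append the planted events.
  events <- events[!(events$line == line & events$gene %in% c(replaced, novel)), ]
  events$selected[events$line == line] <- FALSE
  events <- bind_rows(events, mk(replaced, "sweep_replaced"),
                      mk(novel, "sweep_novel"))
  list(
    events = events,
    truth = list(line = line, interval = c(g1, g2),
                 replaced = replaced, novel = novel)
  )
}

# Frequency trajectory of one event across the sampled generations.
event_frequencies <- function(appearance, selected, role, config) {
  gens <- config$generations
  f <- numeric(length(gens))

  if (role == "sweep_replaced") {
    g1 <- config$sweep_spec$interval[1]
    g2 <- config$sweep_spec$interval[2]
    f[gens <= g1] <- clamp(0.85 + rnorm(sum(gens <= g1), 0, 0.04), 0.60, 0.99)
    f[gens >= g2] <- clamp(0.01 + rnorm(sum(gens >= g2), 0, 0.01), 0, 0.04)
    mid <- gens > g1 & gens < g2
    f[mid] <- clamp(0.85 + rnorm(sum(mid), 0, 0.04), 0.60, 0.99)
    return(f)
  }
  if (role == "sweep_novel") {
    g1 <- config$sweep_spec$interval[1]
    g2 <- config$sweep_spec$interval[2]
    f[gens <= g1] <- clamp(rnorm(sum(gens <= g1), 0.01, 0.01), 0, 0.04)
    f[gens >= g2] <- clamp(0.85 + rnorm(sum(gens >= g2), 0, 0.04), 0.60, 0.99)
    mid <- gens > g1 & gens < g2
    f[mid] <- clamp(rnorm(sum(mid), 0.01, 0.01), 0, 0.04)
    return(f)
  }

  active <- gens >= appearance
  if (selected) {
    # Logistic rise: near the detection limit at appearance, >= 0.97 two
    # sampled generations later, then held near fixation.
    rise_span <- runif(1, 250, 450)
    mid <- appearance + rise_span / 2
    rate <- 8 / rise_span
    base <- 1 / (1 + exp(-rate * (gens - mid)))
    f[active] <- base[active]
    f[gens >= appearance + rise_span] <- 0.985
  } else {
    level <- runif(1, config$detection_limit + 0.02, 0.35)
    f[active] <- level
  }
  # Frequency-dependent noise, tiny near the 0/1 boundaries so fixed
  # mutations stay fixed in the sampled data.
  noisy <- f + rnorm(length(f), 0, 0.05) * sqrt(pmax(f * (1 - f), 0))
  noisy[!active] <- 0
  clamp(noisy)
}

build_trajectories <- function(events, config) {
  cols <- c("line", "organism", "generation", "gene", "frequency", "annotation")
  if (nrow(events) == 0) {
    return(tibble(line = character(), organism = character(),
                  generation = integer(), gene = character(),
                  frequency = numeric(), annotation = character()))
  }
  gens <- config$generations
  per_event <- pmap(
    list(events$appearance_generation, events$selected, events$role,
         events$line, events$organism, events$gene, events$annotation),
    function(app, sel, role, line, org, gene, ann) {
      tibble(line = line, organism = org, generation = gens, gene = gene,
             frequency = event_frequencies(app, sel, role, config),
             annotation = ann)
    }
  )
  traj <- bind_rows(per_event)
  # Two events in the same line x gene collapse to the gene-level frequency
  # (the bulk data is per-gene); keep the larger clone.
  traj %>%
    group_by(.data$line, .data$organism, .data$generation, .data$gene) %>%
    summarise(frequency = max(.data$frequency),
              annotation = first(.data$annotation), .groups = "drop") %>%
    arrange(.data$line, .data$organism, .data$gene, .data$generation) %>%
    select(all_of(cols))
}
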