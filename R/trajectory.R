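#' Earliest sustained fixation generation of a frequency trajectory
#'
#' Returns the earliest sampled generation at which the frequency is at or
#' above `threshold` and stays there at every later sample; transient
#' excursions above the threshold do not count.
#'
#' @param frequency Numeric frequency series, or a data frame with
#'   `generation` and `frequency` columns.
#' @param generation Generations matching `frequency` (ignored for data-frame
#'   input).
#' @param threshold Fixation threshold in (0, 1] (default 0.95).
#' @return The fixation generation, or `NA` if the mutation never fixes.
#' @export
#' @examples
#' detect_fixation(c(0.1, 0.6, 0.97, 0.99), c(100, 300, 500, 780)) # 500
detect_fixation <- function(frequency, generation = NULL, threshold = 0.95) {
  if (is.data.frame(frequency)) {
    check_columns(frequency, c("generation", "frequency"), "frequency")
    generation <- frequency$generation
    frequency <- frequency$frequency
  }
  if (length(frequency) == 0) abort("empty trajectory.")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  if (is.null(generation)) generation <- seq_along(frequency)
  ord <- order(generation)
  frequency <- frequency[ord]
  generation <- generation[ord]
  ok <- rev(cumprod(rev(frequency >= threshold))) == 1
  if (!any(ok)) return(NA_integer_)
  generation[which(ok)[1]]
}

# Per-(line, gene) trajectory summaries used by the association machinery:
# a bitmask of detected sample indices, the first detected generation, and
# the sustained fixation generation. Only detected (line, gene) pairs are
# kept.
traj_summaries <- function(trajectories, detection_limit = 0.05,
                           fixation_threshold = 0.95) {
  check_columns(trajectories, c("line", "generation", "gene", "frequency"),
                "trajectories")
  gens <- sort(unique(trajectories$generation))
  trajectories %>%
    group_by(.data$line, .data$gene) %>%
    summarise(
      mask = {
        idx <- match(.data$generation[.data$frequency >= detection_limit], gens)
        as.integer(sum(2^(idx - 1)))
      },
      first_det = {
        d <- .data$generation[.data$frequency >= detection_limit]
        if (length(d)) min(d) else NA_integer_
      },
      fix_gen = detect_fixation(.data$frequency, .data$generation,
                                fixation_threshold),
      .groups = "drop"
    ) %>%
    filter(.data$mask > 0)
}

popcount <- function(x) {
  n <- integer(length(x))
  x <- as.double(x)
  while (any(x > 0)) {
    n <- n + (x %% 2 > 0)
    x <- x %/% 2
  }
  n
}

# Predicate on an ordered summary pair (a then b) for each association mode.
pair_predicate <- function(mode, k) {
  switch(mode,
    co_occurrence = function(a, b) {
      popcount(bitwAnd(as.integer(a$mask), as.integer(b$mask))) >= k
    },
    simultaneous_fixation = function(a, b) {
      !is.na(a$fix_gen) && !is.na(b$fix_gen) && a$fix_gen == b$fix_gen
    },
    nested_fixation = function(a, b) {
      !is.na(a$fix_gen) && !is.na(b$fix_gen) &&
        !is.na(a$first_det) && !is.na(b$first_det) &&
        b$first_det > a$first_det && b$fix_gen <= a$fix_gen
    },
    abort(sprintf("unknown association mode '%s'.", mode))
  )
}

summary_row <- function(summaries, i) {
  list(mask = summaries$mask[i], first_det = summaries$first_det[i],
       fix_gen = summaries$fix_gen[i])
}

#' Association statistic between two loci across evolution lines
#'
#' Counts the number of evolution lines supporting one of three longitudinal
#' association patterns between `locus_a` and `locus_b`:
#' * `co_occurrence` — both loci detected (frequency at or above
#'   `detection_limit`) at `k` or more common sampled time points;
#' * `simultaneous_fixation` — both loci first reach sustained fixation at
#'   the same sampled generation;
#' * `nested_fixation` — `locus_b` rises above detection after `locus_a` yet
#'   fixes at a generation no later than `locus_a`'s fixation.
#'
#' @param trajectories Trajectory tibble (line, generation, gene, frequency).
#' @param locus_a,locus_b Gene/locus ids present in the data.
#' @param mode One of `"co_occurrence"`, `"simultaneous_fixation"`,
#'   `"nested_fixation"`.
#' @param k Minimum number of common detected time points for co-occurrence
#'   (default 2).
#' @param detection_limit Bulk detection limit (default 0.05).
#' @param fixation_threshold Sustained fixation threshold (default 0.95).
#' @return Integer count of supporting lines.
#' @export
association_statistic <- function(trajectories, locus_a, locus_b,
                                  mode = c("co_occurrence",
                                           "simultaneous_fixation",
                                           "nested_fixation"),
                                  k = 2L, detection_limit = 0.05,
                                  fixation_threshold = 0.95) {
  mode <- match.arg(mode)
  summaries <- traj_summaries(trajectories, detection_limit, fixation_threshold)
  if (!locus_a %in% summaries$gene || !locus_b %in% summaries$gene) {
    abort("both loci must be detected somewhere in `trajectories`.")
  }
  count_pair_lines(summaries, locus_a, locus_b, pair_predicate(mode, k))
}

count_pair_lines <- function(summaries, locus_a, locus_b, pred) {
  sa <- summaries[summaries$gene == locus_a, ]
  sb <- summaries[summaries$gene == locus_b, ]
  shared <- intersect(sa$line, sb$line)
  sum(vapply(shared, function(ln) {
    pred(summary_row(sa, match(ln, sa$line)), summary_row(sb, match(ln, sb$line)))
  }, logical(1)))
}

#' Empirical permutation P value for a longitudinal association
#'
#' Tests an [association_statistic()] against a randomization null that
#' maintains the number of mutated genes per evolution line and the number of
#' lines carrying each gene. When the line-by-gene presence matrix admits
#' checkerboard swaps, the null is swap randomization (both margins
#' preserved, with detected-generation trajectories permuted among a line's
#' events); when the matrix is degenerate (no valid swap exists) the null
#' falls back to independent placement of each gene over line subsets of the
#' observed size, the gene's observed trajectories travelling with it. The P
#' value is `(s + 1) / (n + 1)` with `s` the number of null replicates whose
#' statistic is at least the observed one.
#'
#' @inheritParams association_statistic
#' @param n Number of null replicates (default 1e5; the full-fidelity setting
#'   is 1e6).
#' @param seed Integer seed.
#' @param null `"auto"` (swap with placement fallback), `"swap"` or
#'   `"placement"`.
#' @param swap_thin Swap attempts between successive replicates (swap null).
#' @return One-row tibble: `statistic`, `observed`, `s`, `n`, `p`, `null`.
#' @export
permutation_pvalue <- function(trajectories, locus_a, locus_b,
                               mode = c("co_occurrence",
                                        "simultaneous_fixation",
                                        "nested_fixation"),
                               n = 1e5, seed = 1L, k = 2L,
                               detection_limit = 0.05,
                               fixation_threshold = 0.95,
                               null = c("auto", "swap", "placement"),
                               swap_thin = NULL) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  if (n < 1) abort("`n` must be >= 1.")
  summaries <- traj_summaries(trajectories, detection_limit, fixation_threshold)
  if (!locus_a %in% summaries$gene || !locus_b %in% summaries$gene) {
    abort("both loci must be detected somewhere in `trajectories`.")
  }
  pred <- pair_predicate(mode, k)
  observed <- count_pair_lines(summaries, locus_a, locus_b, pred)
  lines <- sort(unique(trajectories$line))

  res <- with_seed(seed, {
    if (null == "placement") {
      list(s = placement_null(summaries, lines, locus_a, locus_b, pred,
                              n, observed),
           null = "placement")
    } else {
      sw <- swap_null(summaries, lines, locus_a, locus_b, pred, n, observed,
                      swap_thin)
      if (is.null(sw)) {
        if (null == "swap") {
          abort("presence matrix admits no checkerboard swaps; use the placement null.")
        }
        list(s = placement_null(summaries, lines, locus_a, locus_b, pred,
                                n, observed),
             null = "placement")
      } else {
        list(s = sw, null = "swap")
      }
    }
  })

  tibble(statistic = mode, observed = observed, s = res$s, n = as.integer(n),
         p = (res$s + 1) / (n + 1), null = res$null)
}

# Placement null: each gene is dropped onto a uniform subset of lines of its
# observed size; its observed per-line summaries are shuffled onto those
# lines. Only the two tested loci matter for the statistic.
placement_null <- function(summaries, lines, locus_a, locus_b, pred, n,
                           observed) {
  L <- length(lines)
  sa <- summaries[summaries$gene == locus_a, ]
  sb <- summaries[summaries$gene == locus_b, ]
  ka <- nrow(sa)
  kb <- nrow(sb)
  s <- 0L
  for (r in seq_len(n)) {
    la <- sample.int(L, ka)
    lb <- sample.int(L, kb)
    pa <- sample.int(ka)
    pb <- sample.int(kb)
    co <- intersect(la, lb)
    stat <- 0L
    for (ln in co) {
      a <- summary_row(sa, pa[match(ln, la)])
      b <- summary_row(sb, pb[match(ln, lb)])
      if (pred(a, b)) stat <- stat + 1L
    }
    if (stat >= observed) s <- s + 1L
  }
  s
}

# Swap null: checkerboard-swap randomization of the line x gene presence
# matrix (both margins preserved exactly); within a line, the observed
# trajectory summaries are re-dealt among that line's events. Returns NULL
# when the matrix is degenerate (no successful swap during burn-in).
swap_null <- function(summaries, lines, locus_a, locus_b, pred, n, observed,
                      swap_thin = NULL) {
  genes <- sort(unique(summaries$gene))
  L <- length(lines)
  G <- length(genes)
  if (L < 2 || G < 2) return(NULL)
  M <- matrix(0L, L, G, dimnames = list(lines, genes))
  M[cbind(match(summaries$line, lines), match(summaries$gene, genes))] <- 1L

  # Per-line pools of event summaries (the row margins fix the pool sizes).
  pool <- map(lines, function(ln) {
    idx <- which(summaries$line == ln)
    list(mask = summaries$mask[idx], first_det = summaries$first_det[idx],
         fix_gen = summaries$fix_gen[idx])
  })
  pool_n <- vapply(pool, function(p) length(p$mask), integer(1))

  try_swap <- function(M) {
    r <- sample.int(L, 2)
    c <- sample.int(G, 2)
    a <- M[r[1], c[1]]; b <- M[r[1], c[2]]
    d <- M[r[2], c[1]]; e <- M[r[2], c[2]]
    if (a == e && b == d && a != b) {
      M[r[1], c[1]] <- b; M[r[1], c[2]] <- a
      M[r[2], c[1]] <- e; M[r[2], c[2]] <- d
      attr(M, "swapped") <- TRUE
    } else {
      attr(M, "swapped") <- FALSE
    }
    M
  }

  fill <- sum(M)
  burn_attempts <- max(200L, 10L * fill)
  swapped_any <- FALSE
  for (i in seq_len(burn_attempts)) {
    M <- try_swap(M)
    swapped_any <- swapped_any || attr(M, "swapped")
  }
  if (!swapped_any) return(NULL)

  thin <- swap_thin %||% max(2L * L, 10L)
  ca <- match(locus_a, genes)
  cb <- match(locus_b, genes)
  s <- 0L
  for (r in seq_len(n)) {
    for (i in seq_len(thin)) M <- try_swap(M)
    co <- which(M[, ca] == 1L & M[, cb] == 1L)
    stat <- 0L
    for (ln in co) {
      np <- pool_n[ln]
      if (np < 2) next
      ij <- sample.int(np, 2)
      a <- list(mask = pool[[ln]]$mask[ij[1]],
                first_det = pool[[ln]]$first_det[ij[1]],
                fix_gen = pool[[ln]]$fix_gen[ij[1]])
      b <- list(mask = pool[[ln]]$mask[ij[2]],
                first_det = pool[[ln]]$first_det[ij[2]],
                fix_gen = pool[[ln]]$fix_gen[ij[2]])
      if (pred(a, b)) stat <- stat + 1L
    }
    if (stat >= observed) s <- s + 1L
  }
  s
}

#' Exact enumeration P value for the placement null
#'
#' Independent oracle for [permutation_pvalue()] on instances small enough to
#' enumerate: every assignment of each locus to a line subset of its observed
#' size is enumerated and the exact probability of an association statistic
#' at least as large as observed is returned. Requires the pair predicate to
#' be constant across the loci's trajectory summaries (which holds for the
#' canonical enumerable fixtures); otherwise the within-line dealing of
#' summaries would make the placement-conditional law non-degenerate and
#' enumeration is refused.
#'
#' @inheritParams association_statistic
#' @param max_space Maximum number of placement pairs to enumerate.
#' @return Exact P value (numeric scalar).
#' @export
exact_association_pvalue <- function(trajectories, locus_a, locus_b,
                                     mode = c("co_occurrence",
                                              "simultaneous_fixation",
                                              "nested_fixation"),
                                     k = 2L, detection_limit = 0.05,
                                     fixation_threshold = 0.95,
                                     max_space = 1e6) {
  mode <- match.arg(mode)
  summaries <- traj_summaries(trajectories, detection_limit, fixation_threshold)
  pred <- pair_predicate(mode, k)
  observed <- count_pair_lines(summaries, locus_a, locus_b, pred)
  lines <- sort(unique(trajectories$line))
  L <- length(lines)
  sa <- summaries[summaries$gene == locus_a, ]
  sb <- summaries[summaries$gene == locus_b, ]
  ka <- nrow(sa)
  kb <- nrow(sb)
  if (choose(L, ka) * choose(L, kb) > max_space) {
    abort("placement space too large to enumerate; use permutation_pvalue().")
  }
  vals <- as.logical(outer(seq_len(ka), seq_len(kb), Vectorize(function(i, j) {
    pred(summary_row(sa, i), summary_row(sb, j))
  })))
  if (length(unique(vals)) > 1) {
    abort(paste("pair predicate varies across trajectory summaries;",
                "exact enumeration is not available for this instance."))
  }
  pred_const <- vals[1]

  sets_a <- utils::combn(L, ka, simplify = FALSE)
  sets_b <- utils::combn(L, kb, simplify = FALSE)
  hits <- 0
  for (A in sets_a) {
    for (B in sets_b) {
      stat <- if (pred_const) length(intersect(A, B)) else 0L
      if (stat >= observed) hits <- hits + 1
    }
  }
  hits / (length(sets_a) * length(sets_b))
}

#' Detect a cross-species selective sweep in one evolution line
#'
#' Scans adjacent sampled generation intervals `(g1, g2]` of one line for the
#' signature of a joint sweep: in *both* partner organisms, a non-empty set
#' of loci falls from dominance (frequency at or above `dominance`) to below
#' the detection limit, while a disjoint non-empty set rises from below
#' detection to dominance. The earliest such interval is reported.
#'
#' @param trajectories Trajectory tibble with an `organism` column.
#' @param line Line id to scan.
#' @param detection_limit Below-detection cutoff (default 0.05).
#' @param dominance Dominance cutoff (default 0.5).
#' @return Tibble (line, gen_start, gen_end, organism, locus, role) with
#'   roles `"replaced"` and `"novel"`; zero rows when no cross-species sweep
#'   is found.
#' @export
detect_sweep <- function(trajectories, line, detection_limit = 0.05,
                         dominance = 0.5) {
  check_columns(trajectories, c("line", "organism", "generation", "gene",
                                "frequency"), "trajectories")
  tr <- filter(trajectories, .data$line == !!line)
  if (nrow(tr) == 0) abort(sprintf("line '%s' not found.", line))
  orgs <- sort(unique(tr$organism))
  if (length(orgs) < 2) abort("cross-species sweep detection needs both organisms.")
  grids <- map(orgs, ~ sort(unique(tr$generation[tr$organism == .x])))
  if (length(unique(map_chr(grids, paste, collapse = ","))) != 1) {
    abort("organisms were sampled on different generation grids.")
  }
  gens <- grids[[1]]

  empty <- tibble(line = character(), gen_start = integer(),
                  gen_end = integer(), organism = character(),
                  locus = character(), role = character())
  if (length(gens) < 2) return(empty)

  freq_mat <- function(org) {
    sub <- filter(tr, .data$organism == org)
    wide <- pivot_wider(sub[, c("gene", "generation", "frequency")],
                        names_from = "generation", values_from = "frequency",
                        values_fill = 0)
    m <- as.matrix(wide[, as.character(gens), drop = FALSE])
    rownames(m) <- wide$gene
    m
  }
  mats <- setNames(map(orgs, freq_mat), orgs)

  for (i in seq_len(length(gens) - 1)) {
    records <- list()
    ok <- TRUE
    for (org in orgs) {
      m <- mats[[org]]
      replaced <- rownames(m)[m[, i] >= dominance & m[, i + 1] < detection_limit]
      novel <- rownames(m)[m[, i] < detection_limit & m[, i + 1] >= dominance]
      if (length(replaced) == 0 || length(novel) == 0) {
        ok <- FALSE
        break
      }
      records[[org]] <- tibble(
        line = line, gen_start = gens[i], gen_end = gens[i + 1],
        organism = org,
        locus = c(replaced, novel),
        role = rep(c("replaced", "novel"), c(length(replaced), length(novel)))
      )
    }
    if (ok) return(bind_rows(records))
  }
  empty
}
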