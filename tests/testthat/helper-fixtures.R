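# Fixtures and independent oracles used across the suite.

# Canonical five-variant multi-caller fixture:
#   A by 3 callers @ 0.5, B by 2 @ 0.25, C by 1 @ 0.9, D by 3 @ 0.19,
#   E by 2 @ 0.20  ->  consensus keeps {A, B, E}.
five_variant_calls <- function() {
  mk <- function(locus, position, callers, freq) {
    tibble::tibble(caller = callers, chrom = "genome", position = position,
                   ref = "A", alt = "T", frequency = freq, locus = locus)
  }
  dplyr::bind_rows(
    mk("A", 100L, c("gatk", "varscan", "bcftools"), 0.5),
    mk("B", 200L, c("gatk", "varscan"), 0.25),
    mk("C", 300L, "gatk", 0.9),
    mk("D", 400L, c("gatk", "varscan", "bcftools"), 0.19),
    mk("E", 500L, c("gatk", "varscan"), 0.20)
  )
}

# Enumerable permutation instance: 3 lines, 2 genes, each gene detected in
# exactly lines L1 and L2 (so observed co-occurrence = 2 with k = 1).
# The L3 row sits below the detection limit: the line exists but carries no
# event, so the 3 x 2 presence matrix admits no checkerboard swap.
# Exact placement-null P(X >= 2) = 3/9 = 1/3.
enumerable_trajectories <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(line = c("L1", "L2"), gene = c("gA", "gB"),
                       generation = c(100L, 300L)) |>
      dplyr::mutate(frequency = 0.6),
    tibble::tibble(line = "L3", gene = "gA", generation = 100L,
                   frequency = 0)
  )
}

# Independent-gene data for P-uniformity: each tested gene present in each
# line independently with probability p, constant frequency trajectories.
independent_gene_trajectories <- function(seed, n_lines = 150, p = 0.5) {
  withr::with_seed(seed, {
    lines <- sprintf("L%03d", seq_len(n_lines))
    rows <- lapply(c("gA", "gB"), function(g) {
      pres <- lines[stats::runif(n_lines) < p]
      tibble::tibble(line = pres, generation = 100L, gene = g,
                     frequency = 0.6)
    })
    dplyr::bind_rows(
      dplyr::bind_rows(rows),
      tibble::tibble(line = lines, generation = 300L, gene = "anchor",
                     frequency = 0.6)
    )
  })
}

# --- brute-force mutation-tree oracle (independent of the package path) ---

# All valid parent vectors on m labeled mutations, found by checking that a
# walk from every node reaches the root.
oracle_all_trees <- function(m) {
  combos <- vector("list", 0)
  recurse <- function(prefix) {
    i <- length(prefix) + 1
    if (i > m) {
      combos[[length(combos) + 1]] <<- prefix
      return(invisible())
    }
    for (p in setdiff(0:m, i)) recurse(c(prefix, p))
  }
  recurse(integer(0))
  ok <- vapply(combos, function(parent) {
    for (v in seq_len(m)) {
      seen <- integer(0)
      u <- v
      while (u != 0) {
        if (u %in% seen) return(FALSE)
        seen <- c(seen, u)
        u <- parent[u]
      }
    }
    TRUE
  }, logical(1))
  combos[ok]
}

# Direct likelihood of one tree: explicit per-cell, per-node, per-mutation
# probability products (no logs, no matrix algebra).
oracle_tree_lik <- function(parent, D, fd, ad) {
  m <- length(parent)
  genotype_of <- function(v) {
    g <- integer(m)
    while (v != 0) {
      g[v] <- 1L
      v <- parent[v]
    }
    g
  }
  genos <- rbind(integer(m), t(vapply(seq_len(m), genotype_of, integer(m))))
  total <- 0
  for (i in seq_len(nrow(D))) {
    best <- 0
    for (v in seq_len(m + 1)) {
      p <- 1
      for (j in seq_len(m)) {
        obs <- D[i, j]
        g <- genos[v, j]
        p <- p * if (obs == 3) 1 else if (obs == 1) {
          if (g == 1) 1 - ad else fd
        } else {
          if (g == 1) ad else 1 - fd
        }
      }
      best <- max(best, p)
    }
    total <- total + log(best)
  }
  total
}

oracle_best_tree <- function(D, fd, ad) {
  m <- ncol(D)
  trees <- oracle_all_trees(m)
  lls <- vapply(trees, oracle_tree_lik, numeric(1), D = D, fd = fd, ad = ad)
  list(loglik = max(lls), trees = trees[lls >= max(lls) - 1e-9])
}
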