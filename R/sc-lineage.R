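#' Build a single-cell mutation matrix from per-cell variant records
#'
#' Applies the single-cell genotyping cutoffs: a cell's state at a site is 3
#' (not enough reads) when its fold coverage is below `min_coverage`
#' (default 8), otherwise 1 when the within-cell variant frequency is at or
#' above `min_frequency` (default 0.80) and 0 otherwise. Mutation columns
#' are retained only when at least `min_cells` cells (default 2) carry the
#' mutation. Missing (cell, mutation) records are treated as no reads
#' (state 3).
#'
#' @param per_cell_calls Tibble with columns `cell`, `mutation`, `coverage`,
#'   `frequency`.
#' @param min_coverage Minimum fold coverage for a callable genotype.
#' @param min_cells Minimum number of state-1 cells to keep a mutation.
#' @param min_frequency Minimum within-cell frequency to call presence.
#' @param fd,ad Error-model rates stored on the matrix (defaults are the
#'   single-cell pipeline's estimates).
#' @return A [mutation_matrix()].
#' @export
build_mutation_matrix <- function(per_cell_calls, min_coverage = 8L,
                                  min_cells = 2L, min_frequency = 0.80,
                                  fd = 6.04e-5, ad = 0.21545) {
  check_columns(per_cell_calls, c("cell", "mutation", "coverage", "frequency"),
                "per_cell_calls")
  if (nrow(per_cell_calls) == 0) abort("`per_cell_calls` is empty.")
  if (min_coverage < 0 || min_cells < 0) abort("thresholds must be >= 0.")
  check_probability(min_frequency, "min_frequency")

  df <- per_cell_calls %>%
    mutate(state = dplyr::case_when(
      .data$coverage < min_coverage ~ 3L,
      .data$frequency >= min_frequency ~ 1L,
      TRUE ~ 0L
    ))
  cells <- sort(unique(df$cell))
  muts <- sort(unique(df$mutation))
  M <- matrix(3L, length(cells), length(muts),
              dimnames = list(cells, muts))
  M[cbind(match(df$cell, cells), match(df$mutation, muts))] <- df$state

  keep <- colSums(M == 1L) >= min_cells
  if (!any(keep)) {
    warn("no mutation passed the min_cells filter; matrix has zero columns.")
  }
  mutation_matrix(M[, keep, drop = FALSE], fd = fd, ad = ad)
}

LOG_ZERO <- -1e9 # stands in for log(0); exp() of it underflows to exactly 0

# Per-cell, per-attachment-node log-likelihood matrix under the fd/ad model.
attachment_loglik <- function(G, D, fd, ad) {
  l1g1 <- log(1 - ad) # observed 1, true 1
  l1g0 <- if (fd > 0) log(fd) else LOG_ZERO
  l0g1 <- if (ad > 0) log(ad) else LOG_ZERO
  l0g0 <- log(1 - fd)
  A1 <- (D == 1L) * 1
  A0 <- (D == 0L) * 1
  Gt <- t(G)
  G0 <- t(1L - G)
  A1 %*% Gt * l1g1 + A1 %*% G0 * l1g0 + A0 %*% Gt * l0g1 + A0 %*% G0 * l0g0
}

#' Log-likelihood of a mutation tree for a single-cell matrix
#'
#' SCITE-style likelihood: for every cell and candidate attachment node, an
#' observed 1 against a true 0 has probability `fd`, an observed 0 against a
#' true 1 has probability `ad` (with complements for concordant states), and
#' the missing state 3 contributes a factor of 1. With `attachment = "max"`
#' each cell is scored at its best (maximum-likelihood) attachment node;
#' with `"sum"` the cell likelihood is averaged over attachment nodes
#' (uniform prior including the root). The total is the sum of per-cell log
#' likelihoods.
#'
#' @param tree A [mutation_tree()] whose labels cover the matrix columns.
#' @param matrix A [mutation_matrix()].
#' @param attachment `"max"` (default) or `"sum"`.
#' @param fd,ad Optional overrides of the matrix's error rates.
#' @return Log-likelihood (numeric scalar).
#' @export
tree_loglikelihood <- function(tree, matrix, attachment = c("max", "sum"),
                               fd = NULL, ad = NULL) {
  attachment <- match.arg(attachment)
  stopifnot(inherits(tree, "mutation_tree"))
  fd <- fd %||% attr(matrix, "fd")
  ad <- ad %||% attr(matrix, "ad")
  if (fd >= 1 || ad >= 1) abort("`fd` and `ad` must be < 1.")
  missing_labels <- setdiff(colnames(matrix), tree$labels)
  if (length(missing_labels) > 0) {
    abort(sprintf("matrix mutation(s) not labeled in the tree: %s",
                  paste(missing_labels, collapse = ", ")))
  }
  G <- tree_genotypes(tree)[, colnames(matrix), drop = FALSE]
  S <- attachment_loglik(G, unclass(matrix), fd, ad)
  if (attachment == "max") {
    sum(apply(S, 1, max))
  } else {
    sum(apply(S, 1, function(r) {
      mx <- max(r)
      mx + log(mean(exp(r - mx)))
    }))
  }
}

# All parent vectors of rooted labeled trees on m mutations.
enumerate_parent_vectors <- function(m) {
  grid <- as.matrix(expand.grid(rep(list(0:m), m)))
  colnames(grid) <- NULL
  grid <- grid[!apply(grid == matrix(seq_len(m), nrow(grid), m, byrow = TRUE),
                      1, any), , drop = FALSE]
  cur <- grid
  for (i in seq_len(m)) {
    idx <- cur != 0L
    cur[idx] <- grid[cbind(row(cur)[idx], cur[idx])]
  }
  grid[rowSums(cur) == 0, , drop = FALSE]
}

#' Infer the maximum-likelihood mutation tree
#'
#' Either exhaustively enumerates every rooted labeled mutation tree (all
#' parent vectors; feasible for up to 7 mutations) and returns the global
#' optimum of [tree_loglikelihood()], or runs a seeded Metropolis search
#' (prune-and-reattach and label-swap proposals) and returns the best tree
#' visited. Likelihood ties are broken deterministically in favor of the
#' lexicographically smallest parent vector, and label pairs whose exchange
#' leaves the likelihood unchanged are reported as ties.
#'
#' @param matrix A [mutation_matrix()] with at least one column.
#' @param search `"exhaustive"` or `"mcmc"`.
#' @param seed Integer seed (MCMC).
#' @param chain_length MCMC iterations (default 1e5).
#' @param attachment Passed to [tree_loglikelihood()].
#' @param fd,ad Optional error-rate overrides.
#' @return Object of class `ml_tree_fit`: list with `tree`, `loglik`,
#'   `n_ties` (number of optimal trees, exhaustive only), `tied_labels`
#'   (label pairs exchangeable without likelihood change) and `search`.
#' @export
infer_ml_tree <- function(matrix, search = c("exhaustive", "mcmc"), seed = 1L,
                          chain_length = 1e5, attachment = "max",
                          fd = NULL, ad = NULL) {
  search <- match.arg(search)
  m <- ncol(matrix)
  if (m == 0) abort("matrix has zero retained mutations.")
  fd <- fd %||% attr(matrix, "fd")
  ad <- ad %||% attr(matrix, "ad")
  labels <- colnames(matrix)
  D <- unclass(matrix)

  score <- function(parent) {
    G <- tree_genotypes(list(parent = parent, labels = labels))
    S <- attachment_loglik(G, D, fd, ad)
    if (attachment == "max") sum(apply(S, 1, max)) else
      sum(apply(S, 1, function(r) {
        mx <- max(r)
        mx + log(mean(exp(r - mx)))
      }))
  }

  if (search == "exhaustive") {
    if (m > 7) abort("exhaustive search supports at most 7 mutations; use mcmc.")
    vecs <- enumerate_parent_vectors(m)
    ll <- apply(vecs, 1, score)
    best_ll <- max(ll)
    tied <- which(ll >= best_ll - 1e-9)
    # lexicographic tie-break on the parent vector
    ord <- do.call(order, as.data.frame(vecs[tied, , drop = FALSE]))
    best_parent <- vecs[tied[ord[1]], ]
    n_ties <- length(tied)
  } else {
    best <- with_seed(seed, mcmc_search(score, m, chain_length))
    best_parent <- best$parent
    best_ll <- best$loglik
    n_ties <- NA_integer_
  }

  tree <- mutation_tree(best_parent, labels)
  structure(
    list(tree = tree, loglik = best_ll, n_ties = n_ties,
         tied_labels = tied_label_pairs(best_parent, labels, score, best_ll),
         search = search),
    class = "ml_tree_fit"
  )
}

mcmc_search <- function(score, m, chain_length) {
  parent <- random_mutation_tree(m)$parent
  ll <- score(parent)
  best_parent <- parent
  best_ll <- ll
  for (it in seq_len(chain_length)) {
    prop <- parent
    if (m >= 2 && runif(1) < 0.4) {
      ij <- sample.int(m, 2)
      # label swap = swap the two nodes' positions in the parent vector
      prop <- swap_nodes(parent, ij[1], ij[2])
    } else {
      v <- sample.int(m, 1)
      desc <- descendants(parent, v)
      candidates <- setdiff(0:m, c(v, desc, parent[v]))
      if (length(candidates) == 0) next
      prop[v] <- candidates[sample.int(length(candidates), 1)]
    }
    prop_ll <- score(prop)
    if (prop_ll >= ll || runif(1) < exp(prop_ll - ll)) {
      parent <- prop
      ll <- prop_ll
      if (ll > best_ll) {
        best_ll <- ll
        best_parent <- parent
      }
    }
  }
  list(parent = best_parent, loglik = best_ll)
}

descendants <- function(parent, v) {
  m <- length(parent)
  out <- integer(0)
  frontier <- v
  while (length(frontier) > 0) {
    kids <- which(parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

swap_nodes <- function(parent, i, j) {
  new <- parent
  pi <- parent[i]
  pj <- parent[j]
  new[i] <- if (pj == i) j else pj
  new[j] <- if (pi == j) i else pi
  kids_i <- which(parent == i)
  kids_j <- which(parent == j)
  new[setdiff(kids_i, j)] <- j
  new[setdiff(kids_j, i)] <- i
  new
}

tied_label_pairs <- function(parent, labels, score, best_ll) {
  m <- length(parent)
  if (m < 2) return(list())
  pairs <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (abs(score(swap_nodes(parent, i, j)) - best_ll) < 1e-9) {
        pairs[[length(pairs) + 1]] <- c(labels[i], labels[j])
      }
    }
  }
  pairs
}

#' @export
print.ml_tree_fit <- function(x, ...) {
  cat(sprintf("<ml_tree_fit> (%s search)\n", x$search))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (!is.na(x$n_ties) && x$n_ties > 1) {
    cat(sprintf("  %d trees tie at the optimum\n", x$n_ties))
  }
  cat(" ", as_newick(x$tree), "\n")
  invisible(x)
}

#' @rdname infer_ml_tree
#' @param x,object An `ml_tree_fit`.
#' @param ... Unused.
#' @export
glance.ml_tree_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_mutations = length(x$tree$parent),
         n_ties = x$n_ties, n_tied_labels = length(x$tied_labels),
         search = x$search, newick = as_newick(x$tree))
}

#' @rdname infer_ml_tree
#' @export
tidy.ml_tree_fit <- function(x, ...) {
  parent <- x$tree$parent
  tibble(
    mutation = x$tree$labels,
    parent = if_else(parent == 0L, "root", x$tree$labels[parent]),
    depth = node_depths(parent) + 1L
  )
}

#' Order likelihood-tied trunk mutations by longitudinal first detection
#'
#' The trunk is the maximal unbranched path from the root. For adjacent
#' trunk mutations reported as likelihood ties, the order is set by the
#' first generation each mutation was detected in the longitudinal bulk
#' data; a tied mutation absent from the bulk data keeps its tree position
#' and is flagged as a rare / below-detection lineage.
#'
#' @param fit An `ml_tree_fit` (or a [mutation_tree()] plus `tied_labels`).
#' @param trajectories Longitudinal trajectory tibble (line, generation,
#'   gene, frequency).
#' @param detection_limit Detection limit for first appearance (default
#'   0.05).
#' @param tied_labels Optional list of tied label pairs (defaults to the
#'   fit's).
#' @return List with the re-ordered `tree` and a `decisions` tibble (upper,
#'   lower, action, flag).
#' @export
order_trunk_by_generations <- function(fit, trajectories,
                                       detection_limit = 0.05,
                                       tied_labels = NULL) {
  if (inherits(fit, "ml_tree_fit")) {
    tree <- fit$tree
    tied_labels <- tied_labels %||% fit$tied_labels
  } else {
    tree <- fit
    tied_labels <- tied_labels %||% list()
  }
  check_columns(trajectories, c("generation", "gene", "frequency"),
                "trajectories")

  first_det <- trajectories %>%
    filter(.data$frequency >= detection_limit) %>%
    group_by(.data$gene) %>%
    summarise(first_gen = min(.data$generation), .groups = "drop")
  gen_of <- function(lbl) {
    g <- first_det$first_gen[first_det$gene == lbl]
    if (length(g)) g[1] else NA_integer_
  }
  is_tied_pair <- function(a, b) {
    any(vapply(tied_labels, function(p) all(sort(p) == sort(c(a, b))),
               logical(1)))
  }

  decisions <- tibble(upper = character(), lower = character(),
                      action = character(), flag = character())
  parent <- tree$parent
  repeat {
    trunk <- trunk_path(parent)
    swapped <- FALSE
    if (length(trunk) >= 2) {
      for (i in seq_len(length(trunk) - 1)) {
        up <- trunk[i]
        dn <- trunk[i + 1]
        a <- tree$labels[up]
        b <- tree$labels[dn]
        if (!is_tied_pair(a, b)) next
        ga <- gen_of(a)
        gb <- gen_of(b)
        if (is.na(ga) || is.na(gb)) {
          flagged <- c(a, b)[is.na(c(ga, gb))]
          decisions <- bind_rows(decisions, tibble(
            upper = a, lower = b, action = "kept",
            flag = paste0("rare/below-detection: ",
                          paste(flagged, collapse = ","))
          ))
        } else if (gb < ga) {
          parent <- swap_nodes(parent, up, dn)
          decisions <- bind_rows(decisions, tibble(
            upper = a, lower = b, action = "swapped", flag = NA_character_))
          swapped <- TRUE
          break
        } else {
          decisions <- bind_rows(decisions, tibble(
            upper = a, lower = b, action = "kept", flag = NA_character_))
        }
      }
    }
    if (!swapped) break
  }
  list(tree = mutation_tree(parent, tree$labels),
       decisions = distinct(decisions))
}

trunk_path <- function(parent) {
  children <- split(seq_along(parent), parent)
  path <- integer(0)
  v <- 0L
  repeat {
    kids <- children[[as.character(v)]]
    if (is.null(kids) || length(kids) != 1) break
    v <- kids
    path <- c(path, v)
  }
  path
}
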