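#' Rooted mutation tree
#'
#' A mutation tree is a rooted tree whose non-root nodes each carry exactly
#' one mutation label; a cell attached at a node carries every mutation on
#' the root-to-node path. Internally the tree is a parent vector: entry `i`
#' is the parent of mutation node `i`, with 0 denoting the (unlabeled) root.
#'
#' @param parent Integer vector; `parent[i]` in `0:m`, no self-loops, acyclic.
#' @param labels Character vector of unique mutation ids (default
#'   `M1..Mm`).
#' @return Object of class `mutation_tree`.
#' @export
#' @examples
#' mutation_tree(c(0, 1, 1), c("dsrC", "galU", "fliA")) # dsrC trunk, two branches
mutation_tree <- function(parent, labels = NULL) {
  parent <- as.integer(parent)
  m <- length(parent)
  if (m == 0) abort("tree must contain at least one mutation.")
  labels <- labels %||% paste0("M", seq_len(m))
  if (length(labels) != m || anyDuplicated(labels)) {
    abort("`labels` must be unique and match the number of nodes.")
  }
  if (any(parent < 0) || any(parent > m) || any(parent == seq_len(m))) {
    abort("`parent` entries must be in 0..m with no self-loops.")
  }
  if (!is_acyclic_parent(parent)) abort("`parent` vector contains a cycle.")
  structure(list(parent = parent, labels = labels), class = "mutation_tree")
}

is_acyclic_parent <- function(parent) {
  m <- length(parent)
  cur <- parent
  for (i in seq_len(m)) {
    cur <- ifelse(cur == 0L, 0L, parent[cur])
  }
  all(cur == 0L)
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("<mutation_tree> %d mutations\n", length(x$parent)))
  cat(" ", as_newick(x), "\n")
  invisible(x)
}

#' Draw a random mutation tree
#'
#' Nodes are attached in a random order, each to a parent chosen uniformly
#' among the root and previously attached nodes (a random recursive tree on a
#' random node ordering).
#'
#' @param m Number of mutations.
#' @param labels Optional labels.
#' @param seed Optional seed.
#' @return A [mutation_tree()].
#' @export
random_mutation_tree <- function(m, labels = NULL, seed = NULL) {
  draw <- function() {
    ord <- sample.int(m)
    parent <- integer(m)
    for (j in seq_along(ord)) {
      choices <- c(0L, ord[seq_len(j - 1)])
      parent[ord[j]] <- choices[sample.int(length(choices), 1)]
    }
    mutation_tree(parent, labels)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Genotype matrix of a tree: (m + 1) x m binary matrix, row v + 1 giving the
# genotype of a cell attached at node v (row 1 = root = all zeros).
tree_genotypes <- function(tree) {
  parent <- tree$parent
  m <- length(parent)
  G <- matrix(0L, m + 1, m)
  depth_order <- order(node_depths(parent))
  for (v in depth_order) {
    G[v + 1, ] <- G[parent[v] + 1, ]
    G[v + 1, v] <- 1L
  }
  colnames(G) <- tree$labels
  G
}

node_depths <- function(parent) {
  m <- length(parent)
  d <- integer(m)
  for (v in seq_len(m)) {
    u <- v
    while (parent[u] != 0L) {
      u <- parent[u]
      d[v] <- d[v] + 1L
    }
  }
  d
}

#' Newick serialization of a mutation tree
#'
#' Internal nodes carry their mutation label; the root is unlabeled. Children
#' are ordered alphabetically so equal trees serialize identically.
#'
#' @param tree A [mutation_tree()].
#' @return Newick string.
#' @export
as_newick <- function(tree) {
  children <- split(seq_along(tree$parent), tree$parent)
  render <- function(v) {
    kids <- children[[as.character(v)]]
    label <- if (v == 0L) "" else tree$labels[v]
    if (is.null(kids)) return(label)
    sub <- sort(vapply(kids, render, character(1)))
    paste0("(", paste(sub, collapse = ","), ")", label)
  }
  paste0(render(0L), ";")
}

#' Simulate a single-cell mutation matrix from a known tree
#'
#' Each cell attaches uniformly at random to a tree node (including the
#' root, i.e. no mutations); its true genotype is the root-to-node path. The
#' observation model flips a true 0 to 1 with probability `fd` (false
#' positive), a true 1 to 0 with probability `ad` (allelic dropout), and
#' overrides any entry with the missing state 3 with probability
#' `missing_rate`.
#'
#' @param tree A [mutation_tree()].
#' @param n_cells Number of cells (>= 1).
#' @param fd False-positive probability.
#' @param ad Allelic-dropout probability.
#' @param missing_rate Missing-data probability.
#' @param seed Integer seed.
#' @return A `mutation_matrix` (cells x mutations integer matrix over
#'   \{0, 1, 3\}) with attributes `fd`, `ad` and `truth` (the attachment
#'   vector, 0 = root).
#' @export
simulate_single_cells <- function(tree, n_cells, fd = 6.04e-5, ad = 0.21545,
                                  missing_rate = 0, seed = 1L) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  check_probability(fd, "fd")
  check_probability(ad, "ad")
  check_probability(missing_rate, "missing_rate")

  G <- tree_genotypes(tree)
  m <- length(tree$parent)
  with_seed(seed, {
    attach_at <- sample.int(m + 1, n_cells, replace = TRUE) - 1L
    truth <- G[attach_at + 1, , drop = FALSE]
    obs <- truth
    flip_up <- truth == 0L & matrix(runif(n_cells * m) < fd, n_cells, m)
    flip_dn <- truth == 1L & matrix(runif(n_cells * m) < ad, n_cells, m)
    obs[flip_up] <- 1L
    obs[flip_dn] <- 0L
    obs[matrix(runif(n_cells * m) < missing_rate, n_cells, m)] <- 3L
    rownames(obs) <- sprintf("cell_%03d", seq_len(n_cells))
    mutation_matrix(obs, fd = fd, ad = ad, truth = attach_at)
  })
}

#' Construct a mutation matrix
#'
#' @param states Integer matrix (cells x mutations) over \{0, 1, 3\}.
#' @param fd,ad Error-model probabilities in `[0, 1)` attached to the matrix.
#' @param truth Optional ground-truth attachment vector.
#' @return Object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(states, fd = 6.04e-5, ad = 0.21545, truth = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L, 3L))) {
    abort("matrix states must be 0 (absent), 1 (present) or 3 (not enough reads).")
  }
  if (fd < 0 || fd >= 1 || ad < 0 || ad >= 1) {
    abort("`fd` and `ad` must lie in [0, 1).")
  }
  mode(states) <- "integer"
  if (is.null(colnames(states)) && ncol(states) > 0) {
    colnames(states) <- paste0("M", seq_len(ncol(states)))
  }
  structure(states, fd = fd, ad = ad, truth = truth,
            class = c("mutation_matrix", "matrix", "array"))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix> %d cells x %d mutations (fd = %g, ad = %g)\n",
              nrow(x), ncol(x), attr(x, "fd"), attr(x, "ad")))
  tab <- table(factor(as.vector(x), levels = c(0, 1, 3)))
  cat(sprintf("  states: 0 x %d, 1 x %d, 3 x %d\n", tab[1], tab[2], tab[3]))
  invisible(x)
}
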