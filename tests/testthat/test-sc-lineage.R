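test_that("mutation-matrix construction applies the coverage/frequency/cell cutoffs", {
  calls <- dplyr::bind_rows(
    tibble::tibble(cell = paste0("c", 1:4), mutation = "M1",
                   coverage = c(10, 12, 9, 3),
                   frequency = c(0.85, 0.90, 0.10, 0.5)),
    tibble::tibble(cell = paste0("c", 1:4), mutation = "M2",
                   coverage = 10, frequency = c(0.9, 0.1, 0.1, 0.1)),
    tibble::tibble(cell = paste0("c", 1:4), mutation = "M3",
                   coverage = c(5, 5, 10, 10), frequency = 0.95)
  )
  mat <- build_mutation_matrix(calls)
  # M1: states (1, 1, 0, 3), retained with two presence cells
  expect_true("M1" %in% colnames(mat))
  expect_equal(unname(mat[paste0("c", 1:4), "M1"]), c(1L, 1L, 0L, 3L))
  # M2: one presence cell only -> dropped
  expect_false("M2" %in% colnames(mat))
  # M3: low-coverage cells become state 3, the two covered cells carry it
  expect_equal(unname(mat[, "M3"]), c(3L, 3L, 1L, 1L))

  expect_error(build_mutation_matrix(calls[0, ]), "empty")
  expect_error(build_mutation_matrix(calls, min_frequency = 2), "probability")
  expect_error(mutation_matrix(matrix(2L, 1, 1)), "0.*1.*3")
})

test_that("tree likelihood matches closed-form values under the error model", {
  # noiseless cells at exact path genotypes have probability 1
  tree <- mutation_tree(c(0L, 1L, 2L, 3L))
  mat0 <- simulate_single_cells(tree, 30, fd = 0, ad = 0, missing_rate = 0,
                                seed = 1)
  expect_equal(tree_loglikelihood(tree, mat0), 0)

  # one mutation, one cell observing 1: best attachment gives max(fd, 1-ad)
  fd <- 6.04e-5
  ad <- 0.21545
  m1 <- mutation_matrix(matrix(1L, 1, 1, dimnames = list("c1", "M1")),
                        fd = fd, ad = ad)
  chain <- mutation_tree(0L, "M1")
  expect_equal(tree_loglikelihood(chain, m1), log(1 - ad))
  expect_equal(tree_loglikelihood(chain, m1), -0.2426, tolerance = 1e-3)

  # missing data is uninformative for every tree
  m3 <- mutation_matrix(matrix(3L, 4, 2), fd = fd, ad = ad)
  t1 <- mutation_tree(c(0L, 1L), c("M1", "M2"))
  t2 <- mutation_tree(c(2L, 0L), c("M1", "M2"))
  expect_equal(tree_loglikelihood(t1, m3), 0)
  expect_equal(tree_loglikelihood(t2, m3), 0)

  expect_error(tree_loglikelihood(t1, m1, fd = 1), "< 1")
  expect_error(
    tree_loglikelihood(mutation_tree(0L, "other"), m1),
    "not labeled")
})

test_that("likelihood is invariant to cell order and column order", {
  tree <- random_mutation_tree(4, seed = 2)
  mat <- simulate_single_cells(tree, 25, fd = 1e-4, ad = 0.2,
                               missing_rate = 0.1, seed = 3)
  ll <- tree_loglikelihood(tree, mat)
  perm_cells <- mutation_matrix(unclass(mat)[sample(nrow(mat)), ],
                                fd = attr(mat, "fd"), ad = attr(mat, "ad"))
  expect_equal(tree_loglikelihood(tree, perm_cells), ll)
  perm_cols <- mutation_matrix(unclass(mat)[, c(3, 1, 4, 2)],
                               fd = attr(mat, "fd"), ad = attr(mat, "ad"))
  expect_equal(tree_loglikelihood(tree, perm_cols), ll)
  # sum mode never exceeds max mode
  expect_lte(tree_loglikelihood(tree, mat, attachment = "sum"), ll)
})

test_that("exhaustive search equals the brute-force oracle", {
  for (s in 1:6) {
    tree <- random_mutation_tree(4, seed = 100 + s)
    mat <- simulate_single_cells(tree, 25, fd = 6.04e-5, ad = 0.21545,
                                 missing_rate = 0.05, seed = 200 + s)
    fit <- infer_ml_tree(mat, "exhaustive")
    oracle <- oracle_best_tree(unclass(mat), 6.04e-5, 0.21545)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-9)
    expect_true(any(vapply(oracle$trees, identical,
                           logical(1), y = fit$tree$parent)))
  }
})

test_that("noiseless matrices identify the generating tree exactly", {
  for (s in 1:8) {
    tree <- random_mutation_tree(5, seed = 300 + s)
    mat <- simulate_single_cells(tree, 60, fd = 0, ad = 0, missing_rate = 0,
                                 seed = 400 + s)
    fit <- infer_ml_tree(mat, "exhaustive")
    expect_identical(fit$tree$parent, tree$parent)
    expect_equal(fit$loglik, 0)
  }
})

test_that("MCMC attains the exhaustive optimum and never exceeds it", {
  for (s in 1:4) {
    tree <- random_mutation_tree(5, seed = 500 + s)
    mat <- simulate_single_cells(tree, 50, fd = 1e-4, ad = 0.2,
                                 missing_rate = 0.05, seed = 600 + s)
    fe <- infer_ml_tree(mat, "exhaustive")
    fm <- infer_ml_tree(mat, "mcmc", seed = s, chain_length = 4000)
    expect_lte(fm$loglik, fe$loglik + 1e-9)
    expect_equal(fm$loglik, fe$loglik, tolerance = 1e-6)
  }
  expect_error(infer_ml_tree(mutation_matrix(matrix(1L, 2, 0)), "exhaustive"),
               "zero retained")
})

test_that("identical-support mutations tie and break lexicographically", {
  # two mutations carried by exactly the same cells: both chain orders tie
  D <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  colnames(D) <- c("M1", "M2")
  mat <- mutation_matrix(D, fd = 1e-4, ad = 0.2)
  fit <- infer_ml_tree(mat, "exhaustive")
  expect_gte(fit$n_ties, 2)
  expect_true(length(fit$tied_labels) >= 1)
  expect_true(all(sort(fit$tied_labels[[1]]) == c("M1", "M2")))
  # lexicographic smallest parent vector: M1 under root, M2 under M1
  expect_identical(fit$tree$parent, c(0L, 1L))
})

test_that("trunk ordering follows longitudinal first detection", {
  fit <- list(tree = mutation_tree(c(0L, 1L, 2L), c("B", "A", "C")),
              tied_labels = list(c("A", "B")))
  class(fit) <- "ml_tree_fit"
  traj <- dplyr::bind_rows(
    tibble::tibble(line = "UE3", gene = "A", generation = c(300L, 500L),
                   frequency = c(0.3, 0.8)),
    tibble::tibble(line = "UE3", gene = "B", generation = c(300L, 500L),
                   frequency = c(0.01, 0.6))
  )
  # A first detected at 300, B at 500: the tied pair reorders A before B
  res <- order_trunk_by_generations(fit, traj)
  trunk <- res$tree$labels[syntrophevo:::trunk_path(res$tree$parent)]
  expect_equal(trunk[1:2], c("A", "B"))
  expect_true("swapped" %in% res$decisions$action)

  # no ties: tree unchanged
  fit2 <- fit
  fit2$tied_labels <- list()
  res2 <- order_trunk_by_generations(fit2, traj)
  expect_identical(res2$tree$parent, fit$tree$parent)
  expect_equal(nrow(res2$decisions), 0)

  # tied mutation absent from bulk data: kept, flagged as rare lineage
  traj_missing <- dplyr::filter(traj, gene != "A")
  res3 <- order_trunk_by_generations(fit, traj_missing)
  expect_identical(res3$tree$parent, fit$tree$parent)
  expect_match(res3$decisions$flag[1], "rare/below-detection")
})

test_that("newick serialization is canonical", {
  tree <- mutation_tree(c(0L, 1L, 1L, 0L), c("b", "c", "a", "d"))
  expect_equal(as_newick(tree), "((a,c)b,d);")
  # a linear trunk nests singleton clauses
  chain <- mutation_tree(c(0L, 1L, 2L), c("x", "y", "z"))
  expect_equal(as_newick(chain), "(((z)y)x);")
  # label order within the parent vector does not change the serialization
  relab <- mutation_tree(c(2L, 0L, 2L, 0L), c("c", "b", "a", "d"))
  expect_equal(as_newick(relab), "((a,c)b,d);")
})
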