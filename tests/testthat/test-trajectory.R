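test_that("fixation detection requires a sustained crossing", {
  expect_equal(detect_fixation(c(0.1, 0.6, 0.97, 0.99), c(100, 300, 500, 780)),
               500)
  expect_true(is.na(detect_fixation(c(0.1, 0.5, 0.9), c(100, 300, 500))))
  # transient excursion above threshold does not count
  expect_equal(detect_fixation(c(0.96, 0.4, 0.98), c(1, 2, 3)), 3)
  expect_equal(detect_fixation(
    tibble::tibble(generation = c(100, 300), frequency = c(0.99, 0.98))), 100)
  expect_error(detect_fixation(c(0.5), threshold = 0), "\\(0, 1\\]")
  expect_error(detect_fixation(numeric(0)), "empty")
})

test_that("association statistics count supporting lines per mode", {
  traj <- dplyr::bind_rows(
    tidyr::expand_grid(line = c("L1", "L2", "L3"), gene = "gA",
                       generation = c(100L, 300L)) |>
      dplyr::mutate(frequency = 0.5),
    tidyr::expand_grid(line = c("L2", "L3"), gene = "gB",
                       generation = c(100L, 300L)) |>
      dplyr::mutate(frequency = 0.5)
  )
  expect_equal(association_statistic(traj, "gA", "gB", "co_occurrence", k = 1),
               2)
  expect_equal(association_statistic(traj, "gA", "gB", "co_occurrence", k = 3),
               0)

  fix <- dplyr::bind_rows(
    tibble::tibble(line = "L1", gene = "gA",
                   generation = c(100L, 300L, 500L, 780L),
                   frequency = c(0.1, 0.5, 0.97, 0.99)),
    tibble::tibble(line = "L1", gene = "gB",
                   generation = c(100L, 300L, 500L, 780L),
                   frequency = c(0.2, 0.6, 0.96, 0.98))
  )
  expect_equal(
    association_statistic(fix, "gA", "gB", "simultaneous_fixation"), 1)

  # nested: A detected gen 100 fixes 780; B detected 300 fixes 500
  nest <- dplyr::bind_rows(
    tibble::tibble(line = "L1", gene = "gA",
                   generation = c(100L, 300L, 500L, 780L),
                   frequency = c(0.1, 0.3, 0.6, 0.99)),
    tibble::tibble(line = "L1", gene = "gB",
                   generation = c(100L, 300L, 500L, 780L),
                   frequency = c(0.0, 0.2, 0.97, 0.99))
  )
  expect_equal(association_statistic(nest, "gA", "gB", "nested_fixation"), 1)
  # the reverse direction is not nested
  expect_equal(association_statistic(nest, "gB", "gA", "nested_fixation"), 0)
  expect_error(association_statistic(nest, "gA", "missing", "co_occurrence"),
               "detected")
})

test_that("permutation P values follow (s+1)/(n+1) and its bounds", {
  tr <- enumerable_trajectories()
  res <- permutation_pvalue(tr, "gA", "gB", "co_occurrence", n = 10,
                            seed = 3, k = 1)
  expect_equal(res$p, (res$s + 1) / 11)
  expect_gte(res$p, 1 / 11)
  expect_lte(res$p, 1)

  # s = n gives P = 1: observed statistic 0 is never beaten strictly
  tr0 <- dplyr::bind_rows(
    tibble::tibble(line = "L1", gene = "gA", generation = 100L,
                   frequency = 0.5),
    tibble::tibble(line = "L2", gene = "gB", generation = 100L,
                   frequency = 0.5)
  )
  res0 <- permutation_pvalue(tr0, "gA", "gB", "co_occurrence", n = 50,
                             seed = 1, k = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
  expect_error(permutation_pvalue(tr, "gA", "gB", n = 0), ">= 1")
})

test_that("degenerate matrices fall back to the placement null; exact oracle matches", {
  tr <- enumerable_trajectories()
  p_exact <- exact_association_pvalue(tr, "gA", "gB", "co_occurrence", k = 1)
  expect_equal(p_exact, 1 / 3)
  res <- permutation_pvalue(tr, "gA", "gB", "co_occurrence", n = 4999,
                            seed = 11, k = 1)
  expect_equal(res$null, "placement")
  expect_lt(abs(res$p - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 4999))
  expect_error(
    permutation_pvalue(tr, "gA", "gB", "co_occurrence", n = 10, seed = 1,
                       k = 1, null = "swap"),
    "no checkerboard swaps")
})

test_that("swap null is selected on non-degenerate matrices", {
  tr <- independent_gene_trajectories(4, n_lines = 12, p = 0.5)
  res <- permutation_pvalue(tr, "gA", "gB", "co_occurrence", n = 99,
                            seed = 5, k = 1)
  expect_equal(res$null, "swap")
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
})

test_that("cross-species sweep detection finds the planted interval only", {
  cfg <- sim_config(seed = 13, n_genes = 30, mutation_rate = 4,
                    sweep_spec = list(line = "L02", interval = c(500L, 780L)))
  sim <- simulate_lines(cfg)
  sw <- detect_sweep(sim$trajectories, "L02")
  expect_gt(nrow(sw), 0)
  expect_equal(unique(sw$gen_start), 500)
  expect_equal(unique(sw$gen_end), 780)
  expect_setequal(sw$locus[sw$role == "replaced"], sim$truth$sweep$replaced)
  expect_setequal(sw$locus[sw$role == "novel"], sim$truth$sweep$novel)

  # a lines without the planted sweep yields no record
  other <- detect_sweep(sim$trajectories, "L05")
  expect_equal(nrow(other), 0)
})

test_that("a sweep in a single organism is not called cross-species", {
  gens <- c(100L, 300L, 500L, 780L)
  one_sided <- dplyr::bind_rows(
    tibble::tibble(line = "LX", organism = "Dv_like", gene = "old",
                   generation = gens, frequency = c(0.9, 0.9, 0.9, 0.01)),
    tibble::tibble(line = "LX", organism = "Dv_like", gene = "new",
                   generation = gens, frequency = c(0.0, 0.0, 0.01, 0.9)),
    tibble::tibble(line = "LX", organism = "Mm_like", gene = "steady",
                   generation = gens, frequency = 0.8)
  )
  expect_equal(nrow(detect_sweep(one_sided, "LX")), 0)

  # no locus ever crosses dominance: nothing to replace
  flat <- dplyr::mutate(one_sided, frequency = 0.2)
  expect_equal(nrow(detect_sweep(flat, "LX")), 0)
  expect_error(detect_sweep(one_sided, "missing_line"), "not found")
})
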