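test_that("per-gene G follows 2*O*ln(O/E) with the zero-count convention", {
  expect_equal(gene_gscore(0, 5), 0)
  expect_equal(gene_gscore(4, 4), 0)
  expect_equal(gene_gscore(6, 2), 2 * 6 * log(3))
  expect_equal(gene_gscore(6, 2), 13.18335, tolerance = 1e-5)
  # under-hit genes contribute negative G, as the formula is written
  expect_lt(gene_gscore(1, 3), 0)
  expect_error(gene_gscore(2, 0), "> 0")
  expect_error(gene_gscore(-1, 2), ">= 0")
})

test_that("observed G-scores match hand enumeration on a 2-gene catalog", {
  catalog <- tibble::tibble(gene = c("g1", "g2"), length_bp = c(500, 1500))
  muts <- tibble::tibble(gene = rep("g1", 8), line = paste0("L", 1:8),
                         position = 1:8)
  per <- observed_gscores(muts, catalog)
  expect_equal(per$expected[per$gene == "g1"], 2)
  expect_equal(per$expected[per$gene == "g2"], 6)
  expect_equal(per$gscore[per$gene == "g1"], 2 * 8 * log(4))
  expect_equal(per$gscore[per$gene == "g2"], 0)
  expect_equal(attr(per, "total"), 2 * 8 * log(4))
  expect_equal(attr(per, "total"), sum(per$gscore)) # total additivity

  # single-gene catalog degenerates to O = E = N, total 0
  one <- observed_gscores(muts, catalog[1, ])
  expect_equal(attr(one, "total"), 0)

  # scale invariance: gene lengths only enter through their proportions
  per10 <- observed_gscores(muts,
                            dplyr::mutate(catalog, length_bp = length_bp * 10))
  expect_equal(per10$gscore, per$gscore)
})

test_that("intergenic calls are excluded with a logged count", {
  catalog <- tibble::tibble(gene = c("g1", "g2"), length_bp = c(500, 1500))
  muts <- tibble::tibble(gene = c("g1", "g1", "IG_184033"), position = 1:3)
  per <- observed_gscores(muts, catalog)
  expect_equal(attr(per, "excluded"), 1)
  expect_equal(attr(per, "n_total"), 2)

  syn <- tibble::tibble(gene = c("g1", "g2"),
                        annotation = c("nonsynonymous_coding",
                                       "synonymous_coding"))
  expect_equal(attr(observed_gscores(syn, catalog), "n_total"), 1)
  expect_error(observed_gscores(syn[0, ], catalog), "N_total")
})

test_that("randomization null is seeded, flagged when degenerate, and guarded", {
  catalog <- make_gene_catalog(20, seed = 3)
  n1 <- expected_gscore_null(catalog, 50, n_sims = 200, seed = 11)
  n2 <- expected_gscore_null(catalog, 50, n_sims = 200, seed = 11)
  expect_identical(n1$totals, n2$totals)
  expect_equal(length(n1$totals), 200)
  expect_gt(n1$sigma, 0)
  expect_error(expected_gscore_null(catalog, 0), ">= 1")
  expect_error(expected_gscore_null(catalog, 10, n_sims = 1), ">= 2")

  # intergenic placements dilute gene hits and lower the null mean
  n_inter <- expected_gscore_null(catalog, 50, n_sims = 500, seed = 2,
                                  genome_length = 2 * sum(catalog$length_bp))
  n_tight <- expected_gscore_null(catalog, 50, n_sims = 500, seed = 2)
  expect_lt(abs(n_inter$mu), abs(n_tight$mu) + 100) # both finite
  expect_error(
    expected_gscore_null(catalog, 10, genome_length = 10),
    "smaller than"
  )
})

test_that("parallelism Z-score reproduces the published arithmetic", {
  # printed observed/null summaries for the two partner organisms
  z_dv <- parallelism_zscore(1092.617, 798.19, 14.99)
  expect_equal(z_dv, (1092.617 - 798.19) / 14.99)
  expect_equal(z_dv, 19.63, tolerance = 0.001) # printed value, rounded inputs
  z_mm <- parallelism_zscore(805.02, 564.83, 15.95)
  expect_equal(round(z_mm, 2), 15.06)
  expect_equal(parallelism_zscore(100, 100, 5), 0)
  expect_error(parallelism_zscore(1, 0, 0), "> 0")
})

test_that("gscore_test wires the pieces together with tidy/glance methods", {
  sim <- simulate_lines(sim_config(seed = 5, n_genes = 25, mutation_rate = 5))
  ev <- dplyr::filter(sim$events, organism == "Dv_like")
  cat_a <- dplyr::filter(sim$catalog, organism == "Dv_like")
  fit <- gscore_test(ev, cat_a, n_sims = 300, seed = 2)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(nrow(td), 25)
  expect_equal(gl$g_obs, sum(td$gscore))
  expect_equal(gl$z, (gl$g_obs - gl$null_mean) / gl$null_sd)
  expect_s3_class(autoplot(fit), "ggplot")
})
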