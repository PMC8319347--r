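test_that("simulate_lines is deterministic and honors the zero-rate edge case", {
  cfg <- sim_config(seed = 7, n_genes = 30, mutation_rate = 4)
  s1 <- simulate_lines(cfg)
  s2 <- simulate_lines(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$events, s2$events)

  s0 <- simulate_lines(sim_config(seed = 7, n_genes = 30, mutation_rate = 0))
  expect_equal(nrow(s0$trajectories), 0)
  expect_equal(nrow(s0$events), 0)

  expect_error(sim_config(generations = c(300, 100)), "strictly increasing")
  expect_error(sim_config(fd = 1.5), "probability")
  expect_error(sim_config(dilution_fold = 1), "> 1")
})

test_that("enrichment-1 gene assignment is length-proportional multinomial", {
  counts <- NULL
  lengths <- NULL
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_genes = 25, mutation_rate = 6, n_lines = 8)
    sim <- simulate_lines(cfg)
    ev <- dplyr::filter(sim$events, organism == "Dv_like")
    cat_a <- dplyr::filter(sim$catalog, organism == "Dv_like")
    hit <- table(factor(ev$gene, levels = cat_a$gene))
    if (is.null(counts)) {
      counts <- as.numeric(hit)
      lengths <- cat_a$length_bp
    } else {
      # catalogs differ by seed; accumulate expected counts gene-wise
      counts <- c(counts, as.numeric(hit))
      lengths <- c(lengths, cat_a$length_bp)
    }
  }
  p <- suppressWarnings(chisq.test(counts, p = lengths / sum(lengths)))$p.value
  expect_gt(p, 0.001)
})

test_that("trajectories reach sustained fixation for selected events", {
  sim <- simulate_lines(sim_config(seed = 3, n_genes = 40, mutation_rate = 6))
  sel <- dplyr::filter(sim$events, selected, role == "background",
                       appearance_generation <= 300)
  expect_gt(nrow(sel), 0)
  fixed <- vapply(seq_len(nrow(sel)), function(i) {
    tr <- dplyr::filter(sim$trajectories, line == sel$line[i],
                        gene == sel$gene[i])
    !is.na(detect_fixation(tr$frequency, tr$generation))
  }, logical(1))
  expect_gt(mean(fixed), 0.9)
})

test_that("caller simulator honors the zero-error and total-dropout cases", {
  truth <- tibble::tibble(chrom = "genome", position = 1:30 * 10L, ref = "A",
                          alt = "T", frequency = runif(30, 0.3, 1))
  prof0 <- tibble::tibble(caller = c("a", "b", "c"), fp_rate = 0, fn_rate = 0,
                          freq_sd = 0)
  calls <- simulate_caller_outputs(truth, prof0, decoy_sites = 50, seed = 1)
  for (cl in c("a", "b", "c")) {
    sub <- dplyr::filter(calls, caller == cl)
    expect_equal(sort(sub$position), sort(truth$position))
    expect_equal(sub$frequency[order(sub$position)],
                 truth$frequency[order(truth$position)])
  }

  prof1 <- tibble::tibble(caller = c("dead", "live"), fp_rate = 0,
                          fn_rate = c(1, 0), freq_sd = 0)
  calls1 <- simulate_caller_outputs(truth, prof1, decoy_sites = 0, seed = 1)
  expect_equal(sum(calls1$caller == "dead"), 0)
  expect_equal(sum(calls1$caller == "live"), 30)

  expect_error(simulate_caller_outputs(truth, prof0[1, ]), ">= 2")
  expect_error(
    simulate_caller_outputs(truth, tibble::tibble(caller = c("a", "b"),
                                                  fp_rate = c(2, 0),
                                                  fn_rate = 0)),
    "probability")
})

test_that("spurious call counts follow the binomial error model", {
  truth <- tibble::tibble(chrom = "genome", position = 1:100 * 10L, ref = "A",
                          alt = "T", frequency = 0.5)
  prof <- tibble::tibble(caller = c("a", "b"), fp_rate = 0.05, fn_rate = 0,
                         freq_sd = 0)
  fps <- vapply(1:20, function(s) {
    calls <- simulate_caller_outputs(truth, prof, decoy_sites = 1000, seed = s)
    sum(calls$caller == "a" & !calls$position %in% truth$position)
  }, numeric(1))
  # Binomial(1000, 0.05): mean 50, sd ~ 6.9; the 20-seed mean has se ~ 1.54
  expect_lt(abs(mean(fps) - 50), 3 * sqrt(1000 * 0.05 * 0.95 / 20))
})

test_that("single-cell simulator reproduces the fd/ad/missing error model", {
  tree <- random_mutation_tree(4, seed = 5)
  mat0 <- simulate_single_cells(tree, 50, fd = 0, ad = 0, missing_rate = 0,
                                seed = 9)
  G <- syntrophevo:::tree_genotypes(tree)
  truth <- attr(mat0, "truth")
  expect_equal(unclass(mat0), G[truth + 1, , drop = FALSE],
               ignore_attr = TRUE)

  mat3 <- simulate_single_cells(tree, 20, missing_rate = 1, seed = 2)
  expect_true(all(unclass(mat3) == 3L))

  # empirical dropout at a mutation carried by many cells
  tree1 <- mutation_tree(0L, "M1")
  mat <- simulate_single_cells(tree1, 2000, fd = 0, ad = 0.2,
                               missing_rate = 0, seed = 4)
  carriers <- attr(mat, "truth") == 1L
  n <- sum(carriers)
  drop_rate <- mean(mat[carriers, 1] == 0L)
  expect_lt(abs(drop_rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  expect_error(simulate_single_cells(tree, 10, fd = -0.1), "probability")
})

test_that("growth plate honors the permissive-density switch and asymptote", {
  cfg <- sim_config(seed = 21, noise_sd = 0.003)
  low <- simulate_growth_plate(cfg, n_dilutions = 5,
                               min_permissive_density = 1e-6)
  prof <- minimal_permissive_density(low)$profile
  expect_true(all(prof$n_grew == prof$n_wells))

  high <- simulate_growth_plate(cfg, n_dilutions = 5,
                                min_permissive_density = 1)
  expect_true(is.na(minimal_permissive_density(high)$minimal_density))

  gp <- cfg$growth_params
  expect_equal(logistic_od(1e6, gp$mu, gp$lambda, gp$A), gp$A,
               tolerance = 1e-6)
  expect_error(simulate_growth_plate(cfg, n_dilutions = 1), ">= 2")
})

test_that("pairing simulator plants the requested interaction mode", {
  for (mode in c("additive", "synergistic", "antagonistic")) {
    p <- simulate_pairings(mode = mode, effect_size = 0.15, noise_sd = 0,
                           seed = 3)
    rep_ <- synergy_report(p)
    planted <- switch(mode, additive = 0, synergistic = 15,
                      antagonistic = -15)
    expect_equal(rep_$eob, rep(planted, 2), tolerance = 1e-8)
    expect_true(all(rep_$classification == mode))
  }
  expect_error(simulate_pairings(mode = "weird"), "arg")
  expect_error(simulate_pairings(f_dv_true = 1.2), "\\[0, 1\\)")
})

test_that("noisy pairing EOB covers the planted value at 3 propagated sd", {
  hits <- vapply(1:100, function(s) {
    p <- simulate_pairings(mode = "synergistic", effect_size = 0.15,
                           noise_sd = 0.05, n_replicates = 6, seed = s)
    r <- synergy_report(p)[1, ]
    abs(r$eob - 15) <= 3 * r$sd_eob
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
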