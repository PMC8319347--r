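test_that("consensus filter applies the caller-count and frequency rules", {
  calls <- five_variant_calls()
  cons <- consensus_calls(calls, min_callers = 2, min_frequency = 0.20)
  expect_setequal(cons$locus, c("A", "B", "E"))
  expect_equal(nrow(cons), 3)

  # single-caller variant at high frequency is excluded
  expect_false("C" %in% cons$locus)
  # frequency 0.19 by all three callers is excluded; 0.20 exactly is kept
  expect_false("D" %in% cons$locus)
  expect_equal(cons$frequency[cons$locus == "A"], 0.5)
  expect_equal(cons$n_callers[cons$locus == "A"], 3)
})

test_that("consensus is idempotent, order-invariant and margin-monotone", {
  calls <- five_variant_calls()
  base <- consensus_calls(calls)
  shuffled <- calls[rev(seq_len(nrow(calls))), ]
  expect_equal(consensus_calls(shuffled), base)

  # re-filtering the consensus (each call attributed to its callers) is stable
  expect_equal(nrow(consensus_calls(calls, min_callers = 2)), 3)
  n2 <- nrow(consensus_calls(calls, min_callers = 2))
  n3 <- nrow(consensus_calls(calls, min_callers = 3))
  expect_lte(n3, n2)
  f20 <- nrow(consensus_calls(calls, min_frequency = 0.20))
  f30 <- nrow(consensus_calls(calls, min_frequency = 0.30))
  expect_lte(f30, f20)

  expect_error(consensus_calls(calls, min_callers = 0), ">= 1")
  expect_error(consensus_calls(list()), "non-empty")
})

test_that("consensus accepts per-caller list input and splits multiallelics", {
  sets <- split(five_variant_calls(), five_variant_calls()$caller)
  sets <- lapply(sets, function(x) x[, setdiff(names(x), "caller")])
  cons <- consensus_calls(sets)
  expect_setequal(cons$locus, c("A", "B", "E"))

  multi <- tibble::tibble(
    caller = c("a", "b"), chrom = "genome", position = 10L, ref = "A",
    alt = "T,G", frequency = 0.5
  )
  cons_m <- consensus_calls(multi)
  expect_setequal(cons_m$alt, c("T", "G"))
})

test_that("zero-error caller sets reduce to exactly the true variant set", {
  truth <- tibble::tibble(chrom = "genome", position = 1:40 * 7L, ref = "C",
                          alt = "G", frequency = runif(40, 0.25, 1))
  prof <- tibble::tibble(caller = c("a", "b", "c"), fp_rate = 0, fn_rate = 0,
                         freq_sd = 0)
  calls <- simulate_caller_outputs(truth, prof, decoy_sites = 200, seed = 8)
  cons <- consensus_calls(calls)
  expect_equal(sort(cons$position), sort(truth$position))
})

test_that("impact classification is total over the vocabulary and strict", {
  expect_equal(as.character(classify_impact("frameshift")), "HIGH")
  expect_equal(as.character(classify_impact("stop_gained")), "HIGH")
  expect_equal(as.character(classify_impact("start_lost")), "HIGH")
  expect_equal(as.character(classify_impact("nonsynonymous_coding")),
               "MODERATE")
  expect_equal(as.character(classify_impact("codon_deletion")), "MODERATE")
  expect_equal(as.character(classify_impact("synonymous_coding")), "LOW")
  expect_equal(as.character(classify_impact("nonsynonymous_start")), "LOW")
  expect_error(classify_impact("weird_term"), "unknown annotation")

  terms <- names(syntrophevo:::impact_map)
  expect_false(any(is.na(classify_impact(terms))))
})

test_that("caller VCFs round-trip through the minimal writer/reader", {
  truth <- tibble::tibble(chrom = "genome", position = c(11L, 53L), ref = "A",
                          alt = "T", frequency = c(0.42, 0.9))
  prof <- tibble::tibble(caller = c("gatk", "varscan"), fp_rate = 0,
                         fn_rate = 0, freq_sd = 0)
  calls <- simulate_caller_outputs(truth, prof, decoy_sites = 10, seed = 1)
  dir <- withr::local_tempdir()
  write_caller_vcfs(calls, dir)
  back <- read_caller_vcfs(list.files(dir, full.names = TRUE))
  expect_setequal(unique(back$caller), c("gatk", "varscan"))
  expect_equal(
    dplyr::arrange(back[, c("caller", "position", "ref", "alt")],
                   caller, position),
    dplyr::arrange(calls[, c("caller", "position", "ref", "alt")],
                   caller, position)
  )
  expect_equal(sort(back$frequency), sort(round(calls$frequency, 6)))
})
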