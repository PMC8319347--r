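#' Merge per-caller variant calls into a consensus set
#'
#' Applies the two population-sequencing filters used throughout the
#' pipeline: a variant is retained when it is reported by at least
#' `min_callers` independent callers (same replicon, position and alternate
#' allele) and its consensus frequency — the median across reporting
#' callers — is at least `min_frequency` (defaults: 2 callers, 20%).
#' Multiallelic records are split before matching.
#'
#' @param calls Either a single tibble of calls carrying a `caller` column,
#'   or a named list of per-caller tibbles. Required columns: `position`,
#'   `alt`, `frequency`; `chrom`, `ref`, `locus` and any metadata columns are
#'   carried through when present.
#' @param min_callers Minimum number of callers reporting the variant.
#' @param min_frequency Minimum consensus (median) frequency.
#'
#' @return Tibble of consensus calls with `frequency` (median), `n_callers`
#'   and `callers` columns, ordered by replicon and position.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   caller = c("gatk", "varscan", "bcftools", "gatk"),
#'   position = c(100, 100, 100, 200), ref = "A",
#'   alt = c("T", "T", "T", "G"), frequency = c(0.5, 0.55, 0.48, 0.9)
#' )
#' consensus_calls(calls)
consensus_calls <- function(calls, min_callers = 2L, min_frequency = 0.20) {
  if (min_callers < 1) abort("`min_callers` must be >= 1.")
  check_probability(min_frequency, "min_frequency")
  if (is.data.frame(calls)) {
    check_columns(calls, c("caller", "position", "alt", "frequency"), "calls")
    df <- as_tibble(calls)
  } else if (is.list(calls) && length(calls) > 0) {
    nm <- names(calls) %||% paste0("caller", seq_along(calls))
    df <- bind_rows(imap(calls, function(x, n) mutate(as_tibble(x), caller = n)))
    check_columns(df, c("position", "alt", "frequency"), "calls")
  } else {
    abort("`calls` must be a data frame or a non-empty list of data frames.")
  }
  if (nrow(df) == 0) abort("`calls` contains no variant records.")
  if (length(unique(df$caller)) < min_callers) {
    abort(sprintf("need call sets from >= %d callers.", min_callers))
  }

  if (!"chrom" %in% names(df)) df$chrom <- "genome"
  if (!"ref" %in% names(df)) df$ref <- NA_character_
  df <- separate_rows(df, "alt", sep = ",")

  meta_cols <- setdiff(names(df),
                       c("caller", "chrom", "position", "ref", "alt", "frequency"))
  out <- df %>%
    distinct(.data$caller, .data$chrom, .data$position, .data$alt,
             .keep_all = TRUE) %>%
    group_by(.data$chrom, .data$position, .data$alt) %>%
    summarise(
      ref = first(.data$ref),
      frequency = median(.data$frequency),
      n_callers = length(unique(.data$caller)),
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      across(all_of(meta_cols), first),
      .groups = "drop"
    ) %>%
    filter(.data$n_callers >= min_callers, .data$frequency >= min_frequency) %>%
    arrange(.data$chrom, .data$position, .data$alt)
  select(out, "chrom", "position", "ref", "alt", "frequency",
         "n_callers", "callers", all_of(meta_cols))
}

impact_map <- c(
  frameshift = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
  start_lost = "HIGH", start_gained = "HIGH",
  codon_deletion = "MODERATE", codon_insertion_or_change = "MODERATE",
  nonsynonymous_coding = "MODERATE",
  synonymous_coding = "LOW", nonsynonymous_start = "LOW"
)

#' Classify mutation impact from its annotation term
#'
#' Start/stop codon gains and losses and frameshifts are HIGH impact; codon
#' deletions, insertions or changes and nonsynonymous coding changes are
#' MODERATE; synonymous coding and nonsynonymous start-codon changes are LOW.
#' Unknown terms are an error, never a silent default.
#'
#' @param annotation Character vector of controlled annotation terms.
#' @return Factor with levels HIGH, MODERATE, LOW.
#' @export
#' @examples
#' classify_impact(c("frameshift", "nonsynonymous_coding", "synonymous_coding"))
classify_impact <- function(annotation) {
  unknown <- setdiff(unique(annotation), names(impact_map))
  if (length(unknown) > 0) {
    abort(sprintf("unknown annotation term(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  factor(unname(impact_map[annotation]), levels = c("HIGH", "MODERATE", "LOW"))
}

#' Simulate per-caller variant call sets with caller-specific error
#'
#' Each caller reports the true variant set minus false-negative dropouts,
#' plus spurious calls drawn from a decoy site space, with frequencies
#' jittered by Gaussian noise. A fixture generator for testing the consensus
#' filter.
#'
#' @param true_calls Tibble of true variants (columns `position`, `alt`;
#'   `chrom`, `ref`, `frequency` and metadata carried through).
#' @param caller_profiles Tibble with columns `caller`, `fp_rate`, `fn_rate`
#'   and optionally `freq_sd` (default 0.02). `fp_rate` is the per-decoy-site
#'   probability of a spurious call.
#' @param decoy_sites Number of decoy sites available for false positives.
#' @param seed Integer seed.
#'
#' @return Tibble of calls across callers (one row per caller x variant).
#' @export
simulate_caller_outputs <- function(true_calls, caller_profiles,
                                    decoy_sites = 1000L, seed = 1L) {
  check_columns(caller_profiles, c("caller", "fp_rate", "fn_rate"),
                "caller_profiles")
  if (nrow(caller_profiles) < 2) abort("need >= 2 caller profiles.")
  check_probability(caller_profiles$fp_rate, "fp_rate")
  check_probability(caller_profiles$fn_rate, "fn_rate")
  if (!"freq_sd" %in% names(caller_profiles)) caller_profiles$freq_sd <- 0.02
  true_calls <- as_tibble(true_calls)
  check_columns(true_calls, c("position", "alt"), "true_calls")
  if (!"chrom" %in% names(true_calls)) true_calls$chrom <- "genome"
  if (!"ref" %in% names(true_calls)) true_calls$ref <- "N"
  if (!"frequency" %in% names(true_calls)) true_calls$frequency <- 1

  # Decoy sites live beyond the true positions so they never collide.
  decoy_start <- if (nrow(true_calls)) max(true_calls$position) + 1L else 1L
  decoy_pos <- decoy_start + seq_len(decoy_sites) - 1L

  with_seed(seed, {
    per_caller <- pmap(caller_profiles, function(caller, fp_rate, fn_rate,
                                                 freq_sd, ...) {
      kept <- true_calls[runif(nrow(true_calls)) >= fn_rate, , drop = FALSE]
      if (nrow(kept)) {
        kept$frequency <- clamp(kept$frequency + rnorm(nrow(kept), 0, freq_sd),
                                0.01, 1)
      }
      fp_idx <- which(runif(decoy_sites) < fp_rate)
      fps <- tibble(
        chrom = "genome",
        position = decoy_pos[fp_idx],
        ref = sample(c("A", "C", "G", "T"), length(fp_idx), replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), length(fp_idx), replace = TRUE),
        frequency = runif(length(fp_idx), 0.05, 0.6)
      )
      mutate(bind_rows(kept, fps), caller = caller)
    })
    arrange(bind_rows(per_caller), .data$caller, .data$chrom, .data$position)
  })
}
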