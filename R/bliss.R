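#' Fractional effect of an evolved pairing relative to the ancestral pair
#'
#' Converts a raw growth-rate or yield measurement into a fractional effect.
#' `relative_to_baseline` is `(v_pair - v_baseline) / v_baseline`;
#' `relative_to_full` rescales by the fully-evolved pairing instead:
#' `(v_pair - v_baseline) / (v_full - v_baseline)`. Values outside `[0, 1]`
#' are clamped (the Bliss model needs fractions) and flagged via the
#' `clamped` attribute.
#'
#' @param v_pair Measured value of the pairing.
#' @param v_baseline Ancestral x ancestral value (> 0).
#' @param normalization `"relative_to_baseline"` or `"relative_to_full"`.
#' @param v_full Fully-evolved pairing value (required for
#'   `relative_to_full`; must exceed `v_baseline`).
#' @return Fraction(s) in `[0, 1]` with logical attribute `clamped`.
#' @export
#' @examples
#' fractional_effect(1.5, 1.0) # 0.5
fractional_effect <- function(v_pair, v_baseline,
                              normalization = c("relative_to_baseline",
                                                "relative_to_full"),
                              v_full = NULL) {
  normalization <- match.arg(normalization)
  if (any(v_baseline <= 0)) abort("`v_baseline` must be > 0.")
  f <- if (normalization == "relative_to_baseline") {
    (v_pair - v_baseline) / v_baseline
  } else {
    if (is.null(v_full)) abort("`v_full` is required for relative_to_full.")
    if (any(v_full <= v_baseline)) abort("`v_full` must exceed `v_baseline`.")
    (v_pair - v_baseline) / (v_full - v_baseline)
  }
  out <- clamp(f)
  attr(out, "clamped") <- f < 0 | f > 1
  out
}

#' Bliss-independence expected fractional effect
#'
#' `f_DvMm = 1 - (1 - f_Dv)(1 - f_Mm) = f_Dv + f_Mm - f_Dv * f_Mm`; the
#' expected combined effect when the two partners' improvements act
#' independently.
#'
#' @param f_dv,f_mm Fractional effects in `[0, 1]`.
#' @return Expected combined fraction.
#' @export
#' @examples
#' bliss_expected(0.5, 0.5) # 0.75
bliss_expected <- function(f_dv, f_mm) {
  check_probability(f_dv, "f_dv")
  check_probability(f_mm, "f_mm")
  f_dv + f_mm - f_dv * f_mm
}

#' Excess over Bliss with first-order error propagation
#'
#' `EOB = (f_z - f_DvMm) * 100`, where `f_z` is the measured fractional
#' effect of the fully-evolved pairing and `f_DvMm` the Bliss expectation
#' from the single-partner effects. The standard deviation is propagated to
#' first order assuming independent measurements:
#' `sd(f_DvMm)^2 = (1 - f_Mm)^2 sd(f_Dv)^2 + (1 - f_Dv)^2 sd(f_Mm)^2` and
#' `sd(EOB) = 100 * sqrt(sd(f_z)^2 + sd(f_DvMm)^2)`. A pairing is additive
#' when `|EOB|` is within `additive_band` propagated standard deviations of
#' zero (zero-sd measurements use a 1e-8 absolute tolerance), synergistic
#' when the EOB is positive beyond the band, antagonistic when negative.
#'
#' @param f_z Measured combined fractional effect.
#' @param f_dv,f_mm Single-partner fractional effects.
#' @param sd_fz,sd_fdv,sd_fmm Standard deviations (>= 0) of the fractions.
#' @param additive_band Half-width of the additive band in units of
#'   `sd(EOB)` (default 2).
#' @return One-row tibble: `f_dv`, `f_mm`, `f_z`, `f_dvmm`, `eob`, `sd_eob`,
#'   `classification`.
#' @export
#' @examples
#' excess_over_bliss(0.9, 0.5, 0.5) # EOB = 15, synergistic
excess_over_bliss <- function(f_z, f_dv, f_mm, sd_fz = 0, sd_fdv = 0,
                              sd_fmm = 0, additive_band = 2) {
  if (any(c(sd_fz, sd_fdv, sd_fmm) < 0)) abort("sds must be >= 0.")
  f_dvmm <- bliss_expected(f_dv, f_mm)
  eob <- (f_z - f_dvmm) * 100
  sd_dvmm2 <- (1 - f_mm)^2 * sd_fdv^2 + (1 - f_dv)^2 * sd_fmm^2
  sd_eob <- 100 * sqrt(sd_fz^2 + sd_dvmm2)
  classification <- dplyr::case_when(
    sd_eob == 0 & abs(eob) <= 1e-8 ~ "additive",
    sd_eob > 0 & abs(eob) <= additive_band * sd_eob ~ "additive",
    eob > 0 ~ "synergistic",
    TRUE ~ "antagonistic"
  )
  tibble(f_dv = f_dv, f_mm = f_mm, f_z = f_z, f_dvmm = f_dvmm,
         eob = eob, sd_eob = sd_eob, classification = classification)
}

#' Synergy report from replicate pairing measurements
#'
#' Summarises a replicate-level pairing table (the 2x2 ancestral/evolved
#' design: AcAc, EvAc, AcEv, EvEv) into fractional effects with first-order
#' standard deviations, then scores Excess over Bliss per metric.
#' Fraction sds are propagated from replicate means and sds of the raw
#' measurements (independent ratios, delta method).
#'
#' @param pairings Tibble with columns `pairing` (AcAc, EvAc, AcEv, EvEv),
#'   `metric`, `replicate`, `value`.
#' @param normalization Passed to [fractional_effect()] (full mode uses the
#'   EvEv mean as `v_full`).
#' @param additive_band Passed to [excess_over_bliss()].
#' @return Tibble, one row per metric, as from [excess_over_bliss()] plus a
#'   `metric` column.
#' @export
synergy_report <- function(pairings,
                           normalization = c("relative_to_baseline",
                                             "relative_to_full"),
                           additive_band = 2) {
  normalization <- match.arg(normalization)
  check_columns(pairings, c("pairing", "metric", "replicate", "value"),
                "pairings")
  need <- c("AcAc", "EvAc", "AcEv", "EvEv")
  missing <- setdiff(need, unique(pairings$pairing))
  if (length(missing)) {
    abort(sprintf("missing pairing level(s): %s", paste(missing, collapse = ", ")))
  }

  stats <- pairings %>%
    group_by(.data$metric, .data$pairing) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n = n(), .groups = "drop")
  if (any(stats$n < 2)) abort("every pairing needs >= 2 replicates.")

  per_metric <- stats %>%
    group_by(.data$metric) %>%
    dplyr::group_map(function(df, key) {
      g <- function(p, col) df[[col]][df$pairing == p]
      v0 <- g("AcAc", "mean"); s0 <- g("AcAc", "sd")
      frac <- function(p) {
        v <- g(p, "mean"); s <- g(p, "sd")
        f <- (v - v0) / v0
        # delta method for the ratio, independent numerator/denominator
        sdf <- sqrt(s^2 / v0^2 + v^2 * s0^2 / v0^4)
        list(f = clamp(f), sd = sdf)
      }
      fdv <- frac("EvAc"); fmm <- frac("AcEv"); fz <- frac("EvEv")
      mutate(
        excess_over_bliss(fz$f, fdv$f, fmm$f, fz$sd, fdv$sd, fmm$sd,
                          additive_band = additive_band),
        metric = key$metric, normalization = normalization
      )
    }) %>%
    bind_rows()
  per_metric
}

#' Simulate replicate pairing measurements with a planted interaction mode
#'
#' Generates the 2x2 clonal-pairing design (ancestral/evolved for each
#' partner) for growth rate and yield. Single-partner pairings improve on
#' the ancestral baseline by the planted fractional effects; the fully
#' evolved pairing's fractional effect equals the Bliss expectation
#' (additive), exceeds it by `effect_size` (synergistic) or falls short of
#' it by `effect_size` (antagonistic). Replicate noise is Gaussian on the
#' fractional scale.
#'
#' @param base_rate,base_yield Ancestral growth rate (1/h) and yield (OD).
#' @param f_dv_true,f_mm_true Planted single-partner fractional effects in
#'   `[0, 1)`.
#' @param mode `"additive"`, `"synergistic"` or `"antagonistic"`.
#' @param effect_size Fractional departure from the Bliss expectation.
#' @param n_replicates Replicates per pairing (>= 2).
#' @param noise_sd Replicate noise sd on the fractional scale.
#' @param seed Integer seed.
#' @return Tibble (pairing, metric, replicate, value) with a `truth`
#'   attribute recording the planted fractions, mode and EOB (x100).
#' @export
simulate_pairings <- function(base_rate = 0.06, base_yield = 0.4,
                              f_dv_true = 0.3, f_mm_true = 0.25,
                              mode = c("additive", "synergistic",
                                       "antagonistic"),
                              effect_size = 0.15, n_replicates = 4L,
                              noise_sd = 0.02, seed = 1L) {
  mode <- match.arg(mode)
  if (f_dv_true < 0 || f_dv_true >= 1 || f_mm_true < 0 || f_mm_true >= 1) {
    abort("planted fractions must lie in [0, 1).")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  f_bliss <- bliss_expected(f_dv_true, f_mm_true)
  f_z <- switch(mode,
    additive = f_bliss,
    synergistic = f_bliss + effect_size,
    antagonistic = f_bliss - effect_size
  )

  bases <- c(growth_rate = base_rate, yield = base_yield)
  fracs <- c(AcAc = 0, EvAc = f_dv_true, AcEv = f_mm_true, EvEv = f_z)
  grid <- expand_grid(pairing = names(fracs), metric = names(bases),
                      replicate = seq_len(n_replicates))
  out <- with_seed(seed, {
    mutate(grid,
           value = bases[.data$metric] *
             (1 + fracs[.data$pairing] +
                rnorm(nrow(grid), 0, noise_sd)))
  })
  attr(out, "truth") <- list(mode = mode, f_dv = f_dv_true, f_mm = f_mm_true,
                             f_z = f_z, eob = (f_z - f_bliss) * 100)
  out
}
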