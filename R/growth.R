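#' Parametric growth-curve models
#'
#' Modified logistic and Gompertz parameterizations in terms of the maximum
#' growth rate `mu` (OD/h), lag time `lambda` (h) and carrying capacity `A`
#' (OD), the standard reparameterizations used for microbial growth-curve
#' analysis:
#' * logistic: `A / (1 + exp(4 * mu * (lambda - t) / A + 2))`
#' * Gompertz: `A * exp(-exp(mu * e * (lambda - t) / A + 1))`
#'
#' @param t Time (hours).
#' @param mu Maximum growth rate (OD/h).
#' @param lambda Lag time (h).
#' @param A Carrying capacity (OD).
#' @return OD values.
#' @export
logistic_od <- function(t, mu, lambda, A) {
  A / (1 + exp(4 * mu * (lambda - t) / A + 2))
}

#' @rdname logistic_od
#' @export
gompertz_od <- function(t, mu, lambda, A) {
  A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1))
}

#' Fit a growth curve and call growth
#'
#' Estimates (`mu`, `lambda`, `A`) by bounded Levenberg-Marquardt least
#' squares for the logistic and/or Gompertz model and selects the better
#' model by small-sample-corrected AIC (ties go to the logistic). A well is
#' called as growing when its OD rises at least `growth_threshold` above
#' baseline for three or more consecutive readings; wells that fail the
#' call, or whose fits do not converge, return `grew = FALSE` with a
#' diagnostic rather than an error. The baseline is estimated as the mean of
#' the three lowest readings unless given.
#'
#' @param curve Tibble with `time` (hours, strictly increasing) and `od`
#'   columns; at least 5 points.
#' @param models Subset of `c("logistic", "gompertz")`.
#' @param growth_threshold OD rise above baseline that counts as growth
#'   (default 0.05).
#' @param baseline Optional fixed baseline OD.
#' @return Object of class `growth_fit` with [tidy()]/[glance()] methods.
#' @export
#' @examples
#' tt <- seq(0, 48, by = 1)
#' fit <- fit_growth(tibble::tibble(time = tt, od = logistic_od(tt, 0.2, 5, 1)))
#' glance(fit)
fit_growth <- function(curve, models = c("logistic", "gompertz"),
                       growth_threshold = 0.05, baseline = NULL) {
  check_columns(curve, c("time", "od"), "curve")
  models <- match.arg(models, several.ok = TRUE)
  t <- curve$time
  y <- curve$od
  if (length(t) < 5) abort("need at least 5 time points to fit.")
  if (any(diff(t) <= 0)) abort("`time` must be strictly increasing.")
  if (any(y < 0)) abort("`od` must be >= 0.")

  baseline_est <- baseline %||% mean(sort(y)[1:3])
  grew <- sustained_rise(y, baseline_est, growth_threshold)
  out_baseline <- baseline_est
  out <- list(grew = grew, baseline = baseline_est, data = as_tibble(curve),
              growth_threshold = growth_threshold, model = NA_character_,
              mu = NA_real_, lambda = NA_real_, A = NA_real_,
              sigma = NA_real_, aicc = c(logistic = NA_real_,
                                         gompertz = NA_real_),
              diagnostic = NA_character_)
  if (!grew) {
    out$diagnostic <- "no sustained OD rise above threshold"
    return(structure(out, class = "growth_fit"))
  }

  # With an unknown baseline, fit it as a free offset; a fixed baseline is
  # subtracted before the three-parameter fit.
  free_baseline <- is.null(baseline)
  yy <- if (free_baseline) y else y - baseline
  fits <- list()
  for (mod in models) {
    fits[[mod]] <- try_growth_fit(t, yy, mod, free_baseline, baseline_est)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    out$grew <- FALSE
    out$diagnostic <- "model fitting failed to converge"
    return(structure(out, class = "growth_fit"))
  }

  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  out$aicc[names(aiccs)] <- aiccs
  # ties (within 1e-8) resolve to logistic by the names() ordering below
  ordered <- c("logistic", "gompertz")
  ordered <- ordered[ordered %in% names(aiccs)]
  best <- ordered[which.min(aiccs[ordered] - c(1e-8, 0)[seq_along(ordered)])]
  f <- fits[[best]]
  if (f$A - 0 < growth_threshold) {
    out$grew <- FALSE
    out$diagnostic <- "fitted amplitude below growth threshold"
    return(structure(out, class = "growth_fit"))
  }
  out$model <- best
  out$mu <- f$mu
  out$lambda <- f$lambda
  out$A <- f$A
  out$sigma <- f$sigma
  if (!is.null(f$baseline)) out$baseline <- f$baseline
  structure(out, class = "growth_fit")
}

sustained_rise <- function(y, baseline, threshold, run = 3L) {
  above <- y - baseline >= threshold
  r <- rle(above)
  any(r$values & r$lengths >= run)
}

try_growth_fit <- function(t, y, model, free_baseline = FALSE,
                           baseline_est = 0) {
  fun <- if (model == "logistic") logistic_od else gompertz_od
  # data-driven starts: amplitude from the max OD, slope from the steepest
  # finite difference, lag from that tangent's baseline intercept
  b0 <- if (free_baseline) baseline_est else 0
  A0 <- max(y) - b0
  slopes <- diff(y) / diff(t)
  i <- which.max(slopes)
  mu0 <- max(slopes[i], 1e-4)
  tm <- (t[i] + t[i + 1]) / 2
  ym <- (y[i] + y[i + 1]) / 2 - b0
  lam0 <- tm - ym / mu0
  span <- diff(range(t))

  starts <- list(
    c(mu = mu0, lambda = lam0, A = A0),
    c(mu = mu0 * 2, lambda = max(lam0, 0.1), A = A0 * 1.1),
    c(mu = mu0 / 2, lambda = min(t) + span / 4, A = A0)
  )
  for (st in starts) {
    fit <- tryCatch({
      if (free_baseline) {
        minpack.lm::nlsLM(
          y ~ b + fun(t, mu, lambda, A),
          start = c(as.list(st), list(b = b0)),
          lower = c(mu = 1e-6, lambda = min(t) - span, A = 1e-6, b = 0),
          upper = c(mu = Inf, lambda = max(t), A = 10 * A0 + 1,
                    b = max(y)),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      } else {
        minpack.lm::nlsLM(
          y ~ fun(t, mu, lambda, A),
          start = as.list(st),
          lower = c(mu = 1e-6, lambda = min(t) - span, A = 1e-6),
          upper = c(mu = Inf, lambda = max(t), A = 10 * A0 + 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        )
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      n <- length(y)
      k <- length(cf) + 1 # curve parameters + residual variance
      aicc <- AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
      return(list(mu = unname(cf["mu"]), lambda = unname(cf["lambda"]),
                  A = unname(cf["A"]), sigma = sqrt(mean(resid(fit)^2)),
                  baseline = if (free_baseline) unname(cf["b"]) else NULL,
                  aicc = aicc))
    }
  }
  NULL
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>\n")
  if (x$grew) {
    cat(sprintf("  %s fit: mu = %.4f OD/h, lambda = %.2f h, A = %.4f OD\n",
                x$model, x$mu, x$lambda, x$A))
  } else {
    cat(sprintf("  no growth (%s)\n", x$diagnostic))
  }
  invisible(x)
}

#' @rdname fit_growth
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("mu", "lambda", "A"),
         estimate = c(x$mu, x$lambda, x$A),
         unit = c("OD/h", "h", "OD"))
}

#' @rdname fit_growth
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(model = x$model, mu = x$mu, lambda = x$lambda, A = x$A,
         sigma = x$sigma, grew = x$grew, baseline = x$baseline,
         diagnostic = x$diagnostic)
}

#' @rdname fit_growth
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$time, y = .data$od)) +
    geom_point(size = 0.8) +
    labs(x = "time (h)", y = "OD600")
  if (object$grew) {
    fun <- if (object$model == "logistic") logistic_od else gompertz_od
    tt <- seq(min(object$data$time), max(object$data$time), length.out = 200)
    fitted_df <- tibble(time = tt, od = object$baseline +
                          fun(tt, object$mu, object$lambda, object$A))
    p <- p + geom_line(data = fitted_df, color = "firebrick")
  }
  p
}

#' Simulate a dilution-series growth plate
#'
#' Builds a 1.5-fold (configurable) dilution series with `n_replicates`
#' wells per density plus one column of blank wells. Wells seeded at or
#' above `min_permissive_density` grow along the configured logistic curve
#' (starting from their seeding density) with Gaussian OD noise truncated at
#' zero; wells below it, and blanks, stay flat at baseline plus noise.
#'
#' @param config A [sim_config()] (growth parameters, noise, dilution fold,
#'   seed).
#' @param n_dilutions Number of dilution steps (>= 2).
#' @param n_replicates Replicate wells per density.
#' @param min_permissive_density Minimal OD that still permits syntrophic
#'   growth.
#' @param top_density Seeding OD of the least-dilute column.
#' @param times Measurement times (hours).
#' @return Object of class `plate_assay`: list with `curves` (well, time,
#'   od), `map` (well, density, replicate, blank) and `truth`.
#' @export
simulate_growth_plate <- function(config, n_dilutions = 8L, n_replicates = 6L,
                                  min_permissive_density = 0.02,
                                  top_density = 0.1,
                                  times = seq(0, 96, by = 2)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_dilutions < 2) abort("`n_dilutions` must be >= 2.")
  if (min_permissive_density < 0 || top_density <= 0) {
    abort("densities must be non-negative.")
  }
  gp <- config$growth_params
  densities <- top_density / config$dilution_fold^(seq_len(n_dilutions) - 1)
  blank_od <- 0.035

  with_seed(derive_seed(config$seed, 401L), {
    map_df <- bind_rows(
      tibble(well = sprintf("A%02d", seq_len(n_replicates)),
             density = NA_real_, replicate = seq_len(n_replicates),
             blank = TRUE),
      expand_grid(step = seq_len(n_dilutions),
                  replicate = seq_len(n_replicates)) %>%
        mutate(well = sprintf("W%02d_%02d", .data$step, .data$replicate),
               density = densities[.data$step], blank = FALSE) %>%
        select("well", "density", "replicate", "blank")
    )
    curves <- pmap(map_df, function(well, density, replicate, blank) {
      base <- if (blank) blank_od else blank_od + density
      od <- if (!blank && density >= min_permissive_density) {
        base + logistic_od(times, gp$mu, gp$lambda, gp$A)
      } else {
        rep(base, length(times))
      }
      tibble(well = well, time = times,
             od = pmax(od + rnorm(length(times), 0, config$noise_sd), 0))
    }) %>% bind_rows()

    structure(
      list(curves = curves, map = map_df,
           truth = list(min_permissive_density = min_permissive_density,
                        densities = densities, growth_params = gp)),
      class = "plate_assay"
    )
  })
}

#' @export
print.plate_assay <- function(x, ...) {
  cat(sprintf("<plate_assay> %d wells (%d blank), %d densities\n",
              nrow(x$map), sum(x$map$blank), length(x$truth$densities)))
  invisible(x)
}

#' Fit every well of a plate assay
#'
#' @param plate A `plate_assay` (or a list with `curves` and `map` tibbles).
#' @param ... Passed to [fit_growth()].
#' @return Tibble, one row per well, joining the plate map with each well's
#'   [glance()]d fit.
#' @export
fit_growth_plate <- function(plate, ...) {
  curves <- plate$curves
  fits <- curves %>%
    group_by(.data$well) %>%
    dplyr::group_map(function(df, key) {
      g <- glance(fit_growth(df[, c("time", "od")], ...))
      mutate(g, well = key$well)
    }) %>%
    bind_rows()
  left_join(plate$map, fits, by = "well")
}

#' Minimal growth-permissive density of a dilution plate
#'
#' Fits every non-blank well, counts growing replicates per seeding density,
#' and reports the lowest density at which at least
#' `min_replicates_growing` wells grew, together with the full per-density
#' growth profile. Any blank well showing sustained growth aborts with a
#' contamination error.
#'
#' @param plate A `plate_assay`.
#' @param growth_threshold OD rise that counts as growth (default 0.05).
#' @param min_replicates_growing Minimum growing replicates (default 1).
#' @param ... Passed to [fit_growth()].
#' @return List with `minimal_density` (NA when nothing grew) and `profile`
#'   (tibble: density, n_grew, n_wells).
#' @export
minimal_permissive_density <- function(plate, growth_threshold = 0.05,
                                       min_replicates_growing = 1L, ...) {
  fits <- fit_growth_plate(plate, growth_threshold = growth_threshold, ...)
  blanks <- filter(fits, .data$blank)
  if (any(blanks$grew)) {
    abort(sprintf("contaminated blank well(s): %s",
                  paste(blanks$well[blanks$grew], collapse = ", ")))
  }
  profile <- fits %>%
    filter(!.data$blank) %>%
    group_by(.data$density) %>%
    summarise(n_grew = sum(.data$grew), n_wells = n(), .groups = "drop") %>%
    arrange(desc(.data$density))
  ok <- profile$density[profile$n_grew >= min_replicates_growing]
  list(minimal_density = if (length(ok)) min(ok) else NA_real_,
       profile = profile)
}
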