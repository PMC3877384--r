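# Forward prediction of output delta-13C under fluctuating dietary input:
# discrete convolution of the input history with the normalized turnover
# kernel, truncated at six half-lives of the slowest pool.

#' Build the normalized turnover weight kernel
#'
#' Ages run `u = 0, step, 2 step, ..., 6 * t_half_max`; the raw weight at age
#' u is the model value with the offset c removed ([kernel_value()]), and
#' weights are normalized to sum to 1. The mass lost by truncating at six
#' half-lives of the slowest pool is recorded in `tail_fraction` (computed in
#' closed form from the geometric tails).
#'
#' @param model A `compartment_model` with same-signed, not all-zero
#'   amplitudes.
#' @param step_h Kernel step, h (default 1).
#' @param form Passed to [kernel_value()].
#' @return Object of class `weight_kernel`: fields `step_h`, `ages`,
#'   `weights`, `window_h`, `delay_h`, `tail_fraction`.
#' @export
build_kernel <- function(model, step_h = 1, form = c("model_value", "impulse_response")) {
  stopifnot(inherits(model, "compartment_model"))
  form <- match.arg(form)
  if (step_h <= 0) iso_validation_error("step_h must be positive")
  if (all(model$pools$a == 0)) {
    iso_validation_error("degenerate model: all amplitudes are zero")
  }
  if (!same_sign_amplitudes(model)) {
    iso_validation_error(
      "turnover kernel requires all pool amplitudes to share one sign")
  }
  window <- 6 * max(half_lives(model))
  ages <- seq(0, window, by = step_h)
  raw <- kernel_value(model, ages, form = form)
  a <- abs(model$pools$a)
  if (form == "impulse_response") a <- a / model$pools$tau
  r <- exp(-step_h / model$pools$tau)
  K <- length(ages) - 1L
  tail_mass <- sum(a * r^(K + 1) / (1 - r))
  structure(list(step_h = step_h, ages = ages, weights = raw / sum(raw),
                 window_h = window, delay_h = model$delay_h,
                 tail_fraction = tail_mass / (sum(raw) + tail_mass),
                 form = form),
            class = "weight_kernel")
}

#' @export
print.weight_kernel <- function(x, ...) {
  cat(sprintf("<weight_kernel> step %g h, window %g h (%d weights), delay %g h; truncated tail mass %.3g\n",
              x$step_h, x$window_h, length(x$weights), x$delay_h, x$tail_fraction))
  invisible(x)
}

#' Predict output delta-13C from an input history
#'
#' For each requested time `now`, the prediction is
#' `sum_u w_u * input(now - delay - u) + shift`, with the input read as a
#' carried-forward step function at the kernel ages. The input series must
#' cover `[min(times) - delay - window, max(times) - delay]`; there is no
#' silent extrapolation.
#'
#' @param input_series `isotope_series` of dietary input.
#' @param model `compartment_model` supplying the delay (and the kernel, if
#'   `kernel` is NULL).
#' @param kernel A [build_kernel()] result, or NULL to build one at 1 h.
#' @param shift Trophic shift in permil, or a `shift_estimate`.
#' @param times Numeric vector of prediction times, h.
#' @return `isotope_series` of predictions (stream `"predicted"`).
#' @export
predict_output <- function(input_series, model, kernel = NULL, shift = 0, times) {
  stopifnot(inherits(input_series, "isotope_series"),
            inherits(model, "compartment_model"))
  if (is.null(kernel)) kernel <- build_kernel(model, step_h = 1)
  if (inherits(shift, "shift_estimate")) shift <- shift$shift_permil
  if (length(times) < 1L) iso_validation_error("times must be nonempty")
  d <- kernel$delay_h
  need_lo <- min(times) - d - kernel$window_h
  need_hi <- max(times) - d
  have_lo <- min(input_series$time_h)
  have_hi <- max(input_series$time_h)
  if (have_lo > need_lo + 1e-9 || have_hi < need_hi - 1e-9) {
    iso_coverage_error(sprintf(
      "input covers [%g, %g] h but predictions need [%g, %g] h (delay %g + window %g)",
      have_lo, have_hi, need_lo, need_hi, d, kernel$window_h))
  }
  lookup_t <- outer(times - d, kernel$ages, "-")  # n_times x n_ages
  vals <- matrix(lookup_previous(input_series, as.numeric(lookup_t)),
                 nrow = length(times))
  pred <- as.numeric(vals %*% kernel$weights) + shift
  isotope_series(input_series$animal_id, "predicted", times, pred)
}

#' Estimate the trophic shift from measured vs. shift-free predictions
#'
#' Pairs measured and predicted samples by nearest time (within `tolerance`)
#' and returns the mean difference with its standard error.
#'
#' @param measured `isotope_series` of measurements.
#' @param predicted_no_shift `isotope_series` predicted with shift 0.
#' @param tolerance Matching tolerance, h (defaults to 1).
#' @return Object of class `shift_estimate`: fields `shift_permil`, `se`,
#'   `n`.
#' @export
estimate_shift <- function(measured, predicted_no_shift, tolerance = 1) {
  pr <- match_pairs(measured, predicted_no_shift, tolerance)
  if (pr$n == 0L) iso_validation_error("no overlapping times between series")
  if (pr$n < 3L) iso_validation_error("need at least 3 paired time points")
  d <- pr$x - pr$y
  structure(list(shift_permil = mean(d),
                 se = if (pr$n > 1L) stats::sd(d) / sqrt(pr$n) else 0,
                 n = pr$n),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> %+.3f permil (SE %.3f, n = %d)\n",
              x$shift_permil, x$se, x$n))
  invisible(x)
}

match_pairs <- function(sa, sb, tolerance) {
  xs <- numeric(); ys <- numeric(); ts <- numeric()
  for (i in seq_along(sa$time_h)) {
    j <- which.min(abs(sb$time_h - sa$time_h[i]))
    if (abs(sb$time_h[j] - sa$time_h[i]) <= tolerance) {
      xs <- c(xs, sa$delta13C[i])
      ys <- c(ys, sb$delta13C[j])
      ts <- c(ts, sa$time_h[i])
    }
  }
  list(x = xs, y = ys, t = ts, n = length(xs))
}

#' Validate predictions against measurements
#'
#' Regresses measured on predicted values (OLS), tests the slope against 1
#' and the intercept against 0, and reports the RMSE of the raw differences
#' (not the regression residual). The prediction-interval half-width is
#' `SD * T_a`, with SD the standard deviation of the measured values and
#' `T_a` the Student-t percentile with n - 1 degrees of freedom.
#'
#' @param measured,predicted `isotope_series` with >= 3 common times.
#' @param confidence Confidence level (default 0.95).
#' @param tolerance Time-matching tolerance, h.
#' @return Object of class `validation_report`: `rmse`, `n`, `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `p_slope_vs_1`,
#'   `p_intercept_vs_0`, `prediction_interval_halfwidth`.
#' @export
validate_predictions <- function(measured, predicted, confidence = 0.95,
                                 tolerance = 1) {
  pr <- match_pairs(measured, predicted, tolerance)
  if (pr$n < 3L) iso_validation_error("need at least 3 paired time points")
  diffs <- pr$x - pr$y
  rmse <- sqrt(mean(diffs^2))
  Ta <- stats::qt(1 - (1 - confidence) / 2, df = pr$n - 1L)
  pih <- stats::sd(pr$x) * Ta
  out <- list(rmse = rmse, n = pr$n,
              slope = NA_real_, intercept = NA_real_,
              slope_se = NA_real_, intercept_se = NA_real_,
              p_slope_vs_1 = NA_real_, p_intercept_vs_0 = NA_real_,
              prediction_interval_halfwidth = pih,
              confidence = confidence)
  if (stats::var(pr$y) > 1e-12) {
    fit <- stats::lm(pr$x ~ pr$y)
    # a perfect fit is a legitimate input here (summary.lm warns about it)
    cf <- suppressWarnings(summary(fit))$coefficients
    out$intercept <- cf[1L, 1L]; out$intercept_se <- cf[1L, 2L]
    out$slope <- cf[2L, 1L]; out$slope_se <- cf[2L, 2L]
    df <- pr$n - 2L
    out$p_slope_vs_1 <- 2 * stats::pt(-abs((out$slope - 1) / out$slope_se), df)
    out$p_intercept_vs_0 <- 2 * stats::pt(-abs(out$intercept / out$intercept_se), df)
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, RMSE %.3f permil\n", x$n, x$rmse))
  if (is.finite(x$slope)) {
    cat(sprintf("  slope %.3f (p vs 1: %.3f), intercept %.3f (p vs 0: %.3f)\n",
                x$slope, x$p_slope_vs_1, x$intercept, x$p_intercept_vs_0))
  }
  invisible(x)
}

# Continuous-time convolution of a step input with the normalized exponential
# kernel (truncated at six half-lives). Used as an independent oracle for the
# discrete engine: for an input that switches from `pre` to `post` just after
# time 0, the exact prediction at time `now` is
#   pre + (post - pre) * F(now - delay), F the truncated kernel CDF.
continuous_step_prediction <- function(model, pre, post, now) {
  d <- model$delay_h
  W <- 6 * max(half_lives(model))
  a <- abs(model$pools$a)
  tau <- model$pools$tau
  total <- sum(a * tau * (1 - exp(-W / tau)))
  cdf <- function(x) {
    x <- min(max(x, 0), W)
    sum(a * tau * (1 - exp(-x / tau))) / total
  }
  vapply(now, function(tt) pre + (post - pre) * cdf(tt - d), numeric(1))
}
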