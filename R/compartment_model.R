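# The mathematical kernel: delay + multi-pool exponential turnover models.
#
# A model describes one output stream's delta-13C response to a diet switch at
# t = 0:
#   delta(t) = c + sum_p a_p                          for t <= delay
#   delta(t) = c + sum_p a_p * exp(-(t - delay)/tau_p) for t >  delay
# where c is the asymptotic baseline (permil), a_p the initial deviation
# contributed by pool p, and tau_p its mean residence time (h). The pool
# half-life is t_half = tau * ln 2.

#' Construct a compartmental turnover model
#'
#' @param c_permil Asymptotic baseline in permil vs. VPDB.
#' @param delay_h Ingestion-to-output delay in hours (>= 0).
#' @param amplitudes Numeric vector of pool amplitudes `a_p` (permil).
#' @param taus Numeric vector of pool mean residence times `tau_p` (h), same
#'   length as `amplitudes`. Pools are stored sorted by increasing tau;
#'   pools with (numerically) identical tau are merged.
#' @return An object of class `compartment_model`.
#' @export
compartment_model <- function(c_permil, delay_h = 0, amplitudes, taus) {
  if (!is.finite(c_permil)) iso_validation_error("c must be finite")
  if (!is.finite(delay_h) || delay_h < 0) iso_validation_error("delay_h must be finite and >= 0")
  amplitudes <- as.numeric(amplitudes)
  taus <- as.numeric(taus)
  if (length(amplitudes) != length(taus)) {
    iso_validation_error("amplitudes and taus must have equal length")
  }
  if (length(taus) < 1L || length(taus) > 4L) {
    iso_validation_error("between 1 and 4 pools are supported")
  }
  if (!all(is.finite(amplitudes))) iso_validation_error("amplitudes must be finite")
  if (!all(is.finite(taus)) || any(taus <= 0)) iso_validation_error("taus must be positive")
  ord <- order(taus)
  taus <- taus[ord]
  amplitudes <- amplitudes[ord]
  # merge pools whose residence times are numerically indistinguishable
  if (length(taus) > 1L) {
    grp <- cumsum(c(TRUE, diff(taus) / taus[-length(taus)] > 1e-9))
    if (max(grp) < length(taus)) {
      amplitudes <- as.numeric(tapply(amplitudes, grp, sum))
      taus <- as.numeric(tapply(taus, grp, function(x) x[1L]))
    }
  }
  structure(list(c = c_permil, delay_h = delay_h,
                 pools = data.frame(a = amplitudes, tau = taus)),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("<compartment_model> c = %.3f permil, delay = %.2f h, %d pool(s)\n",
              x$c, x$delay_h, nrow(x$pools)))
  ph <- half_lives(x)
  for (p in seq_len(nrow(x$pools))) {
    cat(sprintf("  pool %d: a = %+.3f permil, tau = %.3f h (t1/2 = %.2f h)\n",
                p, x$pools$a[p], x$pools$tau[p], ph[p]))
  }
  invisible(x)
}

same_sign_amplitudes <- function(model) {
  a <- model$pools$a
  all(a >= 0) || all(a <= 0)
}

#' Evaluate a compartment model
#'
#' Returns the pre-switch plateau `c + sum(a)` for `t <= delay` and the
#' multi-exponential decay for `t > delay`; continuous at the delay.
#'
#' @param model A `compartment_model`.
#' @param t Numeric vector of times (h, relative to the switch).
#' @return Numeric vector of delta-13C values (permil).
#' @export
evaluate_model <- function(model, t) {
  stopifnot(inherits(model, "compartment_model"))
  u <- pmax(t - model$delay_h, 0)
  E <- exp(-outer(u, 1 / model$pools$tau))
  as.numeric(model$c + E %*% model$pools$a)
}

#' @rdname evaluate_model
#' @param object A `compartment_model`.
#' @param ... unused.
#' @export
predict.compartment_model <- function(object, t, ...) evaluate_model(object, t)

#' Half-life from mean residence time
#'
#' `t_half = tau * ln 2`.
#'
#' @param tau Mean residence time(s), h.
#' @return Half-life/-lives, h.
#' @export
half_life <- function(tau) {
  if (any(tau <= 0)) iso_validation_error("tau must be positive")
  tau * log(2)
}

#' Mean residence time from half-life
#' @param t_half Half-life/-lives, h.
#' @return tau, h.
#' @export
tau_from_half_life <- function(t_half) {
  if (any(t_half <= 0)) iso_validation_error("t_half must be positive")
  t_half / log(2)
}

#' Pool half-lives of a model
#' @param model A `compartment_model`.
#' @return Numeric vector of pool half-lives, h.
#' @export
half_lives <- function(model) half_life(model$pools$tau)

#' Gross half-life: time after the switch at which half the total shift is done
#'
#' Solves `sum_p a_p exp(-(t - delay)/tau_p) = sum_p a_p / 2` for `t > delay`
#' by bracketed root finding. For a one-pool model this equals
#' `delay + tau * ln 2`. Unlike pool half-lives the gross half-life includes
#' the delay and only applies to the first half-life period after a switch.
#'
#' @param model A `compartment_model` with nonzero total amplitude and
#'   same-signed pool amplitudes.
#' @param tol Root-finding tolerance in hours.
#' @return Gross half-life, h.
#' @export
gross_half_life <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "compartment_model"))
  a_tot <- sum(model$pools$a)
  if (a_tot == 0) iso_validation_error("total amplitude is zero; gross half-life undefined")
  if (!same_sign_amplitudes(model)) {
    iso_validation_error("gross half-life requires same-signed pool amplitudes")
  }
  d <- model$delay_h
  f <- function(t) {
    u <- t - d
    sum(model$pools$a * exp(-u / model$pools$tau)) / a_tot - 0.5
  }
  hi <- d + 10 * max(half_lives(model))
  r <- stats::uniroot(f, lower = d, upper = hi, tol = tol)
  r$root
}

#' Unnormalized turnover-kernel value at a given age
#'
#' The model value with the offset c removed, taken as a magnitude so an
#' upward or downward switch yields the identical weighting:
#' `|sum_p a_p exp(-age/tau_p)|`. The impulse-response variant
#' `|sum_p (a_p/tau_p) exp(-age/tau_p)|` is available for sensitivity
#' analysis.
#'
#' @param model A `compartment_model`.
#' @param age_h Age(s) since the input passed the delay, h (>= 0).
#' @param form `"model_value"` (default) or `"impulse_response"`.
#' @return Nonnegative kernel value(s).
#' @export
kernel_value <- function(model, age_h, form = c("model_value", "impulse_response")) {
  stopifnot(inherits(model, "compartment_model"))
  form <- match.arg(form)
  if (any(age_h < 0)) iso_validation_error("age_h must be >= 0")
  a <- model$pools$a
  if (form == "impulse_response") a <- a / model$pools$tau
  E <- exp(-outer(as.numeric(age_h), 1 / model$pools$tau))
  abs(as.numeric(E %*% a))
}

#' Serialize a compartment model to JSON
#' @param model A `compartment_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "compartment_model"))
  x <- list(c = model$c, delay_h = model$delay_h,
            pools = lapply(seq_len(nrow(model$pools)), function(p) {
              list(a = model$pools$a[p], tau = model$pools$tau[p])
            }))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a compartment model from JSON
#' @param x JSON string or file path.
#' @return A `compartment_model`.
#' @export
model_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(obj$c) || is.null(obj$pools)) {
    iso_format_error("model JSON must contain fields c, delay_h, pools")
  }
  compartment_model(
    c_permil = as.numeric(obj$c),
    delay_h = if (is.null(obj$delay_h)) 0 else as.numeric(obj$delay_h),
    amplitudes = vapply(obj$pools, function(p) as.numeric(p$a), numeric(1)),
    taus = vapply(obj$pools, function(p) as.numeric(p$tau), numeric(1)))
}
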