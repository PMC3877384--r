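# Carbon-weighted mixing (diet from components; whole milk back-calculated
# from lactose, casein and milk fat) and the diet-switch shift epsilon.

#' Define a carbon-fraction mixture
#'
#' @param streams Character vector of component stream labels.
#' @param fractions Numeric carbon fractions in `[0, 1]`, summing to 1.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(streams, fractions) {
  streams <- as.character(streams)
  fractions <- as.numeric(fractions)
  if (length(streams) != length(fractions) || length(streams) < 2L) {
    iso_validation_error("need >= 2 components with one fraction each")
  }
  if (any(fractions < 0 | fractions > 1)) {
    iso_validation_error("fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    iso_validation_error(sprintf("fractions must sum to 1 (got %.12f)", sum(fractions)))
  }
  if (anyDuplicated(streams)) iso_validation_error("duplicate component stream")
  structure(list(streams = streams, fractions = fractions),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec>", paste(sprintf("%s: %.3f", x$streams, x$fractions),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Carbon-weighted mean delta-13C of a mixture
#'
#' @param spec A [mixture_spec()].
#' @param component_deltas Named numeric vector/list of component delta-13C
#'   values (permil); every spec component must be present.
#' @return Mixture delta-13C, permil.
#' @export
mix_delta <- function(spec, component_deltas) {
  stopifnot(inherits(spec, "mixture_spec"))
  component_deltas <- unlist(component_deltas)
  missing <- setdiff(spec$streams, names(component_deltas))
  if (length(missing)) {
    iso_validation_error(sprintf("missing component delta for: %s",
                                 paste(missing, collapse = ", ")))
  }
  sum(spec$fractions * as.numeric(component_deltas[spec$streams]))
}

#' Back-calculate a composite series from component series
#'
#' Per-time carbon-weighted mixing of component series sharing sampling times
#' (within `tolerance` hours); the first listed component's times are the
#' reference grid.
#'
#' @param components Named list of `isotope_series` (names = stream labels)
#'   or a list whose elements carry the spec's stream labels.
#' @param spec A [mixture_spec()].
#' @param tolerance Time-alignment tolerance, h.
#' @return `isotope_series` with stream `"back_calculated"`.
#' @export
back_calculate_series <- function(components, spec, tolerance = 1) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    names(components) <- vapply(components, `[[`, character(1), "stream")
  }
  missing <- setdiff(spec$streams, names(components))
  if (length(missing)) {
    iso_validation_error(sprintf("missing component series for: %s",
                                 paste(missing, collapse = ", ")))
  }
  ref <- components[[spec$streams[1L]]]
  times <- ref$time_h
  vals <- matrix(NA_real_, length(times), length(spec$streams))
  for (j in seq_along(spec$streams)) {
    s <- components[[spec$streams[j]]]
    for (i in seq_along(times)) {
      k <- which.min(abs(s$time_h - times[i]))
      if (abs(s$time_h[k] - times[i]) > tolerance) {
        bad <- times[vapply(times, function(tt)
          min(abs(s$time_h - tt)) > tolerance, logical(1))]
        iso_validation_error(sprintf(
          "component %s misaligned beyond %g h at time(s): %s",
          spec$streams[j], tolerance,
          paste(format(utils::head(bad, 10)), collapse = ", ")))
      }
      vals[i, j] <- s$delta13C[k]
    }
  }
  isotope_series(ref$animal_id, "back_calculated", times,
                 as.numeric(vals %*% spec$fractions))
}

#' Shift in output delta-13C following the diet switch
#'
#' `delta_b` is the delay-period (pre-response) delta-13C and `delta_a` the
#' fitted asymptote c. Under the `"difference"` convention
#' `epsilon = delta_a - delta_b`; under `"ratio"`,
#' `epsilon = ((1000 + delta_a)/(1000 + delta_b) - 1) * 1000`, the
#' conventional epsilon notation for isotopic enrichment factors.
#'
#' @param delta_b,delta_a Delta-13C before/after the switch, permil
#'   (> -1000).
#' @param convention `"difference"` (default) or `"ratio"`.
#' @return Object of class `switch_shift`: fields `delta_b`, `delta_a`,
#'   `epsilon`, `convention`.
#' @export
switch_shift <- function(delta_b, delta_a, convention = c("difference", "ratio")) {
  convention <- match.arg(convention)
  if (delta_b <= -1000 || delta_a <= -1000) {
    iso_validation_error("delta values must exceed -1000 permil")
  }
  eps <- if (convention == "difference") delta_a - delta_b
         else ((1000 + delta_a) / (1000 + delta_b) - 1) * 1000
  structure(list(delta_b = delta_b, delta_a = delta_a, epsilon = eps,
                 convention = convention),
            class = "switch_shift")
}

#' @export
print.switch_shift <- function(x, ...) {
  cat(sprintf("<switch_shift> epsilon = %+.3f permil (%s; delta_b %.3f -> delta_a %.3f)\n",
              x$epsilon, x$convention, x$delta_b, x$delta_a))
  invisible(x)
}
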