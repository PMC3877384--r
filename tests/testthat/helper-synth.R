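# Shared fixtures: small builders used across test files. All data are
# generated in code; nothing is read from disk except explicit round-trips
# through temporary files.

one_pool <- function(c_permil = -30.04, delay = 12, a = 2.9, t_half = 10) {
  compartment_model(c_permil, delay, a, tau_from_half_life(t_half))
}

# study-design sampling grids: twice-daily, 32 equilibration + 15 chase
equil_times <- seq(-384, -12, by = 12)
chase_times <- seq(0, 168, by = 12)
study_times <- c(equil_times, chase_times)

# dense-grid scan oracle for root-type operations: first crossing of the
# (unclamped) exponential branch with a level, scanned at 0.001 h
grid_first_crossing <- function(model, level, from = 0, to = NULL, by = 1e-3) {
  if (is.null(to)) to <- model$delay_h + 12 * max(model$pools$tau)
  tt <- seq(from, to, by = by)
  v <- vapply(tt, function(t) {
    model$c + sum(model$pools$a * exp(-(t - model$delay_h) / model$pools$tau))
  }, numeric(1))
  s <- sign(v - level)
  i <- which(s[-1] != s[-length(s)])[1]
  if (is.na(i)) return(NA_real_)
  tt[i] + by / 2
}

post_switch <- function(series_list) {
  lapply(series_list, function(s) {
    keep <- s$time_h >= 0
    isotope_series(s$animal_id, s$stream, s$time_h[keep], s$delta13C[keep])
  })
}
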