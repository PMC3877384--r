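test_that("exact data are recovered to high precision", {
  m <- one_pool(-30.04, 12, 2.9, 10)
  sp <- output_stream_spec("lactose", m, noise_sd = 0, times = seq(12, 180, 12))
  out <- gen_model_output(sp, n_animals = 8, seed = 1)
  fit <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$param_estimates[["c"]], -30.04, tolerance = 1e-4)
  expect_equal(fit$param_estimates[["a1"]], 2.9, tolerance = 1e-4)
  expect_equal(fit$param_estimates[["tau1"]], tau_from_half_life(10),
               tolerance = 1e-4)
  # overfitting the same data with 2 pools cannot beat the 1-pool AIC
  fit2 <- fit_model(out, 2, sharing_structure(), delay_h = 12, seed = 1)
  expect_gte(fit2$aic, fit$aic - 1e-6)
})

test_that("fit is invariant to animal order and deterministic under seed", {
  m <- one_pool(-30, 12, 2.64, 10)
  sp <- output_stream_spec("lactose", m, noise_sd = 0.15, times = chase_times)
  out <- gen_model_output(sp, n_animals = 6, seed = 9)
  f1 <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 4)
  f2 <- fit_model(rev(out), 1, sharing_structure(), delay_h = 12, seed = 4)
  expect_equal(f1$param_estimates, f2$param_estimates, tolerance = 1e-8)
  f3 <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 4)
  expect_identical(f1$param_estimates, f3$param_estimates)
})

test_that("fully shared joint fit equals plain least squares on pooled data", {
  m <- one_pool(-30, 12, 2.64, 14)
  sp <- output_stream_spec("x", m, noise_sd = 0.2, times = chase_times)
  out <- gen_model_output(sp, n_animals = 5, seed = 2)
  fit <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 1)
  df <- do.call(rbind, lapply(out, function(s)
    data.frame(t = s$time_h, y = s$delta13C)))
  df <- df[df$t >= 12, ]
  oracle <- stats::nls(y ~ cc + a * exp(-(t - 12) / tau), data = df,
                       start = list(cc = -30, a = 2.6, tau = 20))
  oc <- coef(oracle)
  expect_equal(fit$param_estimates[["c"]], unname(oc["cc"]), tolerance = 1e-5)
  expect_equal(fit$param_estimates[["a1"]], unname(oc["a"]), tolerance = 1e-5)
  expect_equal(fit$param_estimates[["tau1"]], unname(oc["tau"]), tolerance = 1e-4)
  # AIC identity and parameter counting
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$log_likelihood)
})

test_that("parameter recovery: median t1/2 error < 10% at the study design", {
  m <- one_pool(-30, 12, 2.64, 10)
  sp <- output_stream_spec("x", m, noise_sd = 0.15, times = seq(12, 180, 12))
  err <- vapply(1:25, function(s) {
    out <- gen_model_output(sp, n_animals = 8, seed = s)
    fit <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = s)
    abs(half_life(fit$param_estimates[["tau1"]]) - 10) / 10
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("two-pool CIs cover the truth when both pools are identifiable", {
  m <- compartment_model(-30, 12, -2.1 * c(0.55, 0.45),
                         tau_from_half_life(c(10, 21)))
  sp <- output_stream_spec("wm", m, noise_sd = 0.15, times = seq(12, 168, 12))
  res <- vapply(1:25, function(s) {
    out <- gen_model_output(sp, n_animals = 8, seed = s)
    fit <- fit_model(out, 2, sharing_structure(), delay_h = 12, seed = s)
    ci1 <- tryCatch(half_life_ci(fit, 1), iso_error = function(e) NULL)
    ci2 <- tryCatch(half_life_ci(fit, 2), iso_error = function(e) NULL)
    if (is.null(ci1) || is.null(ci2)) return(NA)  # non-identifiable pool
    ci1$lower <= 10 && 10 <= ci1$upper && ci2$lower <= 21 && 21 <= ci2$upper
  }, logical(1))
  expect_gte(mean(!is.na(res)), 0.6)       # most replicates identifiable
  expect_gte(mean(res[!is.na(res)]), 0.9)  # and then the CIs cover
})

test_that("AIC selection picks the parsimonious truth", {
  m <- one_pool(-29.58, 12, 2.64, 10)
  sp <- output_stream_spec("lactose", m, noise_sd = 0.13, times = seq(12, 168, 12))
  sel <- vapply(1:15, function(s) {
    out <- gen_model_output(sp, n_animals = 8, seed = s)
    select_model(out, max_pools = 2, structures = list(sharing_structure()),
                 delay_h = 12, seed = s)$pool_count
  }, numeric(1))
  expect_gte(mean(sel == 1), 0.9)
})

test_that("a per-animal baseline offset is detected by structure selection", {
  m <- one_pool(-30, 12, 2.64, 10)
  sp <- output_stream_spec("x", m, noise_sd = 0.12, times = seq(12, 168, 12))
  out <- gen_model_output(sp, n_animals = 8, seed = 6)
  out[[3]] <- isotope_series(out[[3]]$animal_id, "x", out[[3]]$time_h,
                             out[[3]]$delta13C + 1.0)
  sel <- select_model(out, max_pools = 1, delay_h = 12, seed = 1)
  expect_equal(sel$structure$c, "per_animal")
  expect_equal(sel$pool_count, 1L)
  # the selected AIC is the best among converged candidates
  cand <- attr(sel, "candidates")
  expect_lte(sel$aic, min(cand$aic[cand$converged]) + 2)
})

test_that("half-life CI arithmetic matches the t-distribution rule", {
  m <- one_pool(-30, 12, 2.64, 9)
  sp <- output_stream_spec("feces", m, noise_sd = 0.15, times = seq(12, 168, 12))
  out <- gen_model_output(sp, n_animals = 8, seed = 3)
  fit <- fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 1)
  ci <- half_life_ci(fit, 1)
  Ta <- qt(0.975, 7)
  expect_equal(Ta, 2.3646, tolerance = 1e-4)
  expect_equal(ci$upper - ci$t_half, ci$se * Ta)
  expect_equal(ci$t_half - ci$lower, ci$se * Ta)
  # the width the published table implies: SE(t1/2) = 1.27, n = 8 -> (6, 12)
  expect_equal(9 - 1.27 * Ta, 6.0, tolerance = 0.005)
  expect_equal(9 + 1.27 * Ta, 12.0, tolerance = 0.005)
  # zero-noise fit: degenerate CI at the estimate
  sp0 <- output_stream_spec("x", m, noise_sd = 0, times = seq(12, 168, 12))
  fit0 <- fit_model(gen_model_output(sp0, n_animals = 8, seed = 1), 1,
                    sharing_structure(), delay_h = 12, seed = 1)
  ci0 <- half_life_ci(fit0, 1)
  expect_equal(ci0$lower, ci0$upper, tolerance = 1e-5)
  # ordering always holds, even at n = 2 (very wide interval)
  out2 <- gen_model_output(sp, n_animals = 2, seed = 5)
  fit2 <- fit_model(out2, 1, sharing_structure(), delay_h = 12, seed = 1)
  ci2 <- half_life_ci(fit2, 1)
  expect_true(ci2$lower <= ci2$t_half && ci2$t_half <= ci2$upper)
  expect_gt(ci2$upper - ci2$lower, ci$upper - ci$lower)
})

test_that("insufficient data raise informative errors", {
  m <- one_pool(-30, 12, 2.64, 10)
  sp <- output_stream_spec("x", m, noise_sd = 0.1, times = c(12, 24))
  out <- gen_model_output(sp, n_animals = 1, seed = 1)
  expect_error(fit_model(out, 1, sharing_structure(), delay_h = 12, seed = 1),
               class = "iso_validation_error")
})
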