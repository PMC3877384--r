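test_that("partition finds the modal chase boundary on feces-like data", {
  # true delay 20 h, twice-daily sampling: the first time with any real
  # response is 24 h, which should be the modal detected boundary
  m <- one_pool(-30.61, 20, 1.1, 9)
  sp <- output_stream_spec("feces", m, noise_sd = 0.12, times = study_times)
  bounds <- vapply(1:40, function(s) {
    out <- gen_model_output(sp, n_animals = 8, seed = s)
    partition_delay_chase(post_switch(out))$first_chase_time_h
  }, numeric(1))
  tab <- table(bounds)
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 24)
  expect_gte(mean(bounds == 24), 0.7)
})

test_that("partition handles null, degenerate and small-herd cases", {
  # no switch applied: time-constant series, no response detectable
  flat <- lapply(1:8, function(i)
    isotope_series(paste0("A", i), "x", chase_times,
                   rep(-27 - 0.05 * i, length(chase_times))))
  expect_error(partition_delay_chase(flat), "no switch response",
               class = "iso_no_response_error")
  # instantaneous shift, zero noise: first tested time significant
  step <- lapply(1:8, function(i)
    isotope_series(paste0("A", i), "x", chase_times,
                   c(-27, rep(-29.7, length(chase_times) - 1)) + i * 1e-4))
  p <- partition_delay_chase(step)
  expect_equal(p$first_chase_time_h, 12)
  expect_equal(p$delay_sample_times, 0)
  # fewer than 5 pairs at a time point: skipped with a warning
  small <- lapply(1:2, function(i)
    isotope_series(paste0("A", i), "x", chase_times,
                   c(-27, rep(-29.7, length(chase_times) - 1))))
  w <- capture_warnings(expect_error(partition_delay_chase(small)))
  expect_true(any(grepl("matched pairs", w)))
})

test_that("partition boundary is monotone in alpha", {
  m <- one_pool(-30, 12, 2.64, 10)
  sp <- output_stream_spec("lactose", m, noise_sd = 0.15, times = study_times)
  for (s in 1:10) {
    out <- post_switch(gen_model_output(sp, n_animals = 8, seed = s))
    b_strict <- partition_delay_chase(out, alpha = 0.01)$first_chase_time_h
    b_loose <- partition_delay_chase(out, alpha = 0.10)$first_chase_time_h
    expect_gte(b_strict, b_loose)
  }
})

test_that("delay refinement matches its closed-form cases", {
  # baseline equal to the initial value: intersection at the delay itself
  m <- one_pool(-29.8, 12, 2.9, 10)
  expect_equal(refine_delay_by_intersection(m, -26.9)$delay_h, 12)
  # baseline halfway between plateau and asymptote: delay + t1/2
  expect_equal(refine_delay_by_intersection(m, -29.8 + 2.9 / 2)$delay_h,
               12 + 10, tolerance = 1e-6)
  # baseline on the wrong side of the asymptote: no intersection
  expect_error(refine_delay_by_intersection(m, -31),
               class = "iso_no_intersection_error")
})

test_that("refinement agrees with the 0.001 h grid-scan oracle", {
  m2 <- compartment_model(-30, 12, c(1.3, 1.3), tau_from_half_life(c(10, 21)))
  base <- (m2$c + sum(m2$pools$a)) + 0.25 * (m2$c - (m2$c + sum(m2$pools$a)))
  expect_equal(refine_delay_by_intersection(m2, base)$delay_h,
               grid_first_crossing(m2, base), tolerance = 0.01)
  set.seed(42)
  for (i in 1:100) {
    P <- sample(1:2, 1)
    m <- compartment_model(runif(1, -32, -26), runif(1, 0, 20),
                           runif(P, 0.3, 2.5), sort(runif(P, 5, 35)))
    plateau <- m$c + sum(m$pools$a)
    base <- m$c + runif(1, 0.05, 0.95) * (plateau - m$c)
    est <- refine_delay_by_intersection(m, base)$delay_h
    expect_equal(est, grid_first_crossing(m, base), tolerance = 0.01)
  }
})

test_that("on zero-noise data the refined delay equals the generating delay", {
  m <- one_pool(-30.04, 12, 2.9, 10)
  sp <- output_stream_spec("lactose", m, noise_sd = 0, times = study_times)
  out <- post_switch(gen_model_output(sp, n_animals = 8, seed = 1))
  part <- partition_delay_chase(out)
  fit <- fit_model(out, 1, sharing_structure(),
                   delay_h = part$first_chase_time_h, seed = 1)
  ref <- refine_delay_by_intersection(fit$models[[1]], part$baseline_mean)
  expect_equal(ref$delay_h, 12, tolerance = 1e-4)
})
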