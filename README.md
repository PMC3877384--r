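# isoturn

Delay-aware compartmental modelling of carbon isotope turnover in animal
products, and forward prediction of product δ¹³C under fluctuating dietary
input.

`isoturn` is aimed at isotope ecologists and animal scientists running
diet-switch (tracer washout) experiments: the diet's δ¹³C is changed
abruptly at *t* = 0 and the washout of the old signal is tracked in outputs
such as whole milk, lactose, casein, milk fat and feces. Each output stream
is modelled as

δ(t) = c + Σₚ aₚ · exp(−(t − d)/τₚ)  for t > d,

with the pre-switch plateau c + Σₚ aₚ for t ≤ d: an ingestion-to-output
delay *d* (h) followed by 1–4 independent pools with amplitudes aₚ (‰) and
mean residence times τₚ (h); pool half-lives are t½ = τₚ·ln 2. The package
implements the full workflow:

* **Delay detection** — stepwise Wilcoxon matched-pairs partition of the
  post-switch samples into delay and chase periods, then refinement of the
  delay as the intersection of the fitted model with the delay-period
  baseline.
* **Model fitting** — joint nonlinear least squares across animals
  (Levenberg–Marquardt) with enumerable parameter-sharing structures
  (shared vs. per-animal c, aₚ, τₚ), AIC selection over pool counts and
  structures, half-life confidence intervals (t½ ± SE·T₀.₉₇₅ with
  n_animals − 1 df), gross half-lives and switch shifts.
* **Forward prediction** — convolution of the dietary input history with
  the normalized turnover kernel (model value with the offset removed,
  truncated at six half-lives of the slowest pool), trophic-shift
  estimation and validation statistics (RMSE, slope/intercept tests,
  prediction intervals).
* **Carbon-weighted mixing** — diet δ¹³C from feed components; whole milk
  back-calculated from lactose, casein and milk fat.
* **Synthetic studies** — a seeded generator reproducing the emulated
  study design (8 animals, 32 + 15 samples, realistic delays, half-lives,
  shifts and noise) with retained ground truth.

## Worked example

```r
library(isoturn)

study <- gen_study(seed = 7)                       # synthetic 8-cow study
ser   <- get_series(study$dataset, stream = "feces")
res   <- fit_stream(ser, fit_config(max_pools = 2, seed = 7))

res$fit
#> <fit_result> 1 pool(s), c:shared,a:shared,tau:shared; converged: TRUE
#>   AIC -76.41, logLik 42.21, residual SD 0.1636 permil, n = 104, k = 4

res$delay$delay_h          # refined ingestion-to-output delay (h)
#> [1] 21.20987
res$half_life_cis[[1]]
#> <half_life_ci> 12.31 h (95% CI 10.18-14.44)
res$gross_half_life_h      # delay + washout to half completion (h)
#> [1] 28.08802
res$switch_shift
#> <switch_shift> epsilon = -2.060 permil (difference; delta_b -29.792 -> delta_a -31.852)
```

The generating truth for this stream was delay 20 h, t½ 9 h, gross
half-life 29 h and a realized switch of −2.1 ‰ after attenuation of the
shared dietary fluctuations. The gross half-life — the operationally
useful summary — lands within an hour of truth; the individual delay and
half-life trade off against each other by a couple of hours, which is the
expected behaviour when the chase data also carry shared input
fluctuations (see the vignette's limitations section). Forward validation
against the fluctuating equilibration period:

```r
truem <- study$truth$streams$lactose$true_model
rep <- cmd_predict(study$dataset, truem, predict_config(stream = "lactose"))
rep$pooled_validation$rmse     # ~ the 0.13 permil analytical noise
#> [1] 0.119039
rep$pooled_validation$slope
#> [1] 0.9974262
```

A measured-vs-predicted slope near 1 with RMSE at the analytical-noise
scale is the signature that chase-derived turnover parameters predict
equilibration-period fluctuations.

See `vignettes/turnover-modelling.Rmd` for the model, its assumptions,
numerical choices and known identifiability limits.

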