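# Joint nonlinear least-squares fitting of the turnover model across animals,
# with enumerable parameter-sharing structures compared by AIC.
#
# "Shared vs. per-animal" plays the role of the fixed/random factor decision:
# each of c, a_p and tau_p is either one value common to all animals or one
# value per animal; candidates (pool count x structure) are fitted by
# Levenberg-Marquardt least squares and compared by AIC on the Gaussian
# profile likelihood. tau is fitted on the log scale to enforce positivity.

#' Define a parameter-sharing structure
#'
#' @param c `"shared"` or `"per_animal"`: asymptotic baseline.
#' @param a `"shared"` or `"per_animal"`: pool amplitudes.
#' @param tau `"shared"` or `"per_animal"`: pool residence times.
#' @return An object of class `sharing_structure`.
#' @export
sharing_structure <- function(c = "shared", a = "shared", tau = "shared") {
  flags <- c(c = match.arg(c, c("shared", "per_animal")),
             a = match.arg(a, c("shared", "per_animal")),
             tau = match.arg(tau, c("shared", "per_animal")))
  structure(as.list(flags), class = "sharing_structure")
}

#' @export
format.sharing_structure <- function(x, ...) {
  paste0("c:", x$c, ",a:", x$a, ",tau:", x$tau)
}

#' @export
print.sharing_structure <- function(x, ...) {
  cat("<sharing_structure>", format(x), "\n")
  invisible(x)
}

#' Default candidate sharing structures
#'
#' Fully shared parameters plus per-animal baseline, the two structures that
#' discriminate "identical kinetics across animals" from animal-specific
#' offsets.
#' @return List of [sharing_structure()] objects.
#' @export
default_sharing_structures <- function() {
  list(sharing_structure(),
       sharing_structure(c = "per_animal"))
}

# ---- parameter packing ------------------------------------------------------

# theta layout: [log_tau block][a block][c block]; shared blocks have one set,
# per_animal blocks one set per animal (animal-major within a block).
param_layout <- function(pool_count, structure, animals) {
  m <- length(animals)
  n_tau <- if (structure$tau == "shared") pool_count else pool_count * m
  n_a <- if (structure$a == "shared") pool_count else pool_count * m
  n_c <- if (structure$c == "shared") 1L else m
  nm_tau <- if (structure$tau == "shared") paste0("log_tau", seq_len(pool_count))
            else as.vector(outer(paste0("log_tau", seq_len(pool_count)), animals, paste, sep = "."))
  nm_a <- if (structure$a == "shared") paste0("a", seq_len(pool_count))
          else as.vector(outer(paste0("a", seq_len(pool_count)), animals, paste, sep = "."))
  nm_c <- if (structure$c == "shared") "c" else paste0("c.", animals)
  list(n = n_tau + n_a + n_c,
       i_tau = seq_len(n_tau),
       i_a = n_tau + seq_len(n_a),
       i_c = n_tau + n_a + seq_len(n_c),
       names = c(nm_tau, nm_a, nm_c),
       m = m, P = pool_count)
}

# per-animal parameter extraction; ai is the animal index
unpack_animal <- function(theta, layout, structure, ai) {
  P <- layout$P
  tau <- if (structure$tau == "shared") exp(theta[layout$i_tau])
         else exp(theta[layout$i_tau][(ai - 1L) * P + seq_len(P)])
  a <- if (structure$a == "shared") theta[layout$i_a]
       else theta[layout$i_a][(ai - 1L) * P + seq_len(P)]
  cc <- if (structure$c == "shared") theta[layout$i_c]
        else theta[layout$i_c][ai]
  list(tau = tau, a = a, c = cc)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a multi-pool turnover model jointly across animals
#'
#' Minimizes the residual sum of squares of the delay-anchored
#' multi-exponential model over all animals simultaneously, with the delay
#' held fixed. tau parameters are fitted on the log scale; the optimizer is
#' restarted from `n_starts` deterministic initial values with residence
#' times log-spaced in [2, 200] h, and the best converged start is returned
#' with pools canonicalized to increasing tau.
#'
#' @param chase_series List of `isotope_series` (one per animal); only samples
#'   with `time_h >= delay_h` enter the fit.
#' @param pool_count Number of exponential pools (1-4).
#' @param structure A [sharing_structure()].
#' @param delay_h Fixed ingestion-to-output delay, h.
#' @param seed Integer seed controlling the multistart jitter.
#' @param n_starts Number of deterministic starts.
#' @return An object of class `fit_result`: fields `structure`, `pool_count`,
#'   `models` (per-animal `compartment_model`), `param_estimates`,
#'   `standard_errors`, `residual_sd`, `log_likelihood`, `aic`, `n_obs`,
#'   `n_params`, `n_animals`, `converged`.
#' @export
fit_model <- function(chase_series, pool_count, structure = sharing_structure(),
                      delay_h, seed = 1L, n_starts = 8L) {
  if (inherits(chase_series, "isotope_series")) chase_series <- list(chase_series)
  stopifnot(inherits(structure, "sharing_structure"))
  if (!pool_count %in% 1:4) iso_validation_error("pool_count must be in 1..4")
  if (!is.finite(delay_h) || delay_h < 0) iso_validation_error("delay_h must be >= 0")

  # canonical animal order makes the fit invariant to input permutation
  ids <- vapply(chase_series, `[[`, character(1), "animal_id")
  chase_series <- chase_series[order(ids)]
  animals <- sort(unique(ids))
  if (anyDuplicated(ids)) iso_validation_error("one series per animal expected")

  dat <- lapply(chase_series, function(s) {
    keep <- s$time_h >= delay_h - 1e-9
    list(t = s$time_h[keep], y = s$delta13C[keep])
  })
  n_obs <- sum(vapply(dat, function(d) length(d$t), integer(1)))
  layout <- param_layout(pool_count, structure, animals)
  if (n_obs < layout$n + 3L) {
    iso_validation_error(sprintf(
      "need at least %d observations for %d parameters; have %d",
      layout$n + 3L, layout$n, n_obs))
  }

  u_list <- lapply(dat, function(d) pmax(d$t - delay_h, 0))
  y_all <- unlist(lapply(dat, `[[`, "y"))

  resid_fun <- function(theta) {
    res <- vector("list", layout$m)
    for (ai in seq_len(layout$m)) {
      p <- unpack_animal(theta, layout, structure, ai)
      E <- exp(-outer(u_list[[ai]], 1 / p$tau))
      res[[ai]] <- dat[[ai]]$y - (p$c + as.numeric(E %*% p$a))
    }
    unlist(res)
  }

  # data-driven anchors for the starts
  y_early <- mean(unlist(lapply(dat, function(d) d$y[d$t <= stats::quantile(d$t, 0.15)])))
  y_late <- mean(unlist(lapply(dat, function(d) d$y[d$t >= stats::quantile(d$t, 0.75)])))
  c0 <- y_late
  a_tot0 <- y_early - y_late
  if (!is.finite(a_tot0) || a_tot0 == 0) a_tot0 <- 1e-3

  tau_centers <- exp(seq(log(2), log(200), length.out = n_starts))
  best <- NULL
  diagnostics <- list()
  for (k in seq_len(n_starts)) {
    taus0 <- tau_centers[k] * 2.5^(seq_len(pool_count) - (pool_count + 1) / 2)
    taus0 <- pmin(pmax(taus0, 0.5), 500)
    set.seed((abs(seed) %% 1000000L) * 1000L + k)
    jit <- exp(stats::rnorm(pool_count, 0, 0.05))
    taus0 <- taus0 * jit
    theta0 <- numeric(layout$n)
    theta0[layout$i_tau] <- rep(log(taus0), length.out = length(layout$i_tau))
    theta0[layout$i_a] <- rep(a_tot0 / pool_count, length(layout$i_a))
    theta0[layout$i_c] <- c0
    # residence times are box-bounded to [0.5, 500] h: pools far outside the
    # sampling resolution are degenerate reparameterizations of noise
    lower <- rep(-Inf, layout$n); upper <- rep(Inf, layout$n)
    lower[layout$i_tau] <- log(0.5); upper[layout$i_tau] <- log(500)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(ans)) {
      diagnostics[[k]] <- list(start = k, status = "error")
      next
    }
    ssr <- sum(ans$fvec^2)
    conv <- ans$info %in% 1:3
    diagnostics[[k]] <- list(start = k, status = if (conv) "converged" else "not_converged",
                             info = ans$info, ssr = ssr)
    if (conv && (is.null(best) || ssr < best$ssr - 0)) {
      if (is.null(best) || ssr < best$ssr) best <- list(fit = ans, ssr = ssr)
    }
  }

  if (is.null(best)) {
    return(structure(list(structure = structure, pool_count = pool_count,
                          models = NULL, param_estimates = NULL,
                          standard_errors = NULL, residual_sd = NA_real_,
                          log_likelihood = NA_real_, aic = Inf,
                          n_obs = n_obs, n_params = layout$n + 1L,
                          n_animals = layout$m, delay_h = delay_h,
                          converged = FALSE, diagnostics = diagnostics),
                     class = "fit_result"))
  }

  theta <- best$fit$par
  # canonicalize pool order (increasing tau), uniformly across animals
  if (pool_count > 1L) {
    mean_logtau <- sapply(seq_len(pool_count), function(p) {
      if (structure$tau == "shared") theta[layout$i_tau][p]
      else mean(theta[layout$i_tau][(seq_len(layout$m) - 1L) * pool_count + p])
    })
    perm <- order(mean_logtau)
    if (!identical(perm, seq_len(pool_count))) {
      permute_block <- function(idx, per_animal) {
        v <- theta[idx]
        if (per_animal) {
          for (ai in seq_len(layout$m)) {
            off <- (ai - 1L) * pool_count
            v[off + seq_len(pool_count)] <- v[off + perm]
          }
        } else v <- v[perm]
        v
      }
      theta[layout$i_tau] <- permute_block(layout$i_tau, structure$tau == "per_animal")
      theta[layout$i_a] <- permute_block(layout$i_a, structure$a == "per_animal")
    }
  }
  names(theta) <- layout$names

  ssr <- best$ssr
  sigma2_mle <- ssr / n_obs
  logLik <- -n_obs / 2 * (log(2 * pi * sigma2_mle) + 1)
  n_params <- layout$n + 1L  # + residual variance
  aic <- 2 * n_params - 2 * logLik
  residual_sd <- sqrt(ssr / max(n_obs - layout$n, 1L))

  # standard errors from the Jacobian at the optimum (recomputed at the
  # canonical ordering; J'J from nls.lm is order-dependent)
  se <- rep(NA_real_, layout$n)
  J <- tryCatch(numeric_jacobian(resid_fun, theta), error = function(e) NULL)
  if (!is.null(J)) {
    JtJ <- crossprod(J)
    V <- tryCatch(solve(JtJ) * residual_sd^2, error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))
  }
  names(se) <- layout$names

  models <- lapply(seq_len(layout$m), function(ai) {
    p <- unpack_animal(theta, layout, structure, ai)
    compartment_model(p$c, delay_h, p$a, p$tau)
  })
  names(models) <- animals

  # report tau (and SE via delta method) alongside the raw log-tau estimates
  est <- theta
  for (i in layout$i_tau) {
    nm <- sub("^log_", "", names(theta)[i])
    est[[nm]] <- exp(theta[[i]])
    se[[nm]] <- exp(theta[[i]]) * se[[i]]
  }
  est <- est[!grepl("^log_tau", names(est))]
  se <- se[!grepl("^log_tau", names(se))]

  structure(list(structure = structure, pool_count = pool_count,
                 models = models, param_estimates = est,
                 standard_errors = se, residual_sd = residual_sd,
                 log_likelihood = logLik, aic = aic, n_obs = n_obs,
                 n_params = n_params, n_animals = layout$m,
                 delay_h = delay_h, converged = TRUE,
                 diagnostics = diagnostics),
            class = "fit_result")
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d pool(s), %s; converged: %s\n",
              x$pool_count, format(x$structure), x$converged))
  if (x$converged) {
    cat(sprintf("  AIC %.2f, logLik %.2f, residual SD %.4f permil, n = %d, k = %d\n",
                x$aic, x$log_likelihood, x$residual_sd, x$n_obs, x$n_params))
  }
  invisible(x)
}

#' Select pool count and sharing structure by AIC
#'
#' Fits every (pool_count, structure) combination and returns the converged
#' fit preferred by AIC; when a simpler candidate (fewer parameters) lies
#' within 2 AIC units of the minimum, the simpler one wins.
#'
#' @inheritParams fit_model
#' @param max_pools Maximum pool count to consider (<= 4).
#' @param structures List of [sharing_structure()] candidates.
#' @return The selected `fit_result`, with a `candidates` data.frame attached
#'   as an attribute.
#' @export
select_model <- function(chase_series, max_pools = 3L,
                         structures = default_sharing_structures(),
                         delay_h, seed = 1L, n_starts = 8L) {
  if (max_pools > 4L) iso_validation_error("max_pools must be <= 4")
  fits <- list()
  rows <- list()
  i <- 0L
  for (P in seq_len(max_pools)) {
    for (st in structures) {
      i <- i + 1L
      f <- tryCatch(
        fit_model(chase_series, P, st, delay_h = delay_h, seed = seed,
                  n_starts = n_starts),
        iso_error = function(e) NULL)
      fits[[i]] <- f
      rows[[i]] <- data.frame(pool_count = P, structure = format(st),
                              n_params = if (is.null(f)) NA_integer_ else f$n_params,
                              aic = if (is.null(f) || !f$converged) NA_real_ else f$aic,
                              converged = !is.null(f) && f$converged,
                              stringsAsFactors = FALSE)
    }
  }
  candidates <- do.call(rbind, rows)
  ok <- which(candidates$converged)
  if (length(ok) == 0L) {
    iso_convergence_error(paste0(
      "no (pool count, structure) candidate converged; candidates:\n",
      paste(utils::capture.output(print(candidates)), collapse = "\n")))
  }
  min_aic <- min(candidates$aic[ok])
  near <- ok[candidates$aic[ok] < min_aic + 2]
  pick <- near[order(candidates$n_params[near], candidates$aic[near])][1L]
  sel <- fits[[pick]]
  attr(sel, "candidates") <- candidates
  sel
}

#' Confidence interval for a pool half-life
#'
#' `t_half +/- SE(t_half) * T_a`, with `SE(t_half) = ln 2 * SE(tau)` (delta
#' method) and `T_a` the upper percentile of Student's t with
#' `n_animals - 1` degrees of freedom.
#'
#' @param fit A converged `fit_result` with shared tau.
#' @param pool_index Pool number (1 = fastest).
#' @param confidence Confidence level (default 0.95).
#' @return Object of class `half_life_ci`: fields `t_half`, `lower`,
#'   `upper`, `se`, `confidence`.
#' @export
half_life_ci <- function(fit, pool_index = 1L, confidence = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) iso_convergence_error("fit did not converge; no CI available")
  if (fit$structure$tau != "shared") {
    iso_validation_error("half_life_ci requires a shared-tau structure")
  }
  nm <- paste0("tau", pool_index)
  if (!nm %in% names(fit$param_estimates)) {
    iso_validation_error(sprintf("no pool %d in fit", pool_index))
  }
  tau <- fit$param_estimates[[nm]]
  se_tau <- fit$standard_errors[[nm]]
  if (!is.finite(se_tau)) {
    iso_validation_error(sprintf(
      "singular information matrix: pool %d not identifiable", pool_index))
  }
  t_half <- log(2) * tau
  se_th <- log(2) * se_tau
  Ta <- stats::qt(1 - (1 - confidence) / 2, df = fit$n_animals - 1L)
  structure(list(t_half = t_half, lower = t_half - se_th * Ta,
                 upper = t_half + se_th * Ta, se = se_th,
                 confidence = confidence),
            class = "half_life_ci")
}

#' @export
print.half_life_ci <- function(x, ...) {
  cat(sprintf("<half_life_ci> %.2f h (%.0f%% CI %.2f-%.2f)\n",
              x$t_half, 100 * x$confidence, x$lower, x$upper))
  invisible(x)
}
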