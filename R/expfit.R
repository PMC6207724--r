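# Multi-exponential fitting of relaxation traces by variable projection:
# for trial decay rates the linear coefficients (offset, drift, amplitudes)
# are solved exactly by least squares, and only the log-rates are optimised
# numerically from a multi-start grid. This keeps the noiseless round trip
# exact to numerical precision and is robust to poor initial guesses.

trace_fields <- function(trace) {
  tr <- as.data.frame(trace)
  t <- tr$time_s %||% tr$time
  if (is.null(t)) abort("trace needs a 'time_s' column", "confsel_parse_error")
  if (is.null(tr$signal)) abort("trace needs a 'signal' column", "confsel_parse_error")
  if (any(diff(t) <= 0)) abort("trace times must be strictly increasing",
                               "confsel_parse_error")
  list(t = t, y = tr$signal)
}

exp_design <- function(t, rates, drift) {
  X <- cbind(offset = rep(1, length(t)))
  if (drift) X <- cbind(X, drift = t)
  for (k in rates) X <- cbind(X, exp(-k * t))
  X
}

#' Fit a one- or two-phase exponential decay to a trace
#'
#' Model: `signal = offset [+ drift*t] + sum_i amp_i * exp(-rate_i * t)`.
#' Rates are constrained positive (optimised on the log scale), amplitudes
#' and baseline are profiled out exactly at each step, and the rate search
#' starts from a grid of log-spaced decades bracketing the sampled time
#' span. The parameter covariance is computed from the full Jacobian at the
#' optimum.
#'
#' @param trace data.frame with `time_s` (or `time`) and `signal`.
#' @param n_phases 1 or 2.
#' @param allow_drift Include a linear baseline drift term.
#' @param extra_starts Optional numeric vector of additional rate guesses
#'   (1/s) added to the start grid.
#' @return Object of class `"exp_fit"`: `rates` (1/s, sorted decreasing),
#'   `amplitudes` (matched order), `offset`, `drift` (NA unless requested),
#'   `cov` (parameter covariance, order offset/[drift]/amps/rates),
#'   `sigma2` (residual variance), `aic`, `rss`, `n_phases`, `fitted`.
#' @export
fit_exponentials <- function(trace, n_phases = 2, allow_drift = FALSE,
                             extra_starts = NULL) {
  stopifnot(n_phases %in% c(1L, 2L))
  tf <- trace_fields(trace)
  t <- tf$t; y <- tf$y
  n_par <- 1L + allow_drift + 2L * n_phases
  if (length(t) < 5L * n_par)
    abort(sprintf("trace too short: %d points for %d parameters",
                  length(t), n_par), "confsel_insufficient_data")
  rss_of <- function(logk) {
    k <- exp(logk)
    if (n_phases == 2 && abs(k[1] - k[2]) / max(k) < 1e-8) return(Inf)
    X <- exp_design(t, k, allow_drift)
    f <- stats::.lm.fit(X, y)
    sum(f$residuals^2)
  }
  span <- t[length(t)] - t[1]
  dt <- stats::median(diff(t))
  k_grid <- exp(seq(log(0.2 / span), log(2 / dt), length.out = 7))
  k_grid <- unique(c(k_grid, extra_starts))
  starts <- if (n_phases == 1) as.list(log(k_grid)) else {
    cmb <- utils::combn(log(k_grid), 2)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  optimise_from <- function(s) {
    if (n_phases == 1)
      stats::optim(s, rss_of, method = "Brent",
                   lower = log(min(k_grid)) - 5, upper = log(max(k_grid)) + 5,
                   control = list(reltol = 1e-15, maxit = 3000))
    else
      stats::optim(s, rss_of, method = "Nelder-Mead",
                   control = list(reltol = 1e-15, maxit = 3000))
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optimise_from(s), error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    abort("exponential fit failed to converge from every start",
          "confsel_fit_error")
  best <- optimise_from(best$par)  # polish restart at the winner
  k <- exp(best$par)
  X <- exp_design(t, k, allow_drift)
  lin <- stats::lm.fit(X, y)
  coefs <- lin$coefficients
  offset <- coefs[["offset"]]
  drift <- if (allow_drift) coefs[["drift"]] else NA_real_
  amps <- coefs[(1L + allow_drift + 1L):length(coefs)]
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; amps <- as.numeric(amps)[ord]
  rss <- sum(lin$residuals^2)
  n <- length(t)
  sigma2 <- rss / max(1, n - n_par)
  # Jacobian wrt (offset, [drift], amps, rates)
  J <- exp_design(t, k, allow_drift)
  for (i in seq_along(k)) J <- cbind(J, -amps[i] * t * exp(-k[i] * t))
  cov <- tryCatch(sigma2 * solve(crossprod(J)),
                  error = function(e) matrix(NA_real_, n_par, n_par))
  nm <- c("offset", if (allow_drift) "drift",
          paste0("amp", seq_along(k)), paste0("rate", seq_along(k)))
  if (all(dim(cov) == n_par)) dimnames(cov) <- list(nm, nm)
  if (n_phases == 2 && (k[1] - k[2]) / k[1] < 1e-3)
    warning("fitted rates nearly degenerate; consider a single phase")
  structure(list(rates = k, amplitudes = amps, offset = offset,
                 drift = drift, cov = cov, sigma2 = sigma2, rss = rss,
                 aic = n * log(max(rss, .Machine$double.xmin) / n) + 2 * n_par,
                 n_phases = n_phases, allow_drift = allow_drift,
                 fitted = as.numeric(X %*% coefs), time_s = t),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d phase(s)%s\n", x$n_phases,
              if (x$allow_drift) " + drift" else ""))
  for (i in seq_along(x$rates))
    cat(sprintf("  rate%d = %.5g 1/s  (amp %.4g)\n", i, x$rates[i],
                x$amplitudes[i]))
  cat(sprintf("  offset = %.4g, residual sd = %.3g, AIC = %.1f\n",
              x$offset, sqrt(x$sigma2), x$aic))
  invisible(x)
}

#' Choose between single- and double-exponential descriptions
#'
#' Fits both phase counts and prefers two phases only when AIC improves and
#' the extra phase is resolvable: the two rates differ by at least
#' `min_rate_ratio`-fold, or the smaller amplitude exceeds
#' `amp_noise_factor` times the residual noise of the two-phase fit.
#'
#' @param trace data.frame with `time_s`/`time` and `signal`.
#' @param allow_drift Passed to [fit_exponentials()].
#' @param min_rate_ratio,amp_noise_factor Resolvability guards.
#' @return 1 or 2 (integer), with both fits attached as attributes
#'   `fit1`/`fit2`.
#' @export
select_phase_count <- function(trace, allow_drift = FALSE,
                               min_rate_ratio = 3, amp_noise_factor = 3) {
  f1 <- fit_exponentials(trace, 1, allow_drift)
  y <- trace_fields(trace)$y
  # a numerically perfect single-exponential fit needs no second phase
  if (f1$rss <= 1e-16 * sum((y - mean(y))^2))
    return(structure(1L, fit1 = f1, fit2 = NULL))
  f2 <- tryCatch(suppressWarnings(fit_exponentials(trace, 2, allow_drift)),
                 error = function(e) NULL)
  n <- 1L
  if (!is.null(f2) && f2$aic < f1$aic) {
    ratio_ok <- max(f2$rates) / min(f2$rates) >= min_rate_ratio
    amp_ok <- min(abs(f2$amplitudes)) > amp_noise_factor * sqrt(f2$sigma2)
    if (ratio_ok || amp_ok) n <- 2L
  }
  structure(n, fit1 = f1, fit2 = f2)
}

#' Average replicate traces point-wise
#'
#' Replicate stopped-flow shots on a shared time base are averaged before
#' fitting, mirroring standard practice.
#'
#' @param traces List of trace data.frames with identical time grids.
#' @return A single trace data.frame.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- trace_fields(traces[[1]])$t
  sigs <- vapply(traces, function(tr) {
    tf <- trace_fields(tr)
    if (length(tf$t) != length(t0) || max(abs(tf$t - t0)) > 1e-12)
      abort("replicate traces must share one time grid", "confsel_parse_error")
    tf$y
  }, numeric(length(t0)))
  data.frame(time_s = t0, signal = rowMeans(sigs))
}

#' Fit dissociation kinetics after dilution
#'
#' Single-exponential fit of a dilution trace; when rebinding after
#' dilution is negligible (post-dilution free ligand well below the
#' apparent K_D) the fitted rate is the intrinsic off-rate. With
#' appreciable rebinding the fitted rate overestimates `k_off`; quantify
#' that bias with [simulate_dissociation()].
#'
#' @param trace_after_dilution data.frame with `time_s`/`time`, `signal`.
#' @param allow_drift Include a linear drift term.
#' @return List with `k_off`, `k_off_se`, and the underlying `"exp_fit"`.
#' @export
fit_dissociation <- function(trace_after_dilution, allow_drift = FALSE) {
  fit <- fit_exponentials(trace_after_dilution, 1, allow_drift)
  se <- if (all(is.finite(fit$cov))) sqrt(fit$cov["rate1", "rate1"]) else NA_real_
  list(k_off = fit$rates[1], k_off_se = se, fit = fit)
}
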