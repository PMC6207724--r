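# Conformational-selection binding scheme:
#
#     open  <--k_close--  (exchange)           closed + L  <--k_on-->  closed.L
#     open  --k_close-->  closed                        (k_off back)
#
# k_open is the opening rate (closed -> open), k_close the closing rate
# (open -> closed); the ligand binds only the closed conformer. Units are
# uM and seconds throughout.

#' Construct a conformational-selection scheme
#'
#' @param k_open Opening rate closed -> open, 1/s.
#' @param k_close Closing rate open -> closed, 1/s.
#' @param k_on True (intrinsic) association rate of the ligand with the
#'   closed state, 1/(uM s).
#' @param k_off Dissociation rate, 1/s.
#' @param se Optional named list/vector of standard errors for any of the
#'   four rates (used by [apparent_kd()] error propagation).
#' @return A list of class `"conf_sel_scheme"` with the four rates plus
#'   derived `K_open_close = k_open/k_close`, intrinsic `K_D = k_off/k_on`
#'   (uM) and apparent `K_D_obs = (K_open_close + 1) * K_D` (uM).
#' @export
conf_sel_scheme <- function(k_open, k_close, k_on, k_off, se = NULL) {
  rates <- c(k_open = k_open, k_close = k_close, k_on = k_on, k_off = k_off)
  stopifnot(all(vapply(rates, is_number, logical(1))), all(rates > 0))
  K_oc <- k_open / k_close
  kd <- k_off / k_on
  structure(list(k_open = k_open, k_close = k_close, k_on = k_on,
                 k_off = k_off, K_open_close = K_oc, K_D = kd,
                 K_D_obs = (K_oc + 1) * kd,
                 p_open = K_oc / (1 + K_oc), p_closed = 1 / (1 + K_oc),
                 se = se),
            class = "conf_sel_scheme")
}

#' @export
print.conf_sel_scheme <- function(x, ...) {
  cat("<conf_sel_scheme>  (ligand binds the closed conformer)\n")
  cat(sprintf("  k_open  = %.4g 1/s     k_close = %.4g 1/s\n", x$k_open, x$k_close))
  cat(sprintf("  k_on    = %.4g 1/(uM s)  k_off = %.4g 1/s\n", x$k_on, x$k_off))
  cat(sprintf("  K_open/close = %.4g   p_open = %.3f\n", x$K_open_close, x$p_open))
  cat(sprintf("  K_D = %.4g uM   K_D_obs = %.4g uM\n", x$K_D, x$K_D_obs))
  invisible(x)
}

#' Exact relaxation rates of the pseudo-first-order scheme
#'
#' With the ligand concentration held constant, the three-state system
#' (open, closed, closed.ligand) is linear; its rate matrix has one zero
#' eigenvalue (conservation) and two nonzero eigenvalues whose magnitudes
#' are the observable relaxation rates. They satisfy
#' \deqn{\lambda_f + \lambda_s = k_{open} + k_{close} + k_{on}L + k_{off}}
#' \deqn{\lambda_f \lambda_s = k_{close}(k_{on}L + k_{off}) + k_{open}k_{off}}
#' (sum of the 2x2 principal minors of the rate matrix), and are returned as
#' the roots of the corresponding quadratic.
#'
#' @param scheme A [conf_sel_scheme()].
#' @param ligand Ligand concentration, uM (vectorised).
#' @return A data.frame with columns `ligand_uM`, `lambda_fast`,
#'   `lambda_slow` (1/s).
#' @export
eigen_rates <- function(scheme, ligand) {
  stopifnot(inherits(scheme, "conf_sel_scheme"), all(ligand >= 0))
  ko <- scheme$k_open; kc <- scheme$k_close
  x <- scheme$k_on * ligand + scheme$k_off
  b <- ko + kc + x
  cc <- kc * x + ko * scheme$k_off
  disc <- sqrt(pmax(0, b^2 - 4 * cc))
  data.frame(ligand_uM = ligand,
             lambda_fast = (b + disc) / 2,
             lambda_slow = (b - disc) / 2)
}

#' Fast-phase observed rate (pre-equilibrium approximation)
#'
#' The linear concentration dependence used to analyse the fast binding
#' phase: \eqn{k_{obs} = k_{on} L / (K_{open/close} + 1) + k_{off}}. The
#' slope is the intrinsic on-rate diluted by the closed-state population.
#'
#' @param ligand Ligand concentration, uM (vectorised).
#' @param k_on Intrinsic on-rate, 1/(uM s).
#' @param k_off Off-rate, 1/s.
#' @param k_open_close Open/close equilibrium constant.
#' @return Observed rate, 1/s.
#' @export
fast_phase_rate <- function(ligand, k_on, k_off, k_open_close) {
  k_on * ligand / (k_open_close + 1) + k_off
}

#' Slow-phase observed rate (conformational-selection hyperbola)
#'
#' The hyperbolic concentration dependence of the slow phase:
#' \deqn{k_{obs,slow} = \frac{k_{close} L + \frac{k_{close}+k_{open}}{k_{on}} k_{off}}
#'       {\frac{k_{close}+k_{open}}{k_{on}} + L}}
#' which evaluates to \eqn{k_{off}} at L = 0 and saturates at
#' \eqn{k_{close}} for large L.
#'
#' @param ligand Ligand concentration, uM (vectorised).
#' @param k_close,k_open Exchange rates, 1/s.
#' @param k_on Intrinsic on-rate, 1/(uM s).
#' @param k_off Off-rate, 1/s.
#' @return Observed slow-phase rate, 1/s.
#' @export
slow_phase_rate <- function(ligand, k_close, k_open, k_on, k_off) {
  s <- (k_close + k_open) / k_on
  (k_close * ligand + s * k_off) / (s + ligand)
}

#' Extract intrinsic on/off rates from the fast-phase line
#'
#' Weighted linear regression of the fast-phase rates on ligand
#' concentration. The slope equals the intrinsic on-rate scaled by the
#' closed population, so `k_on = slope * (K_open_close + 1)`; the intercept
#' is `k_off`.
#'
#' @param data data.frame with columns `ligand_uM`, `k_fast_s` and optional
#'   `k_fast_se` (inverse-variance weights when present).
#' @param k_open_close Open/close equilibrium constant (e.g. from
#'   [equilibrium_from_population()]).
#' @return List with `k_on`, `k_on_se`, `k_off`, `k_off_se`,
#'   `slope_observed`, and the `lm` fit.
#' @export
fit_fast_phase <- function(data, k_open_close) {
  data <- as.data.frame(data)
  stopifnot(all(c("ligand_uM", "k_fast_s") %in% names(data)),
            nrow(data) >= 3, is_number(k_open_close), k_open_close >= 0)
  w <- NULL
  if (!is.null(data$k_fast_se) && all(is.finite(data$k_fast_se)) &&
      all(data$k_fast_se > 0))
    w <- 1 / data$k_fast_se^2
  fit <- stats::lm(k_fast_s ~ ligand_uM, data = data, weights = w)
  # suppressed: summary warns on noiseless (numerically exact) fixtures
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["ligand_uM", "Estimate"]
  if (slope <= 0)
    abort("fast-phase rates do not increase with ligand; data inconsistent",
          "confsel_data_inconsistency")
  list(k_on = slope * (k_open_close + 1),
       k_on_se = cf["ligand_uM", "Std. Error"] * (k_open_close + 1),
       k_off = cf["(Intercept)", "Estimate"],
       k_off_se = cf["(Intercept)", "Std. Error"],
       slope_observed = slope, fit = fit)
}

#' Extract the closing rate from the slow-phase hyperbola
#'
#' Nonlinear fit of [slow_phase_rate()] to the slow-phase rates, with the
#' intrinsic `k_on` and `k_off` supplied from the fast-phase analysis. The
#' fitted plateau is `k_close`; the half-saturation constant
#' `(k_close + k_open)/k_on` yields `k_open`.
#'
#' @param data data.frame with columns `ligand_uM`, `k_slow_s` and optional
#'   `k_slow_se`.
#' @param k_on Intrinsic on-rate, 1/(uM s).
#' @param k_off Off-rate, 1/s.
#' @return List with `k_close`, `k_close_se`, `k_open`, `k_open_se`, and
#'   the `nls` fit.
#' @export
fit_slow_phase <- function(data, k_on, k_off) {
  data <- as.data.frame(data)
  stopifnot(all(c("ligand_uM", "k_slow_s") %in% names(data)),
            nrow(data) >= 4, is_number(k_on), is_number(k_off))
  if (stats::sd(data$k_slow_s) / mean(data$k_slow_s) < 1e-10)
    abort("slow-phase rates show no concentration dependence; k_close unidentifiable",
          "confsel_unidentifiable")
  w <- rep(1, nrow(data))
  if (!is.null(data$k_slow_se) && all(is.finite(data$k_slow_se)) &&
      all(data$k_slow_se > 0))
    w <- 1 / data$k_slow_se^2
  L <- data$ligand_uM; y <- data$k_slow_s
  model <- function(kc, s) (kc * L + s * k_off) / (s + L)
  obj <- function(p) sum(w * (y - model(exp(p[1]), exp(p[2])))^2)
  # multi-start over half-saturation guesses; positivity via log parameters
  s_grid <- unique(c(stats::quantile(L, c(.1, .5, .9)), 0.1 * min(L),
                     10 * max(L)))
  best <- NULL
  for (s0 in s_grid) {
    o <- stats::optim(c(log(max(y)), log(s0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
  k_close <- exp(best$par[1]); s_half <- exp(best$par[2])
  if (s_half > 100 * max(L) || s_half < min(L) / 1e4)
    warning("half-saturation point far outside the sampled range; k_close poorly constrained")
  # Gauss-Newton covariance at the optimum
  J <- cbind(k_close = L / (s_half + L),
             s_half = L * (k_off - k_close) / (s_half + L)^2)
  rss <- best$value
  sigma2 <- rss / max(1, nrow(data) - 2)
  vc <- tryCatch(sigma2 * solve(crossprod(J * sqrt(w))),
                 error = function(e) matrix(NA_real_, 2, 2,
                                            dimnames = list(colnames(J),
                                                            colnames(J))))
  k_open <- s_half * k_on - k_close
  # first-order propagation for k_open = s_half*k_on - k_close (treating the
  # supplied k_on as exact; its uncertainty enters via apparent_kd instead)
  k_open_se <- sqrt(max(0, k_on^2 * vc["s_half", "s_half"] +
                          vc["k_close", "k_close"] -
                          2 * k_on * vc["k_close", "s_half"]))
  if (k_open <= 0)
    warning("fitted half-saturation implies non-positive k_open")
  list(k_close = k_close,
       k_close_se = sqrt(vc["k_close", "k_close"]),
       k_open = k_open, k_open_se = k_open_se, s_half = s_half,
       fit = list(par = c(k_close = k_close, s_half = s_half), rss = rss,
                  cov = vc))
}

#' Apparent dissociation constant of a conformational-selection scheme
#'
#' The ligand sees only the closed conformer, so the observed affinity is
#' the intrinsic one diluted by the binding-competent population:
#' \deqn{K_D^{obs} = (K_{open/close} + 1)\, k_{off}/k_{on}.}
#' Uncertainty is propagated to first order from the standard errors stored
#' in the scheme and, when `n_mc > 0`, cross-checked by seeded Monte-Carlo
#' resampling of the rates (Gaussian, truncated at zero).
#'
#' @param scheme A [conf_sel_scheme()]; its `se` field may carry standard
#'   errors for `k_open`, `k_close`, `k_on`, `k_off` (missing ones count
#'   as 0).
#' @param n_mc Monte-Carlo resamples (0 to skip).
#' @param seed RNG seed for the resampling.
#' @return List with `kd_obs` (uM), `se_linear`, `se_mc` (NA when skipped).
#' @export
apparent_kd <- function(scheme, n_mc = 0, seed = 1L) {
  stopifnot(inherits(scheme, "conf_sel_scheme"))
  ko <- scheme$k_open; kc <- scheme$k_close
  kon <- scheme$k_on; koff <- scheme$k_off
  kd_obs <- (ko / kc + 1) * koff / kon
  se <- scheme$se %||% list()
  s <- function(nm) if (!is.null(se[[nm]])) se[[nm]] else 0
  grad <- c(k_open = koff / (kon * kc),
            k_close = -ko * koff / (kon * kc^2),
            k_on = -kd_obs / kon,
            k_off = (ko / kc + 1) / kon)
  se_lin <- sqrt(sum((grad * c(s("k_open"), s("k_close"), s("k_on"),
                               s("k_off")))^2))
  se_mc <- NA_real_
  if (n_mc > 0) {
    se_mc <- with_seed(seed, {
      draw <- function(m, sd) {
        if (sd == 0) return(rep(m, n_mc))
        x <- stats::rnorm(n_mc, m, sd)
        while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, sd)
        x
      }
      kos <- draw(ko, s("k_open")); kcs <- draw(kc, s("k_close"))
      kons <- draw(kon, s("k_on")); koffs <- draw(koff, s("k_off"))
      stats::sd((kos / kcs + 1) * koffs / kons)
    })
  }
  list(kd_obs = kd_obs, se_linear = se_lin, se_mc = se_mc)
}
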