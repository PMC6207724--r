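# Partial substrate inhibition: a two-site sequential (Adair-Pauling type)
# substrate-binding model in which both ES and ESS turn over, with the
# doubly-bound complex slower. The rate rises, peaks, and levels off at the
# second turnover number instead of dropping to zero.

#' Construct two-site sequential model parameters
#'
#' @param kcat1,kcat2 Turnover numbers of the singly (ES) and doubly (ESS)
#'   bound complexes, 1/s. Partial substrate inhibition requires
#'   `kcat1 > kcat2`.
#' @param kd1,kd2 Macroscopic sequential dissociation constants, uM.
#' @param se Optional named list of standard errors.
#' @return List of class `"two_site_params"`.
#' @export
two_site_params <- function(kcat1, kcat2, kd1, kd2, se = NULL) {
  v <- c(kcat1 = kcat1, kcat2 = kcat2, kd1 = kd1, kd2 = kd2)
  stopifnot(all(vapply(v, is_number, logical(1)) | c(FALSE, FALSE, FALSE, is.infinite(kd2))),
            all(v > 0))
  structure(list(kcat1 = kcat1, kcat2 = kcat2, kd1 = kd1, kd2 = kd2, se = se),
            class = "two_site_params")
}

#' @export
print.two_site_params <- function(x, ...) {
  cat("<two_site_params>\n")
  cat(sprintf("  kcat1 = %.4g 1/s, kcat2 = %.4g 1/s\n", x$kcat1, x$kcat2))
  cat(sprintf("  K_D1  = %.4g uM,  K_D2  = %.4g uM\n", x$kd1, x$kd2))
  if (is.finite(x$kd2) && x$kcat1 > x$kcat2)
    cat("  shape: partial substrate inhibition (rise, peak, level off at kcat2)\n")
  invisible(x)
}

#' Observed turnover of the two-site sequential model
#'
#' \deqn{k_{obs}(S) = \frac{k_{cat,1} S/K_{D,1} + k_{cat,2} S^2/(K_{D,1}K_{D,2})}
#'       {1 + S/K_{D,1} + S^2/(K_{D,1}K_{D,2})}}
#' Evaluates to 0 at S = 0 and tends to `kcat2` as S grows. With
#' `kd2 = Inf` this is the Michaelis-Menten special case saturating at
#' `kcat1`.
#'
#' @param substrate Substrate concentration S, uM (vectorised).
#' @param params A [two_site_params()].
#' @return Observed rate, 1/s.
#' @export
two_site_rate <- function(substrate, params) {
  stopifnot(inherits(params, "two_site_params"), all(substrate >= 0))
  x1 <- substrate / params$kd1
  x2 <- if (is.finite(params$kd2)) x1 * substrate / params$kd2 else 0
  (params$kcat1 * x1 + params$kcat2 * x2) / (1 + x1 + x2)
}

#' Fit the two-site sequential model to steady-state rates
#'
#' Weighted nonlinear least squares of [two_site_rate()] against observed
#' turnover. A nested Michaelis-Menten fit (`kd2 -> Inf`) is always run as
#' well; the simpler model is reported as preferred when its AIC is lower
#' or when the data show no descending branch (monotone rates), in which
#' case a warning is issued.
#'
#' @param data data.frame with `substrate_uM`, `k_obs_s`, optional `sd_s`
#'   (inverse-variance weights).
#' @return Object of class `"two_site_fit"`: `params`
#'   ([two_site_params()] with `se`), `preferred` ("two_site" or "mm"),
#'   `mm` (the reduced fit: kcat, kd, se), `aic` (named vector), `fit`
#'   (the nls object of the full model, NULL if it failed).
#' @export
fit_two_site <- function(data) {
  data <- as.data.frame(data)
  stopifnot(all(c("substrate_uM", "k_obs_s") %in% names(data)))
  data <- data[data$substrate_uM > 0, ]
  if (nrow(data) < 6)
    abort("need >= 6 substrate levels", "confsel_insufficient_data")
  w <- rep(1, nrow(data))
  if (!is.null(data$sd_s) && all(is.finite(data$sd_s)) && all(data$sd_s > 0))
    w <- 1 / data$sd_s^2
  i_max <- which.max(data$k_obs_s)
  descent <- data$k_obs_s[nrow(data)] < 0.97 * max(data$k_obs_s) &&
    i_max < nrow(data)
  S <- data$substrate_uM; y <- data$k_obs_s; sw <- sqrt(w)
  n <- length(S)

  # variable projection: for trial (kd1, kd2) the rate law is linear in the
  # turnover numbers through the occupancy basis, solved exactly by WLS
  basis <- function(kd1, kd2) {
    x1 <- S / kd1
    x2 <- if (is.finite(kd2)) x1 * S / kd2 else numeric(n)
    den <- 1 + x1 + x2
    cbind(b1 = x1 / den, b2 = x2 / den)
  }
  solve_kcats <- function(X) stats::lm.fit(X * sw, y * sw)
  rss_full <- function(p) {
    kd1 <- exp(p[1]); kd2 <- exp(p[2])
    f <- solve_kcats(basis(kd1, kd2))
    if (any(f$coefficients <= 0, na.rm = TRUE) ||
        any(is.na(f$coefficients))) return(1e300)
    sum(f$residuals^2)
  }
  s_cand <- stats::quantile(S, c(.25, .5, .75))
  starts <- expand.grid(lk1 = log(s_cand), lk2 = log(c(max(S), 10 * max(S))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), rss_full,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  full <- NULL
  if (is.finite(best$value) && best$value < 1e299) {
    best <- stats::optim(best$par, rss_full, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 5000))
    kd1 <- exp(best$par[1]); kd2 <- exp(best$par[2])
    kc <- solve_kcats(basis(kd1, kd2))$coefficients
    full <- list(kcat1 = unname(kc[1]), kcat2 = unname(kc[2]),
                 kd1 = kd1, kd2 = kd2, rss = best$value)
  }

  # nested Michaelis-Menten reduction (kd2 -> Inf): kcat profiled out
  rss_mm <- function(lkd) {
    X <- cbind(b1 = S / (exp(lkd) + S))
    f <- stats::lm.fit(X * sw, y * sw)
    sum(f$residuals^2)
  }
  omm <- stats::optim(log(stats::median(S)), rss_mm, method = "Brent",
                      lower = log(min(S)) - 10, upper = log(max(S)) + 10,
                      control = list(reltol = 1e-15))
  kd_mm <- exp(omm$par)
  kcat_mm <- unname(stats::lm.fit(cbind(S / (kd_mm + S)) * sw,
                                  y * sw)$coefficients[1])

  # Gauss-Newton covariances from analytic Jacobians at the optima
  gn_cov <- function(model_fun, par, rss, n_par) {
    eps <- pmax(abs(par), 1e-8) * 1e-6
    f0 <- model_fun(par)
    J <- vapply(seq_along(par), function(j) {
      pj <- par; pj[j] <- pj[j] + eps[j]
      (model_fun(pj) - f0) / eps[j]
    }, numeric(n))
    sigma2 <- rss / max(1, n - n_par)
    tryCatch(sigma2 * solve(crossprod(J * sw)),
             error = function(e) matrix(NA_real_, n_par, n_par))
  }
  mm_model <- function(p) p[1] * S / (p[2] + S)
  vc_mm <- gn_cov(mm_model, c(kcat_mm, kd_mm), omm$value, 2)
  mm_out <- list(kcat = kcat_mm, kd = kd_mm,
                 se = list(kcat = sqrt(vc_mm[1, 1]), kd = sqrt(vc_mm[2, 2])))

  aic_of <- function(rss, p) n * log(max(rss, 1e-300) / n) + 2 * p
  aic <- c(two_site = if (!is.null(full)) aic_of(full$rss, 4) else Inf,
           mm = aic_of(omm$value, 2))
  preferred <- if (!descent || aic["mm"] <= aic["two_site"]) "mm" else "two_site"
  if (!descent)
    warning("rates are monotone in substrate (no descending branch); returning the Michaelis-Menten reduction")
  params <- if (!is.null(full)) {
    ts_model <- function(p) {
      x1 <- S / p[3]; x2 <- x1 * S / p[4]
      (p[1] * x1 + p[2] * x2) / (1 + x1 + x2)
    }
    vc <- gn_cov(ts_model, c(full$kcat1, full$kcat2, full$kd1, full$kd2),
                 full$rss, 4)
    two_site_params(full$kcat1, full$kcat2, full$kd1, full$kd2,
                    se = list(kcat1 = sqrt(vc[1, 1]), kcat2 = sqrt(vc[2, 2]),
                              kd1 = sqrt(vc[3, 3]), kd2 = sqrt(vc[4, 4])))
  } else {
    two_site_params(kcat_mm, kcat_mm, kd_mm, Inf, se = mm_out$se)
  }
  structure(list(params = params, preferred = preferred, mm = mm_out,
                 aic = aic, fit = full),
            class = "two_site_fit")
}

#' @export
print.two_site_fit <- function(x, ...) {
  cat(sprintf("<two_site_fit> preferred model: %s\n", x$preferred))
  print(x$params)
  cat(sprintf("  AIC: two_site %.1f, Michaelis-Menten %.1f\n",
              x$aic["two_site"], x$aic["mm"]))
  invisible(x)
}

#' Boltzmann (four-parameter logistic) dose-response fit
#'
#' Fits `response = floor + (ceiling - floor) / (1 + exp(-(x - x50)/dx))`
#' in `x = log10(dose)`. The midpoint `10^x50` is the IC50 in linear uM and
#' the response at the midpoint equals the mean of the asymptotes. With
#' `fix_asymptotes = TRUE` the floor and ceiling are pinned to 0 and 100%
#' (two-parameter fit).
#'
#' @param data data.frame with `inhibitor_uM`, `pct_inhibition`, optional
#'   `sd` (weights).
#' @param fix_asymptotes Pin the asymptotes to 0/100.
#' @return Object of class `"dose_response_fit"`: `ic50` (uM), `ic50_se`,
#'   `slope` (the logistic width dx in log10 units), `floor`, `ceiling`,
#'   `cov`, `fit`.
#' @export
boltzmann_ic50 <- function(data, fix_asymptotes = FALSE) {
  data <- as.data.frame(data)
  stopifnot(all(c("inhibitor_uM", "pct_inhibition") %in% names(data)))
  data <- data[data$inhibitor_uM > 0, ]
  if (nrow(data) < 5)
    abort("need >= 5 positive doses", "confsel_insufficient_data")
  x <- log10(data$inhibitor_uM)
  y <- data$pct_inhibition
  n <- length(x)
  w <- rep(1, n)
  if (!is.null(data$sd) && all(is.finite(data$sd)) && all(data$sd > 0))
    w <- 1 / data$sd^2
  sw <- sqrt(w)
  logistic <- function(x50, dx) 1 / (1 + exp(-(x - x50) / dx))
  # variable projection: the asymptotes enter linearly through
  # y = lo*(1-g) + hi*g and are profiled out by WLS at each (x50, dx)
  rss_of <- function(p) {
    g <- logistic(p[1], exp(p[2]))
    if (fix_asymptotes) return(sum(w * (y - 100 * g)^2))
    f <- stats::lm.fit(cbind(1 - g, g) * sw, y * sw)
    if (any(is.na(f$coefficients))) return(1e300)
    sum(f$residuals^2)
  }
  mid0 <- x[which.min(abs(y - (max(y) + min(y)) / 2))]
  starts <- expand.grid(x50 = unique(c(mid0, stats::median(x))),
                        ldx = log(c(0.15, 0.3, 0.8)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), rss_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, rss_of, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
  x50 <- best$par[1]; dx <- exp(best$par[2])
  g <- logistic(x50, dx)
  if (fix_asymptotes) {
    lo <- 0; hi <- 100
  } else {
    cf <- stats::lm.fit(cbind(1 - g, g) * sw, y * sw)$coefficients
    lo <- unname(cf[1]); hi <- unname(cf[2])
  }
  # sanity: the sigmoid must actually traverse between its asymptotes
  # inside (or near) the sampled dose range
  if (!is.finite(best$value) || best$value >= 1e299 ||
      x50 < min(x) - 3 || x50 > max(x) + 3)
    abort("dose-response fit failed (non-sigmoidal data?)",
          "confsel_fit_error")
  # covariance of (lo, hi, x50, dx) (or (x50, dx) when fixed) from the
  # Jacobian at the optimum
  dgdx50 <- -g * (1 - g) / dx
  dgddx <- -g * (1 - g) * (x - x50) / dx^2
  J <- if (fix_asymptotes) cbind(x50 = 100 * dgdx50, dx = 100 * dgddx)
  else cbind(lo = 1 - g, hi = g, x50 = (hi - lo) * dgdx50,
             dx = (hi - lo) * dgddx)
  sigma2 <- best$value / max(1, n - ncol(J))
  cov <- tryCatch(sigma2 * solve(crossprod(J * sw)),
                  error = function(e)
                    matrix(NA_real_, ncol(J), ncol(J),
                           dimnames = list(colnames(J), colnames(J))))
  ic50 <- 10^x50
  ic50_se <- log(10) * ic50 * sqrt(cov["x50", "x50"])
  if (lo >= hi) warning("fitted floor is not below the ceiling")
  structure(list(ic50 = ic50, ic50_se = ic50_se, slope = dx,
                 floor = lo, ceiling = hi,
                 fixed_asymptotes = fix_asymptotes,
                 cov = cov, rss = best$value),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> (Boltzmann in log10 dose)\n")
  cat(sprintf("  IC50 = %.4g +/- %.2g uM, width dx = %.3g\n",
              x$ic50, x$ic50_se, x$slope))
  cat(sprintf("  asymptotes: %.3g -> %.3g %%%s\n", x$floor, x$ceiling,
              if (x$fixed_asymptotes) " (fixed)" else ""))
  invisible(x)
}

#' Predict percent inhibition from a dose-response fit
#'
#' @param fit A `"dose_response_fit"`.
#' @param dose Inhibitor concentration, uM (vectorised, > 0).
#' @return Percent inhibition.
#' @export
predict_inhibition <- function(fit, dose) {
  stopifnot(inherits(fit, "dose_response_fit"), all(dose > 0))
  x <- log10(dose)
  x50 <- log10(fit$ic50)
  fit$floor + (fit$ceiling - fit$floor) / (1 + exp(-(x - x50) / fit$slope))
}

#' Inhibitor concentration required to reach a target activity
#'
#' Inverts a monotone-decreasing activity-versus-dose model by bisection.
#' The model can be (i) a function `dose -> activity (1/s)`, (ii) a list
#' `list(kd_obs = ...)` describing simple closed-state sequestration
#' `activity = basal / (1 + dose/kd_obs)`, or (iii) a
#' `"dose_response_fit"`, interpreted as
#' `activity = basal * (1 - pct(dose)/100)`.
#'
#' @param basal_activity Activity without drug, 1/s.
#' @param target_activity Desired activity, 1/s (must not exceed basal).
#' @param inhibition_model See Details.
#' @param upper Largest dose searched, uM; if the target is unreachable
#'   below `upper` (or below the model floor), `Inf` is returned.
#' @return Concentration in uM (`0` when no inhibition is needed, `Inf`
#'   when the target lies below the model's reachable floor).
#' @export
restoration_concentration <- function(basal_activity, target_activity,
                                      inhibition_model, upper = 1e6) {
  stopifnot(is_number(basal_activity), is_number(target_activity),
            basal_activity > 0)
  if (target_activity > basal_activity)
    abort("target activity exceeds basal activity", "confsel_argument_error")
  if (target_activity == basal_activity) return(0)
  act <- if (is.function(inhibition_model)) {
    inhibition_model
  } else if (inherits(inhibition_model, "dose_response_fit")) {
    function(d) basal_activity * (1 - predict_inhibition(inhibition_model, d) / 100)
  } else if (is.list(inhibition_model) && !is.null(inhibition_model$kd_obs)) {
    function(d) basal_activity / (1 + d / inhibition_model$kd_obs)
  } else {
    abort("unrecognised inhibition model", "confsel_argument_error")
  }
  if (act(upper) > target_activity) return(Inf)
  lo <- 0
  hi <- upper
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (act(mid) > target_activity) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(1, hi)) break
  }
  (lo + hi) / 2
}
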