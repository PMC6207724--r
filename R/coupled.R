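# Coupled exchange-plus-catalysis model: slow interconversion between a
# catalytically silent, substrate-blind closed state and an open state that
# carries the two-site catalytic engine, with optional sequestration of the
# closed state by an allosteric inhibitor.
#
#   closed.D  <-- drug -->  closed  <-- exchange -->  open  <-> ES <-> ESS
#                                                        \kcat1/   \kcat2/
#
# At steady state the enzyme distributes over {closed.D, closed, open, ES,
# ESS}; observed turnover is kcat1*f_ES + kcat2*f_ESS per enzyme.

#' Configure the coupled open/close + catalysis model
#'
#' @param engine A [two_site_params()]: the catalytic engine of the fully
#'   open conformation.
#' @param k_close Closing rate, 1/s (at the assay temperature; the default
#'   follows the convention that closing is roughly twofold faster at the
#'   activity-assay temperature than in the binding experiments).
#' @param p_open Open-state fraction at equilibrium (give this or
#'   `k_open_close`).
#' @param k_open_close Open/close equilibrium constant `k_open/k_close`
#'   (`K_close_open` is its reciprocal).
#' @param drug Optional list `list(k_on = , k_off = )` for the inhibitor arm
#'   (intrinsic rates toward the closed state, uM and s units).
#' @param enzyme_uM Total enzyme concentration (matters only for free-drug
#'   depletion), uM.
#' @param kon_s Substrate association rate constant for the open state,
#'   1/(uM s). Dissociation rates follow from the engine's K_Ds. The
#'   default is fast enough that substrate binding is effectively at
#'   equilibrium relative to turnover.
#' @param temperature Free-text label stored for provenance.
#' @return List of class `"coupled_config"`.
#' @export
coupled_config <- function(engine, k_close, p_open = NULL,
                           k_open_close = NULL, drug = NULL,
                           enzyme_uM = 1e-3, kon_s = 100,
                           temperature = "35C") {
  stopifnot(inherits(engine, "two_site_params"), is_number(k_close),
            k_close > 0, is_number(kon_s), kon_s > 0, enzyme_uM >= 0)
  if (is.null(k_open_close)) {
    stopifnot(is_number(p_open), p_open > 0, p_open < 1)
    k_open_close <- p_open / (1 - p_open)
  } else {
    stopifnot(is_number(k_open_close), k_open_close > 0)
    if (!is.null(p_open) &&
        abs(p_open / (1 - p_open) - k_open_close) > 1e-6 * k_open_close)
      abort("p_open and k_open_close disagree", "confsel_argument_error")
  }
  if (!is.null(drug))
    stopifnot(is_number(drug$k_on), drug$k_on > 0,
              is_number(drug$k_off), drug$k_off > 0)
  structure(list(engine = engine, k_close = k_close,
                 k_open = k_open_close * k_close,
                 K_open_close = k_open_close,
                 K_close_open = 1 / k_open_close,
                 p_open = k_open_close / (1 + k_open_close),
                 drug = drug, enzyme_uM = enzyme_uM, kon_s = kon_s,
                 temperature = temperature),
            class = "coupled_config")
}

#' @export
print.coupled_config <- function(x, ...) {
  cat("<coupled_config>\n")
  cat(sprintf("  exchange: k_close = %.3g 1/s, k_open = %.3g 1/s (p_open = %.3f)\n",
              x$k_close, x$k_open, x$p_open))
  cat(sprintf("  engine:   kcat1 = %.3g, kcat2 = %.3g 1/s; K_D1 = %.3g, K_D2 = %.3g uM\n",
              x$engine$kcat1, x$engine$kcat2, x$engine$kd1, x$engine$kd2))
  if (!is.null(x$drug))
    cat(sprintf("  drug arm: k_on = %.3g 1/(uM s), k_off = %.3g 1/s (K_D = %.3g uM)\n",
                x$drug$k_on, x$drug$k_off, x$drug$k_off / x$drug$k_on))
  invisible(x)
}

# Rate matrix over states (closedD, closed, open, ES, ESS) at fixed free
# substrate S and free drug D (both uM). dx/dt = M %*% x.
coupled_rate_matrix <- function(config, substrate, drug_free = 0) {
  en <- config$engine
  kon_s <- config$kon_s
  koff1 <- kon_s * en$kd1
  koff2 <- if (is.finite(en$kd2)) kon_s * en$kd2 else Inf
  kon_d <- if (!is.null(config$drug)) config$drug$k_on else 0
  koff_d <- if (!is.null(config$drug)) config$drug$k_off else 1
  s2_on <- if (is.finite(koff2)) kon_s * substrate else 0
  s2_off <- if (is.finite(koff2)) koff2 + en$kcat2 else 0
  M <- matrix(0, 5, 5,
              dimnames = list(c("closedD", "closed", "open", "ES", "ESS"),
                              c("closedD", "closed", "open", "ES", "ESS")))
  add <- function(from, to, k) {
    M[from, from] <<- M[from, from] - k
    M[to, from] <<- M[to, from] + k
  }
  add("closed", "closedD", kon_d * drug_free)
  add("closedD", "closed", koff_d)
  add("closed", "open", config$k_open)
  add("open", "closed", config$k_close)
  add("open", "ES", kon_s * substrate)
  add("ES", "open", koff1 + en$kcat1)   # release + turnover both regenerate open
  add("ES", "ESS", s2_on)
  add("ESS", "ES", s2_off)
  M
}

solve_steady_state <- function(M) {
  A <- M
  A[nrow(A), ] <- 1            # replace one balance with normalisation
  b <- c(rep(0, nrow(A) - 1), 1)
  x <- tryCatch(solve(A, b), error = function(e)
    abort("singular coupled scheme; cannot solve steady state",
          "confsel_solver_error"))
  pmax(x, 0) / sum(pmax(x, 0))
}

relax_steady_state <- function(M, t_end = NULL) {
  if (is.null(t_end)) {
    ev <- abs(Re(eigen(M, only.values = TRUE)$values))
    slow <- min(ev[ev > 1e-9 * max(ev)])
    t_end <- 40 / slow
  }
  rhs <- function(t, y, p) list(as.numeric(M %*% y))
  y0 <- stats::setNames(c(0, 0.5, 0.5, 0, 0), rownames(M))
  sol <- deSolve::ode(y = y0, times = c(0, t_end / 2, t_end), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13, maxsteps = 5e5)
  x <- sol[nrow(sol), -1]
  x / sum(x)
}

#' Steady-state activity of the coupled model
#'
#' Solves the steady state of the linear five-state scheme at each
#' substrate concentration and returns the observed per-enzyme turnover
#' `kcat1*f_ES + kcat2*f_ESS`. The algebraic solution (null space of the
#' rate matrix) and an ODE-relaxation solution are both available and agree
#' to high precision; `method = "algebraic"` is the default.
#'
#' @param config A [coupled_config()].
#' @param substrate Substrate concentration(s), uM.
#' @param drug_free Free inhibitor concentration, uM (0 for no drug).
#' @param method `"algebraic"` or `"ode"`.
#' @return Object of class `"activity_prediction"`: data.frame `grid` with
#'   `substrate_uM`, `k_obs_s`, `p_open_ensemble` (open + ES + ESS
#'   fraction), plus a `fractions` matrix of steady-state species fractions
#'   (rows = substrate levels).
#' @export
steady_state_activity <- function(config, substrate, drug_free = 0,
                                  method = c("algebraic", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "coupled_config"), all(substrate >= 0),
            drug_free >= 0)
  fr <- t(vapply(substrate, function(s) {
    M <- coupled_rate_matrix(config, s, drug_free)
    if (method == "algebraic") solve_steady_state(M) else relax_steady_state(M)
  }, numeric(5)))
  colnames(fr) <- c("closedD", "closed", "open", "ES", "ESS")
  k_obs <- config$engine$kcat1 * fr[, "ES"] + config$engine$kcat2 * fr[, "ESS"]
  grid <- data.frame(substrate_uM = substrate, k_obs_s = k_obs,
                     p_open_ensemble = fr[, "open"] + fr[, "ES"] + fr[, "ESS"])
  structure(list(grid = grid, fractions = fr, method = method,
                 drug_free = drug_free),
            class = "activity_prediction")
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(sprintf("<activity_prediction> (%s solver, free drug %.3g uM)\n",
              x$method, x$drug_free))
  print(utils::head(x$grid, 8), row.names = FALSE)
  if (nrow(x$grid) > 8) cat(sprintf("... %d more rows\n", nrow(x$grid) - 8L))
  invisible(x)
}

#' Predicted activity curves for two full-length variants
#'
#' Runs [steady_state_activity()] for two configurations sharing the same
#' catalytic engine (e.g. wild type and an activating mutant) over one
#' substrate grid and reports, per level, the fold-suppression of each
#' variant relative to the fully open engine.
#'
#' @param config_a,config_b [coupled_config()]s.
#' @param substrate Substrate grid, uM.
#' @return data.frame with `substrate_uM`, `engine_s` (fully open rate,
#'   1/s), `k_obs_a`, `k_obs_b`, `suppression_a`, `suppression_b`.
#' @export
simulate_fulllength_curves <- function(config_a, config_b, substrate) {
  pa <- steady_state_activity(config_a, substrate)
  pb <- steady_state_activity(config_b, substrate)
  engine <- two_site_rate(substrate, config_a$engine)
  data.frame(substrate_uM = substrate, engine_s = engine,
             k_obs_a = pa$grid$k_obs_s, k_obs_b = pb$grid$k_obs_s,
             suppression_a = engine / pa$grid$k_obs_s,
             suppression_b = engine / pb$grid$k_obs_s)
}

coupled_activity_at_dose <- function(config, dose, substrate) {
  if (is.null(config$drug))
    abort("config has no drug arm", "confsel_argument_error")
  free_drug <- dose
  if (config$enzyme_uM > 0 && dose > 0) {
    # solve total = free + bound, bound = enzyme * f_closedD(free)
    bound_at <- function(Df) {
      fr <- steady_state_activity(config, substrate, drug_free = Df)$fractions
      config$enzyme_uM * fr[1, "closedD"]
    }
    g <- function(Df) Df + bound_at(Df) - dose
    free_drug <- stats::uniroot(g, c(0, dose), tol = 1e-12 * max(1, dose))$root
  }
  st <- steady_state_activity(config, substrate, drug_free = free_drug)
  list(k_obs = st$grid$k_obs_s[1], free_drug = free_drug,
       fractions = st$fractions[1, ])
}

#' Inhibition curve and predicted IC50 of the coupled model
#'
#' Re-solves the coupled steady state at each inhibitor dose, with the drug
#' sequestering the closed conformer, and extracts the half-inhibition
#' concentration by bisection on the dose axis. Free-drug depletion by the
#' enzyme is accounted for whenever `enzyme_uM > 0`.
#'
#' @param config A [coupled_config()] with a drug arm.
#' @param doses Total inhibitor doses for the reported curve, uM.
#' @param substrate Substrate concentration, uM.
#' @return List of class `"inhibition_curve"`: `curve` (data.frame
#'   `dose_uM`, `k_obs_s`, `pct_inhibition`), `basal` (1/s), `ic50` (uM).
#' @export
inhibition_curve <- function(config, doses, substrate) {
  stopifnot(all(doses >= 0))
  basal <- coupled_activity_at_dose(config, 0, substrate)$k_obs
  k_obs <- vapply(doses, function(d)
    coupled_activity_at_dose(config, d, substrate)$k_obs, numeric(1))
  act_of <- function(d) coupled_activity_at_dose(config, d, substrate)$k_obs
  hi <- max(max(doses), 1)
  while (act_of(hi) > basal / 2 && hi < 1e9) hi <- hi * 10
  ic50 <- if (act_of(hi) > basal / 2) Inf else
    stats::uniroot(function(d) act_of(d) - basal / 2, c(0, hi),
                   tol = 1e-10 * hi)$root
  structure(list(curve = data.frame(dose_uM = doses, k_obs_s = k_obs,
                                    pct_inhibition = 100 * (1 - k_obs / basal)),
                 basal = basal, ic50 = ic50, substrate_uM = substrate),
            class = "inhibition_curve")
}

#' @export
print.inhibition_curve <- function(x, ...) {
  cat(sprintf("<inhibition_curve> basal %.4g 1/s at %.3g uM substrate; IC50 = %.4g uM\n",
              x$basal, x$substrate_uM, x$ic50))
  invisible(x)
}

#' Thermodynamic linkage shift of the open/close equilibrium by an activator
#'
#' An activator that binds only the open conformation with dissociation
#' constant `K_A_open` pulls the equilibrium open:
#' `K_open_close_eff = K_open_close * (1 + activator / K_A_open)`. The
#' shift is monotone increasing in activator concentration, which is why
#' apparent IC50s of a closed-state binder rise in the presence of an
#' activating peptide.
#'
#' @param K_open_close Equilibrium constant without activator.
#' @param activator Activator concentration, uM (vectorised).
#' @param K_A_open Activator dissociation constant for the open state, uM.
#' @return Effective equilibrium constant(s).
#' @export
activator_shift <- function(K_open_close, activator, K_A_open) {
  stopifnot(is_number(K_open_close), K_open_close > 0, all(activator >= 0),
            is_number(K_A_open), K_A_open > 0)
  K_open_close * (1 + activator / K_A_open)
}
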