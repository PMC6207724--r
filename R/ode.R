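# Forward (mass-action) model of the conformational-selection scheme with
# full ligand depletion, used to generate stopped-flow traces and to
# cross-check the linearised eigenvalue analysis.

#' Analytic equilibrium of the binding scheme
#'
#' Species concentrations at equilibrium for given totals, allowing ligand
#' depletion. Free protein partitions between open and closed according to
#' `K_open_close`; the complex satisfies `closed_free * ligand_free /
#' complex = K_D` (intrinsic). The complex concentration is the root of the
#' quadratic obtained by eliminating the free species.
#'
#' @param scheme A [conf_sel_scheme()].
#' @param protein Total protein, uM.
#' @param ligand Total ligand, uM.
#' @return Named vector `c(open, closed, complex, ligand_free)` in uM.
#' @export
scheme_equilibrium <- function(scheme, protein, ligand) {
  stopifnot(inherits(scheme, "conf_sel_scheme"), protein >= 0, ligand >= 0)
  Koc <- scheme$K_open_close
  kd_app <- scheme$K_D * (1 + Koc)  # apparent K_D of total free protein
  # x = complex: (P - x)(L - x) = kd_app * x
  bq <- protein + ligand + kd_app
  x <- (bq - sqrt(bq^2 - 4 * protein * ligand)) / 2
  free <- protein - x
  c(open = free * Koc / (1 + Koc), closed = free / (1 + Koc),
    complex = x, ligand_free = ligand - x)
}

#' Simulate a stopped-flow mixing experiment (full nonlinear ODE)
#'
#' Integrates the mass-action kinetics of open <-> closed and
#' closed + L <-> closed.L with ligand depletion allowed, and returns the
#' fluorescence-like signal as a weighted sum of the species trajectories.
#' The default initial condition is the ligand-free protein at its
#' conformational equilibrium suddenly mixed with free ligand, which is the
#' association experiment; pass `init` to start elsewhere (e.g. a diluted
#' pre-equilibrated complex for a dissociation experiment).
#'
#' @param scheme A [conf_sel_scheme()].
#' @param protein_0 Total protein after mixing, uM.
#' @param ligand_0 Total ligand after mixing, uM.
#' @param t_grid Time points, seconds (>= 20 points, starting at >= 0).
#' @param fluorophore_weights Named signal coefficients
#'   `c(open=, closed=, complex=)`.
#' @param init Optional explicit initial state `c(open, closed, complex,
#'   ligand_free)` in uM overriding `protein_0`/`ligand_0`.
#' @return A data.frame of class `"sf_trace"` with columns `time_s`,
#'   `signal`; the species trajectories are in `attr(, "species")` and the
#'   inputs in `attr(, "meta")`.
#' @export
simulate_scheme <- function(scheme, protein_0, ligand_0, t_grid,
                            fluorophore_weights = c(open = 1.0, closed = 0.6,
                                                    complex = 0.25),
                            init = NULL) {
  stopifnot(inherits(scheme, "conf_sel_scheme"),
            length(t_grid) >= 20, all(diff(t_grid) > 0), t_grid[1] >= 0)
  w <- fluorophore_weights
  stopifnot(all(c("open", "closed", "complex") %in% names(w)))
  if (is.null(init)) {
    stopifnot(protein_0 >= 0, ligand_0 >= 0)
    init <- c(open = protein_0 * scheme$p_open,
              closed = protein_0 * scheme$p_closed,
              complex = 0, ligand_free = ligand_0)
  }
  rhs <- function(t, y, p) {
    ex <- p$k_close * y["open"] - p$k_open * y["closed"]
    bind <- p$k_on * y["closed"] * y["ligand_free"] - p$k_off * y["complex"]
    list(c(open = -ex, closed = ex - bind, complex = bind,
           ligand_free = -bind))
  }
  sol <- deSolve::ode(y = init, times = t_grid, func = rhs, parms = scheme,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    abort(sprintf("ODE integration failed (istate = %d)",
                  attr(sol, "istate")[1]), "confsel_solver_error")
  species <- as.data.frame(sol)
  names(species)[1] <- "time_s"
  signal <- w["open"] * species$open + w["closed"] * species$closed +
    w["complex"] * species$complex
  out <- data.frame(time_s = species$time_s, signal = as.numeric(signal))
  class(out) <- c("sf_trace", "data.frame")
  attr(out, "species") <- species
  attr(out, "meta") <- list(protein_uM = sum(init[c("open", "closed", "complex")]),
                            ligand_uM = init[["ligand_free"]] + init[["complex"]],
                            weights = w)
  out
}

#' Simulate the dilution (dissociation) experiment
#'
#' Pre-equilibrates protein and ligand at the stated concentrations, then
#' dilutes the mixture `dilution`-fold into buffer and follows the
#' relaxation. This mirrors the standard stopped-flow dissociation assay
#' (one volume of complex into ten volumes of buffer for an 11-fold
#' dilution).
#'
#' @param scheme A [conf_sel_scheme()].
#' @param protein_mix_uM,ligand_mix_uM Concentrations in the pre-incubated
#'   mixture, uM.
#' @param dilution Fold dilution (default 11).
#' @inheritParams simulate_scheme
#' @return An `"sf_trace"` (see [simulate_scheme()]).
#' @export
simulate_dissociation <- function(scheme, protein_mix_uM, ligand_mix_uM,
                                  t_grid, dilution = 11,
                                  fluorophore_weights = c(open = 1.0,
                                                          closed = 0.6,
                                                          complex = 0.25)) {
  eq <- scheme_equilibrium(scheme, protein_mix_uM, ligand_mix_uM)
  init <- eq / dilution
  simulate_scheme(scheme, protein_0 = NA, ligand_0 = NA, t_grid = t_grid,
                  fluorophore_weights = fluorophore_weights, init = init)
}
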