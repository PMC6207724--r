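# Seeded generators for every input the pipeline consumes. Each generator
# is a pure function of (scenario, seed) and returns a machine-readable
# `truth` element recording the generative parameters, so tests never
# hard-code generator internals.

#' Describe a chemical-shift scenario
#'
#' Parameters of a synthetic three-spectra experiment (open reference,
#' closed reference, fast-exchange-averaged query). Query peaks sit at
#' `(1 - f_closed_true) * open + f_closed_true * closed` plus isotropic
#' Gaussian noise in the nitrogen-weighted plane. Violations of each
#' retention filter can be planted deliberately.
#'
#' @param f_closed_true True closed-state fraction of the query.
#' @param n_residues Number of well-behaved (on-axis) residues.
#' @param b_range Range of axis lengths |B| (ppm, nitrogen-weighted plane);
#'   drawn log-uniformly.
#' @param noise_ppm Gaussian SD of the query-peak position (ppm, isotropic
#'   in the weighted plane; 0 for noiseless).
#' @param off_axis_fraction Fraction (of `n_residues`) of extra residues
#'   displaced 30 degrees off the axis (angle-filter violations).
#' @param n_small_b Extra residues with |B| planted below 0.03 ppm.
#' @param n_f_out Extra on-axis residues planted at fraction 1.3
#'   (range-filter violations).
#' @param n_excluded Extra residues flagged for the a-priori exclusion list.
#' @param seed RNG seed.
#' @return List of class `"shift_scenario"`.
#' @export
shift_scenario <- function(f_closed_true, n_residues, b_range = c(0.05, 0.6),
                           noise_ppm = 0, off_axis_fraction = 0,
                           n_small_b = 0, n_f_out = 0, n_excluded = 0,
                           seed = 1L) {
  stopifnot(f_closed_true >= 0, f_closed_true <= 1, n_residues >= 1,
            length(b_range) == 2, all(b_range > 0), noise_ppm >= 0,
            off_axis_fraction >= 0, n_small_b >= 0)
  structure(as.list(environment()), class = "shift_scenario")
}

#' Generate the three peak sets of a shift scenario
#'
#' @param scenario A [shift_scenario()].
#' @return List with [peak_set()]s `query`, `open_ref`, `closed_ref`, the
#'   suggested `exclusions` vector, and `truth` (generative parameters and
#'   planted-violation residue ids).
#' @export
gen_peak_sets <- function(scenario) {
  stopifnot(inherits(scenario, "shift_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    n_off <- round(sc$off_axis_fraction * sc$n_residues)
    n_tot <- sc$n_residues + n_off + sc$n_small_b + sc$n_f_out + sc$n_excluded
    ids <- seq_len(n_tot)
    kind <- rep(c("good", "off_axis", "small_b", "f_out", "excluded"),
                c(sc$n_residues, n_off, sc$n_small_b, sc$n_f_out, sc$n_excluded))
    b <- exp(stats::runif(n_tot, log(sc$b_range[1]), log(sc$b_range[2])))
    b[kind == "small_b"] <- stats::runif(sum(kind == "small_b"), 0.005, 0.025)
    phi <- stats::runif(n_tot, 0, 2 * pi)
    # axis components in the weighted plane, then back to raw ppm
    bh <- b * cos(phi)
    bn <- b * sin(phi) / NITROGEN_WEIGHT
    oh <- stats::runif(n_tot, 7.5, 9.5)
    on_ <- stats::runif(n_tot, 105, 130)
    f <- rep(sc$f_closed_true, n_tot)
    f[kind == "f_out"] <- 1.3
    qh <- oh + f * bh
    qn <- on_ + f * bn
    if (any(kind == "off_axis")) {
      i <- kind == "off_axis"
      # displace perpendicular to the axis so theta = 30 degrees
      perp_h <- -sin(phi[i]); perp_n <- cos(phi[i]) / NITROGEN_WEIGHT
      mag <- f[i] * b[i] * tan(30 * pi / 180)
      qh[i] <- qh[i] + mag * perp_h
      qn[i] <- qn[i] + mag * perp_n
    }
    if (sc$noise_ppm > 0) {
      qh <- qh + stats::rnorm(n_tot, 0, sc$noise_ppm)
      qn <- qn + stats::rnorm(n_tot, 0, sc$noise_ppm / NITROGEN_WEIGHT)
    }
    mk <- function(h, n, label)
      peak_set(data.frame(residue_id = ids, atom_group = "backbone-NH",
                          delta_h_ppm = h, delta_n_ppm = n), label)
    list(query = mk(qh, qn, "query"),
         open_ref = mk(oh, on_, "open_ref"),
         closed_ref = mk(oh + bh, on_ + bn, "closed_ref"),
         exclusions = ids[kind == "excluded"],
         truth = list(f_closed_true = sc$f_closed_true,
                      noise_ppm = sc$noise_ppm, seed = sc$seed,
                      planted = split(ids, kind)[setdiff(unique(kind), "good")],
                      good_ids = ids[kind == "good"]))
  })
}

#' Describe a stopped-flow scenario
#'
#' @param scheme A [conf_sel_scheme()].
#' @param protein_uM Protein concentration after mixing, uM.
#' @param ligand_uM Ligand concentration grid after mixing, uM.
#' @param noise_sd Gaussian trace noise as a fraction of the trace's signal
#'   span.
#' @param drift Linear baseline drift, signal units per second.
#' @param n_replicates Replicate shots per concentration.
#' @param dt,duration Sampling interval and trace length, seconds. The
#'   default duration covers several lifetimes of the slowest relaxation.
#' @param dilution Fold-dilution of the dissociation experiment.
#' @param fluorophore_weights Per-species signal coefficients.
#' @param seed RNG seed.
#' @return List of class `"stopflow_scenario"`.
#' @export
stopflow_scenario <- function(scheme, protein_uM = 0.45,
                              ligand_uM = c(5, 10, 15, 20, 30, 40, 50, 60),
                              noise_sd = 0.02, drift = 0, n_replicates = 5,
                              dt = 0.002, duration = NULL, dilution = 11,
                              fluorophore_weights = c(open = 1.0, closed = 0.6,
                                                      complex = 0.25),
                              seed = 1L) {
  stopifnot(inherits(scheme, "conf_sel_scheme"), protein_uM > 0,
            all(ligand_uM > 0), noise_sd >= 0, n_replicates >= 1, dt > 0)
  if (is.null(duration)) {
    slow <- min(eigen_rates(scheme, min(ligand_uM))$lambda_slow, scheme$k_off)
    duration <- 5 / slow
  }
  structure(as.list(environment()), class = "stopflow_scenario")
}

#' Generate stopped-flow binding and dissociation traces
#'
#' Association traces come from the full nonlinear ODE ([simulate_scheme()])
#' at every ligand concentration, with additive Gaussian noise (scaled to
#' the signal span) and optional linear drift; replicates use successive
#' noise draws. A dissociation experiment (pre-equilibrated 1:1 complex
#' diluted `dilution`-fold) is generated alongside.
#'
#' @param scenario A [stopflow_scenario()].
#' @return List with `binding` (list per concentration: `ligand_uM`,
#'   `replicates` list of traces, `mean` averaged trace), `dissociation`
#'   (same structure, single concentration), and `truth` (the generative
#'   scheme and settings).
#' @export
gen_stopflow <- function(scenario) {
  stopifnot(inherits(scenario, "stopflow_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    t_grid <- seq(0, sc$duration, by = sc$dt)
    noisy <- function(base) {
      span <- diff(range(base$signal))
      span <- if (span > 0) span else max(abs(base$signal), 1)
      lapply(seq_len(sc$n_replicates), function(r) {
        data.frame(time_s = base$time_s,
                   signal = base$signal + sc$drift * base$time_s +
                     stats::rnorm(nrow(base), 0, sc$noise_sd * span))
      })
    }
    binding <- lapply(sc$ligand_uM, function(L) {
      base <- simulate_scheme(sc$scheme, sc$protein_uM, L, t_grid,
                              sc$fluorophore_weights)
      reps <- noisy(base)
      list(ligand_uM = L, replicates = reps, mean = average_traces(reps))
    })
    # dissociation: equimolar pre-incubation at ~10x the apparent K_D so the
    # complex is mostly formed, then dilution
    mix <- max(10 * sc$scheme$K_D_obs, sc$protein_uM)
    t_diss <- seq(0, 6 / sc$scheme$k_off, length.out = 600)
    base_d <- simulate_dissociation(sc$scheme, mix, mix, t_diss, sc$dilution,
                                    sc$fluorophore_weights)
    reps_d <- noisy(base_d)
    list(binding = binding,
         dissociation = list(mix_uM = mix, dilution = sc$dilution,
                             replicates = reps_d,
                             mean = average_traces(reps_d)),
         truth = list(scheme = sc$scheme, protein_uM = sc$protein_uM,
                      ligand_uM = sc$ligand_uM, noise_sd = sc$noise_sd,
                      drift = sc$drift, seed = sc$seed))
  })
}

#' Generate a steady-state activity table
#'
#' Draws `n_rep` replicate observations of [two_site_rate()] with a given
#' coefficient of variation and tabulates mean and SD per substrate level.
#'
#' @param params A [two_site_params()].
#' @param substrate_uM Substrate grid, uM.
#' @param noise_cv Coefficient of variation of each observation (0 for
#'   noiseless; the `sd_s` column is then 0).
#' @param n_rep Replicates per level.
#' @param seed RNG seed.
#' @return List with `data` (data.frame `substrate_uM`, `k_obs_s`, `sd_s`)
#'   and `truth`.
#' @export
gen_activity <- function(params, substrate_uM, noise_cv = 0.05, n_rep = 3,
                         seed = 1L) {
  stopifnot(inherits(params, "two_site_params"), all(substrate_uM > 0),
            noise_cv >= 0, n_rep >= 1)
  with_seed(seed, {
    true <- two_site_rate(substrate_uM, params)
    if (noise_cv == 0) {
      data <- data.frame(substrate_uM = substrate_uM, k_obs_s = true, sd_s = 0)
    } else {
      obs <- vapply(true, function(v)
        stats::rnorm(n_rep, v, noise_cv * v), numeric(n_rep))
      data <- data.frame(substrate_uM = substrate_uM,
                         k_obs_s = colMeans(obs),
                         sd_s = apply(obs, 2, stats::sd))
    }
    list(data = data, truth = list(params = params, noise_cv = noise_cv,
                                   n_rep = n_rep, seed = seed))
  })
}

#' Generate a sigmoidal dose-response table
#'
#' @param ic50 Midpoint, uM.
#' @param slope Logistic width in log10-dose units.
#' @param asymptotes `c(floor, ceiling)` percent inhibition.
#' @param doses Dose grid, uM (log-spaced recommended).
#' @param noise_sd Additive Gaussian noise on the percent scale.
#' @param seed RNG seed.
#' @return List with `data` (data.frame `inhibitor_uM`, `pct_inhibition`,
#'   `sd`) and `truth`.
#' @export
gen_dose_response <- function(ic50, slope = 0.3, asymptotes = c(0, 100),
                              doses = 10^seq(-2, 2, length.out = 9),
                              noise_sd = 0, seed = 1L) {
  stopifnot(ic50 > 0, slope > 0, length(asymptotes) == 2,
            asymptotes[1] < asymptotes[2], all(doses > 0), noise_sd >= 0)
  with_seed(seed, {
    x <- log10(doses)
    y <- asymptotes[1] + diff(asymptotes) /
      (1 + exp(-(x - log10(ic50)) / slope))
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    list(data = data.frame(inhibitor_uM = doses, pct_inhibition = y,
                           sd = rep(noise_sd, length(doses))),
         truth = list(ic50 = ic50, slope = slope, asymptotes = asymptotes,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Preset landscapes and rate constants for the SHP2 study system
#'
#' Returns the conformational landscape and conformational-selection rate
#' constants for wild-type-like, E76D-like and E76K-like full-length SHP2
#' as characterised by NMR populations and stopped-flow kinetics: open
#' fractions 10.4%, 23.0% and 95.8%; wild type binds the allosteric
#' inhibitor with intrinsic k_on 0.44 1/(uM s) and k_off 0.029 1/s and
#' closes at 2.9 1/s (25 C). The E76K off-rate is 0.10 1/s and its
#' intrinsic on-rate follows from the observed ~sevenfold reduction of the
#' binding slope. The opening rate is always `K_open_close * k_close`.
#' Closing at the activity-assay temperature (35 C) is taken as twofold
#' faster, 5.8 1/s. For E76D (no stopped-flow data) the wild-type binding
#' constants are reused with its own landscape; the preset is labelled
#' illustrative for that variant.
#'
#' @param variant `"wt"`, `"e76d"` or `"e76k"`.
#' @return List with `p_open`, `K_open_close`, `scheme`
#'   ([conf_sel_scheme()], 25 C rates), `k_close_35C`.
#' @export
confsel_preset <- function(variant = c("wt", "e76d", "e76k")) {
  variant <- match.arg(variant)
  p_open <- c(wt = 0.104, e76d = 0.230, e76k = 0.958)[[variant]]
  Koc <- p_open / (1 - p_open)
  k_close <- 2.9
  wt_Koc <- 0.104 / 0.896
  wt_kon <- 0.44
  kon <- switch(variant,
                wt = wt_kon,
                e76d = wt_kon,
                # observed slope = WT observed slope / 7, corrected by the
                # E76K closed fraction via the fast-phase relation
                e76k = (wt_kon / (wt_Koc + 1) / 7) * (Koc + 1))
  koff <- switch(variant, wt = 0.029, e76d = 0.029, e76k = 0.10)
  list(variant = variant, p_open = p_open, K_open_close = Koc,
       scheme = conf_sel_scheme(k_open = Koc * k_close, k_close = k_close,
                                k_on = kon, k_off = koff),
       k_close_35C = 5.8)
}
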