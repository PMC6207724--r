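wt_scheme <- function() confsel_preset("wt")$scheme

test_that("scheme constructor derives equilibrium and affinity quantities", {
  s <- conf_sel_scheme(k_open = 0.3366, k_close = 2.9, k_on = 0.44,
                       k_off = 0.029)
  expect_equal(s$K_open_close, 0.3366 / 2.9)
  expect_equal(s$K_D, 0.029 / 0.44)
  expect_equal(s$K_D_obs, (s$K_open_close + 1) * s$K_D)
  expect_error(conf_sel_scheme(-1, 2.9, 0.44, 0.029))
})

test_that("relaxation rates match the rate-matrix eigenvalues", {
  s <- wt_scheme()
  for (L in c(0, 0.5, 2, 10, 60)) {
    er <- eigen_rates(s, L)
    M <- matrix(c(-s$k_close, s$k_close, 0,
                  s$k_open, -(s$k_open + s$k_on * L), s$k_on * L,
                  0, s$k_off, -s$k_off), 3, 3)
    ev <- sort(abs(Re(eigen(M, only.values = TRUE)$values)))
    expect_equal(er$lambda_fast, ev[3], tolerance = 1e-10)
    expect_equal(er$lambda_slow, ev[2], tolerance = 1e-10)
    # invariants: sum and product of the nonzero eigenvalues
    expect_equal(er$lambda_fast + er$lambda_slow,
                 s$k_open + s$k_close + s$k_on * L + s$k_off)
    expect_equal(er$lambda_fast * er$lambda_slow,
                 s$k_close * (s$k_on * L + s$k_off) + s$k_open * s$k_off)
  }
  # decoupled zero-ligand limit: exchange and dissociation relax separately
  er0 <- eigen_rates(s, 0)
  expect_equal(sort(c(er0$lambda_fast, er0$lambda_slow)),
               sort(c(s$k_open + s$k_close, s$k_off)), tolerance = 1e-12)
})

test_that("ODE traces conserve mass and relax to the algebraic equilibrium", {
  s <- wt_scheme()
  tr <- simulate_scheme(s, protein_0 = 0.5, ligand_0 = 2, seq(0, 300, 0.05))
  sp <- attr(tr, "species")
  expect_lt(max(abs(sp$open + sp$closed + sp$complex - 0.5)), 1e-9 * 0.5)
  expect_lt(max(abs(sp$ligand_free + sp$complex - 2)), 1e-9 * 2)
  eq <- equilibrium_oracle(s$k_open, s$k_close, s$k_on, s$k_off, 0.5, 2)
  last <- unlist(sp[nrow(sp), c("open", "closed", "complex", "ligand_free")])
  expect_equal(unname(last), unname(eq), tolerance = 1e-6)
  # no ligand, equilibrium start: flat trace
  tr0 <- simulate_scheme(s, 0.5, 0, seq(0, 10, 0.05))
  expect_lt(diff(range(tr0$signal)) / abs(mean(tr0$signal)), 1e-9)
})

test_that("exponential fits recover generative rates exactly without noise", {
  t <- seq(0, 3, by = 0.005)
  f1 <- fit_exponentials(data.frame(time_s = t,
                                    signal = 2 + 1.5 * exp(-2 * t)), 1)
  expect_equal(f1$rates, 2, tolerance = 1e-6)
  expect_equal(f1$amplitudes, 1.5, tolerance = 1e-6)
  t2 <- seq(0, 10, by = 0.005)
  f2 <- fit_exponentials(data.frame(
    time_s = t2, signal = 1 + 0.8 * exp(-5 * t2) + 0.4 * exp(-0.5 * t2)), 2)
  expect_equal(f2$rates, c(5, 0.5), tolerance = 1e-6)
  expect_equal(f2$amplitudes, c(0.8, 0.4), tolerance = 1e-6)
  # drift term
  f3 <- fit_exponentials(data.frame(
    time_s = t2, signal = 1 + 0.02 * t2 + 0.8 * exp(-1.2 * t2)),
    1, allow_drift = TRUE)
  expect_equal(f3$rates, 1.2, tolerance = 1e-5)
  expect_equal(f3$drift, 0.02, tolerance = 1e-5)
})

test_that("noisy replicate averages recover rates within three standard errors", {
  sc <- stopflow_scenario(wt_scheme(), protein_uM = 0.05, ligand_uM = 20,
                          noise_sd = 0.02, n_replicates = 5, dt = 0.002,
                          duration = 3, seed = 42)
  gen <- gen_stopflow(sc)
  fit <- fit_exponentials(gen$binding[[1]]$mean, 2)
  er <- eigen_rates(wt_scheme(), 20)
  se <- sqrt(diag(fit$cov)[c("rate1", "rate2")])
  expect_lt(abs(fit$rates[1] - er$lambda_fast), 3 * se[["rate1"]])
  expect_lt(abs(fit$rates[2] - er$lambda_slow), 3 * se[["rate2"]])
})

test_that("phase-count selection separates mono- from bi-exponential decays", {
  t <- seq(0, 8, by = 0.004)
  one <- data.frame(time_s = t, signal = 1 + exp(-1.5 * t))
  two <- data.frame(time_s = t,
                    signal = 1 + 0.7 * exp(-6 * t) + 0.5 * exp(-0.4 * t))
  expect_equal(as.integer(select_phase_count(one)), 1L)
  expect_equal(as.integer(select_phase_count(two)), 2L)
})

test_that("fast-phase line yields the population-corrected on-rate", {
  L <- c(2, 5, 10, 20, 40, 60)
  # line generated with the printed observed slope and the wild-type
  # equilibrium constant; the intrinsic on-rate must come out as 0.44
  Koc <- 0.1161
  d <- data.frame(ligand_uM = L, k_fast_s = 0.394 * L + 0.029)
  out <- fit_fast_phase(d, Koc)
  expect_equal(out$k_on, 0.394 * (Koc + 1), tolerance = 1e-9)
  expect_equal(out$k_on, 0.44, tolerance = 0.01 / 0.44)
  expect_equal(out$k_off, 0.029, tolerance = 1e-9)
  # a fully closed protein needs no correction
  expect_equal(fit_fast_phase(d, 0)$k_on, 0.394, tolerance = 1e-9)
  # decreasing rates are rejected
  d_bad <- data.frame(ligand_uM = L, k_fast_s = 5 - 0.01 * L)
  expect_error(fit_fast_phase(d_bad, Koc), class = "confsel_data_inconsistency")
})

test_that("slow-phase hyperbola has the printed limits and round-trips", {
  # zero-ligand limit is the off-rate; saturation is the closing rate
  expect_equal(slow_phase_rate(0, 2.9, 0.3366, 0.44, 0.029), 0.029)
  expect_equal(slow_phase_rate(1e9, 2.9, 0.3366, 0.44, 0.029), 2.9,
               tolerance = 1e-6)
  L <- c(1, 3, 6, 12, 25, 50, 100)
  d <- data.frame(ligand_uM = L,
                  k_slow_s = slow_phase_rate(L, 2.9, 0.3366, 0.44, 0.029))
  out <- fit_slow_phase(d, 0.44, 0.029)
  expect_equal(out$k_close, 2.9, tolerance = 1e-6)
  expect_equal(out$k_open, 0.3366, tolerance = 1e-4)
  # flat data are unidentifiable
  d_flat <- data.frame(ligand_uM = L, k_slow_s = rep(2.9, 7))
  expect_error(fit_slow_phase(d_flat, 0.44, 0.029),
               class = "confsel_unidentifiable")
})

test_that("dissociation fits return the off-rate when rebinding is negligible", {
  t <- seq(0, 250, length.out = 500)
  direct <- data.frame(time_s = t, signal = 0.2 + 0.8 * exp(-0.029 * t))
  expect_equal(fit_dissociation(direct)$k_off, 0.029, tolerance = 1e-6)
  s <- wt_scheme()
  # dilute regime: post-dilution ligand far below the apparent K_D
  lo <- fit_dissociation(simulate_dissociation(s, 0.02, 0.02, t, 11))
  expect_equal(lo$k_off, s$k_off, tolerance = 0.05)
  # rebinding regime: concentrations near the apparent K_D bias upward
  hi <- fit_dissociation(simulate_dissociation(s, 1.0, 1.0, t, 11))
  expect_gt(hi$k_off, s$k_off * 1.5)
})

test_that("apparent affinity reproduces the printed consistency calculations", {
  # wild type: 10.4% open, k_on 0.44, k_off 0.029 -> 0.074 uM
  Koc <- equilibrium_from_population(1 - 0.104)
  s <- conf_sel_scheme(Koc * 2.9, 2.9, 0.44, 0.029)
  expect_equal(apparent_kd(s)$kd_obs, 0.074, tolerance = 0.003 / 0.074)
  # no open state: the apparent and intrinsic affinities coincide
  s0 <- conf_sel_scheme(1e-9, 2.9, 0.44, 0.029)
  expect_equal(apparent_kd(s0)$kd_obs, 0.029 / 0.44, tolerance = 1e-6)
  # activating mutant: 95.8% open, sevenfold-reduced observed slope,
  # k_off 0.10 -> calculated 1.5 +/- 0.9 uM
  Koc_k <- equilibrium_from_population(1 - 0.958)
  slope_k <- (0.44 / (Koc + 1)) / 7
  sk <- conf_sel_scheme(Koc_k * 2.9, 2.9, slope_k * (Koc_k + 1), 0.10)
  expect_lt(abs(apparent_kd(sk)$kd_obs - 1.5), 0.9)
})

test_that("first-order error propagation agrees with Monte-Carlo resampling", {
  se <- list(k_open = 0.02, k_close = 0.1, k_on = 0.01, k_off = 0.001)
  s <- conf_sel_scheme(0.3366, 2.9, 0.44, 0.029, se = se)
  kd <- apparent_kd(s, n_mc = 4000, seed = 99)
  expect_lt(abs(kd$se_linear - kd$se_mc) / kd$se_mc, 0.25)
})
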