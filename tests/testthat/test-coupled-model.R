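# The engine parameters used throughout are illustrative: chosen so the
# fully open engine turns over at roughly the basal rate reported for the
# open-like variants at 500 uM substrate, not a fit to any published table.

test_that("fully open configuration reproduces the bare catalytic engine", {
  en <- wt_engine()
  cfg <- coupled_config(en, k_close = 5.8, p_open = 1 - 1e-9)
  s_grid <- c(1, 10, 100, 500, 2000)
  pred <- steady_state_activity(cfg, s_grid)
  # kon_s default is fast; the Briggs-Haldane correction is ~kcat1/(kon_s*kd1)
  expect_equal(pred$grid$k_obs_s, two_site_rate(s_grid, en), tolerance = 0.01)
})

test_that("algebraic, ODE-relaxation and closed-form chain solutions agree", {
  en <- wt_engine()
  cfg <- coupled_config(en, k_close = 5.8, p_open = 0.104)
  s_grid <- 10^seq(0, 3.3, length.out = 20)
  alg <- steady_state_activity(cfg, s_grid, method = "algebraic")
  ode <- steady_state_activity(cfg, s_grid, method = "ode")
  expect_equal(alg$grid$k_obs_s, ode$grid$k_obs_s, tolerance = 1e-6)
  chain <- vapply(s_grid, function(s)
    chain_steady_state(cfg$K_open_close, cfg$k_close, en$kcat1, en$kcat2,
                       en$kd1, en$kd2, cfg$kon_s, s)$k_obs, numeric(1))
  expect_equal(alg$grid$k_obs_s, chain, tolerance = 1e-9)
  expect_lt(max(abs(rowSums(alg$fractions) - 1)), 1e-9)
})

test_that("dual solvers agree across randomised parameter draws", {
  set.seed(314)
  for (i in 1:40) {
    en <- two_site_params(runif(1, 50, 500), runif(1, 10, 100),
                          runif(1, 100, 2000), runif(1, 500, 8000))
    cfg <- coupled_config(en, k_close = runif(1, 1, 20),
                          p_open = runif(1, 0.02, 0.98),
                          kon_s = runif(1, 10, 200))
    s <- 10^runif(1, 0, 3.3)
    a <- steady_state_activity(cfg, s, method = "algebraic")$grid$k_obs_s
    o <- steady_state_activity(cfg, s, method = "ode")$grid$k_obs_s
    expect_equal(a, o, tolerance = 1e-6)
  }
})

test_that("the exchange dead end pins closed:open to its equilibrium ratio", {
  # the closed state touches the network through one edge only, so at
  # steady state that edge carries no net flux at ANY exchange rate: the
  # suppression relative to the open engine is bounded by 1/p_open and the
  # low-substrate limit is p_open * engine
  en <- wt_engine()
  s_grid <- 10^seq(-1, 3.3, length.out = 25)
  for (kc in c(0.05, 5.8, 5000)) {   # slow, measured, fast exchange
    cfg <- coupled_config(en, k_close = kc, p_open = 0.104)
    pred <- steady_state_activity(cfg, s_grid)
    ratio <- pred$fractions[, "closed"] / pred$fractions[, "open"]
    expect_equal(ratio, rep(cfg$K_close_open, length(s_grid)),
                 tolerance = 1e-9)
    open_chain <- vapply(s_grid, function(s)
      chain_steady_state(1e12, kc, en$kcat1, en$kcat2, en$kd1, en$kd2,
                         cfg$kon_s, s)$k_obs, numeric(1))
    suppression <- open_chain / pred$grid$k_obs_s
    expect_true(all(suppression <= 1 / cfg$p_open + 1e-9))
    expect_true(all(suppression >= 1 - 1e-9))
  }
  # sub-saturating substrate: activity approaches p_open * two_site_rate
  cfg <- coupled_config(en, k_close = 5.8, p_open = 0.104)
  s_small <- c(0.5, 1, 2)   # far below KD1 * (1 + K_close/open)
  pred <- steady_state_activity(cfg, s_small)
  expect_equal(pred$grid$k_obs_s,
               cfg$p_open * two_site_rate(s_small, en), tolerance = 0.01)
})

test_that("predicted activity is ordered by the open population", {
  en <- wt_engine()
  s_grid <- 10^seq(0, 3.3, length.out = 10)
  curves <- simulate_fulllength_curves(
    coupled_config(en, k_close = 5.8, p_open = 0.104),
    coupled_config(en, k_close = 5.8, p_open = 0.230), s_grid)
  expect_true(all(curves$k_obs_a < curves$k_obs_b))
  expect_true(all(curves$k_obs_b < curves$engine_s))
  # monotone in p_open
  p_opens <- c(0.05, 0.2, 0.5, 0.9)
  at500 <- vapply(p_opens, function(p)
    steady_state_activity(coupled_config(en, 5.8, p_open = p),
                          500)$grid$k_obs_s, numeric(1))
  expect_true(all(diff(at500) > 0))
})

test_that("inhibition curve is monotone and IC50 matches the apparent K_D", {
  en <- wt_engine()
  drug <- list(k_on = 0.44, k_off = 0.029)
  cfg <- coupled_config(en, k_close = 5.8, p_open = 0.104, drug = drug,
                        enzyme_uM = 1e-5)
  doses <- c(0, 10^seq(-3, 1, length.out = 9))
  # low substrate so catalysis does not perturb the binding equilibrium
  inh <- inhibition_curve(cfg, doses, substrate = 0.5)
  expect_equal(inh$curve$k_obs_s[1], inh$basal, tolerance = 1e-6)
  expect_true(all(diff(inh$curve$k_obs_s) < 0))
  kd_obs <- (cfg$K_open_close + 1) * drug$k_off / drug$k_on
  expect_equal(inh$ic50, kd_obs, tolerance = 0.02)
})

test_that("free-drug depletion raises the apparent IC50 at high enzyme", {
  en <- wt_engine()
  drug <- list(k_on = 0.44, k_off = 0.029)
  lo <- inhibition_curve(coupled_config(en, 5.8, p_open = 0.104, drug = drug,
                                        enzyme_uM = 1e-5),
                         c(0.01, 0.1), substrate = 0.5)
  hi <- inhibition_curve(coupled_config(en, 5.8, p_open = 0.104, drug = drug,
                                        enzyme_uM = 1.0),
                         c(0.01, 0.1), substrate = 0.5)
  expect_gt(hi$ic50, lo$ic50 * 2)
})

test_that("an open-state activator shifts the equilibrium and the IC50", {
  expect_equal(activator_shift(0.116, 0, 5), 0.116)
  expect_equal(activator_shift(0.116, 5, 5), 0.232)
  shifted <- activator_shift(0.116, c(0, 1, 5, 20, 100), 5)
  expect_true(all(diff(shifted) > 0))
  en <- wt_engine()
  drug <- list(k_on = 0.44, k_off = 0.029)
  ic50s <- vapply(c(0, 5, 25), function(act) {
    cfg <- coupled_config(en, k_close = 5.8,
                          k_open_close = activator_shift(0.116, act, 5),
                          drug = drug, enzyme_uM = 1e-5)
    inhibition_curve(cfg, c(0.05, 0.5), substrate = 0.5)$ic50
  }, numeric(1))
  expect_true(all(diff(ic50s) > 0))
})
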