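test_that("combined chemical-shift perturbation follows the weighted norm", {
  a <- pk(10, 8.00, 120.0)
  expect_identical(csp(a, a), 0)
  expect_equal(csp(pk(10, 8.0, 120.0), pk(10, 8.0, 121.0)), 0.15)
  expect_equal(csp(pk(10, 8.0, 120.0), pk(10, 8.03, 120.2)), 0.04242641,
               tolerance = 1e-6)
  expect_error(csp(pk(10, 8, 120), pk(11, 8, 120)), "different keys")
})

test_that("projection recovers the fractional position along the axis", {
  o <- pk(1, 8.00, 120.0); cl <- pk(1, 8.20, 121.0)
  # endpoints
  expect_equal(project_residue(cl, o, cl)$f, 1)
  expect_equal(project_residue(cl, o, cl)$theta_deg, 0)
  expect_equal(project_residue(o, o, cl)$f, 0)
  # hand-worked interior point: query displacement is exactly 0.75 of the axis
  pr <- project_residue(pk(1, 8.15, 120.75), o, cl)
  expect_equal(pr$f, 0.75, tolerance = 1e-12)
  expect_equal(pr$theta_deg, 0, tolerance = 1e-6)
  # printed-orientation convention measures from the closed reference (F - 1)
  pr2 <- project_residue(pk(1, 8.15, 120.75), o, cl, convention = "printed")
  expect_equal(pr2$f, -0.25, tolerance = 1e-12)
  # degenerate axis
  expect_error(project_residue(o, o, o), class = "confsel_degenerate_axis")
})

test_that("projection is linear in the mixing fraction and scale invariant", {
  set.seed(41)
  for (rep in 1:25) {
    oh <- runif(1, 7, 10); on_ <- runif(1, 105, 130)
    dh <- runif(1, -0.5, 0.5); dn <- runif(1, -3, 3)
    if (abs(dh) + abs(dn) < 1e-3) dh <- 0.1
    p <- runif(1)
    o <- pk(1, oh, on_); cl <- pk(1, oh + dh, on_ + dn)
    q <- pk(1, oh + p * dh, on_ + p * dn)
    expect_equal(project_residue(q, o, cl)$f, p, tolerance = 1e-9)
    # common positive rescaling of both displacement vectors
    s <- runif(1, 0.1, 5)
    cl2 <- pk(1, oh + s * dh, on_ + s * dn)
    q2 <- pk(1, oh + s * p * dh, on_ + s * p * dn)
    pr1 <- project_residue(q, o, cl)
    pr2 <- project_residue(q2, o, cl2)
    expect_equal(pr2$f, pr1$f, tolerance = 1e-9)
    expect_equal(pr2$theta_deg, pr1$theta_deg, tolerance = 1e-6)
  }
})

make_proj_table <- function() {
  # one well-behaved residue per filter class plus clean ones
  data.frame(
    residue_id = 1:6,
    atom_group = "backbone-NH",
    a_norm = c(0.10, 0.10, 0.015, 0.08, 0.21, 0.30),
    b_norm = c(0.20, 0.20, 0.020, 0.08, 0.20, 0.30),
    theta_deg = c(0, 0, 0, 12, 0, 0),
    f = c(0.50, 0.50, 0.75, 0.9, 1.05, 1.0)
  )
}

test_that("retention filters record one primary exclusion reason each", {
  p <- filter_residues(make_proj_table(), exclusions = 2L)
  expect_equal(p$reason[p$residue_id == 2], "excluded")
  expect_equal(p$reason[p$residue_id == 3], "min_b")   # |B| = 0.02 < 0.03
  expect_equal(p$reason[p$residue_id == 4], "angle")   # 12 deg > 10 deg
  expect_equal(p$reason[p$residue_id == 5], "f_range") # F = 1.05
  expect_true(all(p$passed_filters[p$residue_id %in% c(1, 6)]))
  expect_true(all(is.na(p$reason[p$passed_filters])))
  # boundary values are kept: F = 1 exactly passes
  expect_true(p$passed_filters[p$residue_id == 6])
  expect_error(filter_residues(make_proj_table()[3, ]),
               class = "confsel_empty_set")
})

test_that("filter outcome does not depend on residue order", {
  tab <- make_proj_table()
  a <- filter_residues(tab, exclusions = 2L)
  b <- filter_residues(tab[sample(nrow(tab)), ], exclusions = 2L)
  b <- b[order(b$residue_id), ]
  expect_equal(a$passed_filters, b$passed_filters)
  expect_equal(a$reason, b$reason)
})

test_that("closed-form MLE matches the grid/refined likelihood maximiser", {
  for (seed in 1:6) {
    fx <- random_projection_fixture(n = 20, f_true = 0.6, noise = 0.01,
                                    seed = seed)
    est <- estimate_population(fx)
    oracle <- grid_mle(fx$b_norm, fx$f * fx$b_norm)
    expect_equal(est$f_hat_raw, oracle$f, tolerance = 1e-6)
    expect_equal(est$sigma_hat, oracle$sigma, tolerance = 1e-5)
    expect_equal(est$log_likelihood, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("noiseless collinear residues are recovered exactly", {
  fx <- random_projection_fixture(n = 12, f_true = 0.3, noise = 0, seed = 7)
  est <- estimate_population(fx)
  expect_equal(est$f_hat, 0.3, tolerance = 1e-12)
  expect_equal(est$sigma_hat, 0, tolerance = 1e-12)
  expect_error(estimate_population(fx[1, , drop = FALSE]),
               class = "confsel_insufficient_data")
})

test_that("observed-information cross term vanishes at the optimum", {
  fx <- random_projection_fixture(n = 25, f_true = 0.8, noise = 0.008,
                                  seed = 11)
  est <- estimate_population(fx)
  b <- fx$b_norm; y <- fx$f * b
  ll <- function(f, s) sum(-0.5 * log(2 * pi * s^2) - (b * f - y)^2 / (2 * s^2))
  h <- 1e-5
  f0 <- est$f_hat_raw; s0 <- est$sigma_hat
  cross <- (ll(f0 + h, s0 + h) - ll(f0 + h, s0 - h) -
              ll(f0 - h, s0 + h) + ll(f0 - h, s0 - h)) / (4 * h^2)
  d2f <- (ll(f0 + h, s0) - 2 * ll(f0, s0) + ll(f0 - h, s0)) / h^2
  d2s <- (ll(f0, s0 + h) - 2 * ll(f0, s0) + ll(f0, s0 - h)) / h^2
  expect_lt(abs(cross) / sqrt(abs(d2f) * abs(d2s)), 1e-3)
  # and the analytic variances match the numeric Hessian inverse
  expect_equal(est$var_f, -1 / d2f, tolerance = 1e-3)
  expect_equal(est$var_sigma, -1 / d2s, tolerance = 1e-3)
})

test_that("Hessian standard error is calibrated against replicate spread", {
  n_rep <- 300
  f_hats <- numeric(n_rep)
  se_hats <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    fx <- random_projection_fixture(n = 25, f_true = 0.5, noise = 0.01,
                                    seed = 1000 + r)
    est <- estimate_population(fx)
    f_hats[r] <- est$f_hat_raw
    se_hats[r] <- est$se_f
  }
  expect_lt(abs(mean(f_hats) - 0.5), 3 * sd(f_hats) / sqrt(n_rep))
  expect_lt(abs(mean(se_hats) - sd(f_hats)) / sd(f_hats), 0.2)
})

test_that("equilibrium constant from the closed fraction", {
  expect_equal(equilibrium_from_population(0.5), 1.0)
  # printed open fractions for the wild type and the activating mutant
  expect_equal(equilibrium_from_population(0.896), 0.1161, tolerance = 1e-3)
  expect_equal(equilibrium_from_population(0.042), 22.81, tolerance = 1e-3)
  expect_error(equilibrium_from_population(0), class = "confsel_boundary")
  expect_error(equilibrium_from_population(1), class = "confsel_boundary")
})

test_that("peak-set projection joins on keys and flags unmatched peaks", {
  gen <- gen_peak_sets(shift_scenario(0.4, n_residues = 8, seed = 3))
  q <- as.data.frame(gen$query)
  q_extra <- rbind(q, data.frame(residue_id = 99L, atom_group = "backbone-NH",
                                 delta_h_ppm = 8, delta_n_ppm = 120))
  expect_message(
    proj <- project_peak_sets(q_extra, gen$open_ref, gen$closed_ref),
    "dropped 1 query peak")
  expect_equal(nrow(proj), 8)
  expect_equal(proj$f, rep(0.4, 8), tolerance = 1e-9)
})
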