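# Shared fixture builders and independent oracles used across test files.

pk <- function(id, h, n, grp = "backbone-NH")
  list(residue_id = id, atom_group = grp, delta_h = h, delta_n = n)

# Independent brute-force maximiser of the pooled-projection log likelihood:
# dense grid over (F, sigma) followed by local refinement with optim. Used
# as the oracle for the closed-form estimator; works from the raw (b, y)
# pairs and never calls estimate_population().
grid_mle <- function(b, y, f_range = c(-1, 2)) {
  loglik <- function(f, s)
    sum(-0.5 * log(2 * pi * s^2) - (b * f - y)^2 / (2 * s^2))
  f_grid <- seq(f_range[1], f_range[2], length.out = 301)
  s_grid <- exp(seq(log(1e-5), log(1), length.out = 201))
  best <- c(f = NA, s = NA, ll = -Inf)
  for (f in f_grid) {
    ll <- vapply(s_grid, function(s) loglik(f, s), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best["ll"]) best <- c(f = f, s = s_grid[i], ll = ll[i])
  }
  o <- optim(c(best[["f"]], log(best[["s"]])),
             function(p) -loglik(p[1], exp(p[2])),
             method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  list(f = o$par[1], sigma = exp(o$par[2]), loglik = -o$value)
}

# Random on-axis projection fixture in (b, y) form with Gaussian axial noise
random_projection_fixture <- function(n, f_true, noise, seed) {
  set.seed(seed)
  b <- exp(runif(n, log(0.05), log(0.6)))
  y <- b * f_true + rnorm(n, 0, noise)
  data.frame(b_norm = b, f = y / b)
}

# Algebraic three-state equilibrium used as the ODE long-time oracle
# (quadratic in the complex concentration, independent derivation)
equilibrium_oracle <- function(k_open, k_close, k_on, k_off, P, L) {
  Koc <- k_open / k_close
  kd_app <- (k_off / k_on) * (1 + Koc)
  bq <- P + L + kd_app
  x <- (bq - sqrt(bq^2 - 4 * P * L)) / 2
  c(open = (P - x) * Koc / (1 + Koc), closed = (P - x) / (1 + Koc),
    complex = x, ligand_free = L - x)
}

# Closed-form steady state of the open catalytic chain with a dead-end
# closed branch (and optional drug-bound dead end), via effective
# Briggs-Haldane ratios; independent of the matrix solver in the package.
chain_steady_state <- function(k_open_close, k_close, kcat1, kcat2, kd1, kd2,
                               kon_s, S, drug_ratio = 0) {
  # relative populations with open = 1
  closed <- 1 / k_open_close
  closedD <- closed * drug_ratio
  e1 <- kon_s * S / (kon_s * kd1 + kcat1)
  e2 <- if (is.finite(kd2)) e1 * kon_s * S / (kon_s * kd2 + kcat2) else 0
  tot <- closedD + closed + 1 + e1 + e2
  list(k_obs = (kcat1 * e1 + kcat2 * e2) / tot,
       fractions = c(closedD = closedD, closed = closed, open = 1,
                     ES = e1, ESS = e2) / tot)
}

wt_engine <- function() two_site_params(300, 260, 600, 4000)
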