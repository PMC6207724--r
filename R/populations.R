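# Chemical-shift projection analysis: estimate a two-state population from
# the position of fast-exchange-averaged peaks along the line connecting the
# pure open-state and pure closed-state reference shifts, then pool residues
# by maximum likelihood.

scaled_vec <- function(dh, dn, w) c(dh, w * dn)

#' Project one residue's query peak onto the open-closed axis
#'
#' Builds the 2-vectors in the (1H, 0.15*15N) ppm plane and computes the
#' fractional position of the query peak along the open-to-closed axis.
#' Under the default `"closed"` convention, the displacement A is measured
#' from the open reference and B is the closed-minus-open axis, so that
#' F = |A| cos(theta) / |B| is the fraction of the closed state: F = 0 at
#' the open reference and F = 1 at the closed reference, with theta the
#' deviation of the query displacement from the axis. The `"printed"`
#' convention instead measures A from the closed reference, which yields
#' F' = F - 1 for on-axis peaks; it is provided for cross-checking.
#'
#' @param query,open_ref,closed_ref Peaks of the same `(residue_id,
#'   atom_group)` key (see [csp()] for accepted representations).
#' @param n_weight 15N axis weight.
#' @param convention `"closed"` (default) or `"printed"`, see Details.
#' @return A list of class `"residue_projection"` with elements
#'   `residue_id`, `atom_group`, `vec_a`, `vec_b`, `a_norm`, `b_norm`
#'   (ppm), `theta_deg` in \[0, 180\], and the fraction `f`.
#' @export
project_residue <- function(query, open_ref, closed_ref,
                            n_weight = NITROGEN_WEIGHT,
                            convention = c("closed", "printed")) {
  convention <- match.arg(convention)
  q <- peak_fields(query); o <- peak_fields(open_ref); c_ <- peak_fields(closed_ref)
  check_same_key(q, o); check_same_key(q, c_)
  b <- scaled_vec(c_$delta_h - o$delta_h, c_$delta_n - o$delta_n, n_weight)
  ref <- if (convention == "closed") o else c_
  a <- scaled_vec(q$delta_h - ref$delta_h, q$delta_n - ref$delta_n, n_weight)
  b_norm <- sqrt(sum(b^2)); a_norm <- sqrt(sum(a^2))
  if (b_norm == 0)
    abort(sprintf("residue %s: open and closed references coincide (|B| = 0)",
                  q$residue_id %||% "?"), "confsel_degenerate_axis")
  if (a_norm == 0) {
    cos_theta <- 1; theta <- 0
  } else {
    cos_theta <- max(-1, min(1, sum(a * b) / (a_norm * b_norm)))
    theta <- acos(cos_theta) * 180 / pi
  }
  structure(list(residue_id = q$residue_id, atom_group = q$atom_group,
                 vec_a = a, vec_b = b, a_norm = a_norm, b_norm = b_norm,
                 theta_deg = theta, f = a_norm * cos_theta / b_norm,
                 convention = convention),
            class = "residue_projection")
}

#' Project matched peaks of three spectra onto the open-closed axis
#'
#' Joins the query, open-reference and closed-reference peak sets on
#' `(residue_id, atom_group)` and projects every matched residue. Residues
#' present in only some of the three spectra are dropped with a message
#' reporting the count. Residues whose references coincide (degenerate axis,
#' |B| = 0) are retained with `b_norm = 0` and `f = NA` so that the |B|
#' filter removes them with an explicit reason.
#'
#' @param query,open_ref,closed_ref [peak_set()]s (or data.frames coercible
#'   to one).
#' @inheritParams project_residue
#' @return A data.frame of class `"projection_table"` with one row per
#'   matched residue: `residue_id`, `atom_group`, `a_norm`, `b_norm`,
#'   `theta_deg`, `f`.
#' @export
project_peak_sets <- function(query, open_ref, closed_ref,
                              n_weight = NITROGEN_WEIGHT,
                              convention = c("closed", "printed")) {
  convention <- match.arg(convention)
  q <- peak_set(query, "query"); o <- peak_set(open_ref, "open_ref")
  cl <- peak_set(closed_ref, "closed_ref")
  m <- merge(merge(as.data.frame(q), as.data.frame(o),
                   by = c("residue_id", "atom_group"),
                   suffixes = c("", ".open")),
             as.data.frame(cl), by = c("residue_id", "atom_group"),
             suffixes = c("", ".closed"))
  n_drop <- nrow(q) - nrow(m)
  if (n_drop > 0)
    message(sprintf("dropped %d query peak(s) without a match in both references",
                    n_drop))
  if (nrow(m) == 0)
    abort("no residues shared by query and both references", "confsel_empty_set")
  rows <- lapply(seq_len(nrow(m)), function(i) {
    qi <- list(residue_id = m$residue_id[i], atom_group = m$atom_group[i],
               delta_h = m$delta_h_ppm[i], delta_n = m$delta_n_ppm[i])
    oi <- modifyList(qi, list(delta_h = m$delta_h_ppm.open[i],
                              delta_n = m$delta_n_ppm.open[i]))
    ci <- modifyList(qi, list(delta_h = m$delta_h_ppm.closed[i],
                              delta_n = m$delta_n_ppm.closed[i]))
    pr <- tryCatch(project_residue(qi, oi, ci, n_weight, convention),
                   confsel_degenerate_axis = function(e) NULL)
    if (is.null(pr))
      data.frame(residue_id = qi$residue_id, atom_group = qi$atom_group,
                 a_norm = NA_real_, b_norm = 0, theta_deg = NA_real_,
                 f = NA_real_)
    else
      data.frame(residue_id = pr$residue_id, atom_group = pr$atom_group,
                 a_norm = pr$a_norm, b_norm = pr$b_norm,
                 theta_deg = pr$theta_deg, f = pr$f)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_id, out$atom_group), ]
  rownames(out) <- NULL
  class(out) <- c("projection_table", "data.frame")
  attr(out, "convention") <- convention
  out
}

#' Apply the residue retention filters
#'
#' Only residues that report cleanly on two-state averaging enter the
#' population estimate. A residue is retained when it is (in this order of
#' precedence for the recorded exclusion reason):
#' \enumerate{
#'   \item not on the a-priori exclusion list (e.g. residues within 15 A of
#'     the drug-binding site, whose shifts respond to the ligand itself);
#'   \item displaced enough to measure: `b_norm >= min_b_ppm`;
#'   \item collinear with the open-closed axis: `theta_deg <= angle_tol_deg`;
#'   \item inside the physical range: `0 <= f <= 1`.
#' }
#' Every dropped residue carries exactly one primary `reason` from
#' `"excluded"`, `"min_b"`, `"angle"`, `"f_range"`.
#'
#' @param projections A `projection_table` from [project_peak_sets()] (or a
#'   data.frame with columns `b_norm`, `theta_deg`, `f`).
#' @param exclusions Integer vector of residue_ids to drop a priori.
#' @param angle_tol_deg Collinearity tolerance, degrees (default 10).
#' @param min_b_ppm Minimum axis length, ppm (default 0.03).
#' @return The table with added logical `passed_filters` and character
#'   `reason` columns. Errors if no residue survives.
#' @export
filter_residues <- function(projections, exclusions = integer(),
                            angle_tol_deg = 10, min_b_ppm = 0.03) {
  stopifnot(angle_tol_deg > 0, min_b_ppm > 0)
  p <- as.data.frame(projections)
  reason <- rep(NA_character_, nrow(p))
  excl <- p$residue_id %in% exclusions
  bad_b <- !is.na(p$b_norm) & p$b_norm < min_b_ppm | p$b_norm == 0
  bad_angle <- is.na(p$theta_deg) | p$theta_deg > angle_tol_deg
  bad_f <- is.na(p$f) | p$f < 0 | p$f > 1
  reason[bad_f] <- "f_range"
  reason[bad_angle] <- "angle"
  reason[bad_b] <- "min_b"
  reason[excl] <- "excluded"
  p$passed_filters <- is.na(reason)
  p$reason <- reason
  if (!any(p$passed_filters))
    abort("no residues retained after filtering", "confsel_empty_set")
  class(p) <- c("projection_table", "data.frame")
  attr(p, "angle_tol_deg") <- angle_tol_deg
  attr(p, "min_b_ppm") <- min_b_ppm
  p
}

#' Maximum-likelihood global population estimate
#'
#' Pools the retained residues into a single closed-state fraction. Writing
#' \eqn{y_i = |A|_i \cos\theta_i} (the signed length of the query
#' displacement along the axis) and \eqn{b_i = |B|_i}, the model is
#' \eqn{y_i \sim N(b_i F, \sigma^2)} and the log likelihood
#' \deqn{l(F,\sigma) = \sum_i \left[-\tfrac12\log(2\pi\sigma^2)
#'   - (b_i F - y_i)^2 / (2\sigma^2)\right]}
#' is maximised in closed form:
#' \eqn{\hat F = \sum_i b_i y_i / \sum_i b_i^2},
#' \eqn{\hat\sigma^2 = n^{-1}\sum_i (b_i\hat F - y_i)^2}.
#' Variances come from the negative inverse Hessian (observed information)
#' at the optimum, where the cross term vanishes:
#' \eqn{\mathrm{var}(\hat F) = \hat\sigma^2/\sum_i b_i^2},
#' \eqn{\mathrm{var}(\hat\sigma) = \hat\sigma^2/(2n)}.
#'
#' @param projections A filtered `projection_table` (rows with
#'   `passed_filters == FALSE` are ignored); at least 2 retained residues.
#' @return An object of class `"population_estimate"`: `f_hat` (reported,
#'   clipped to \[0,1\]), `f_hat_raw` (unclipped maximiser), `sigma_hat`
#'   (ppm), `var_f`, `var_sigma`, `se_f`, `n_residues`, `log_likelihood`.
#' @export
estimate_population <- function(projections) {
  p <- as.data.frame(projections)
  if (!is.null(p$passed_filters)) p <- p[p$passed_filters, ]
  n <- nrow(p)
  if (n < 2)
    abort("population estimation needs at least 2 retained residues",
          "confsel_insufficient_data")
  b <- p$b_norm
  y <- p$f * b                      # |A| cos(theta)
  sum_b2 <- sum(b^2)
  f_hat <- sum(b * y) / sum_b2
  resid <- b * f_hat - y
  sigma2 <- mean(resid^2)
  sigma_hat <- sqrt(sigma2)
  var_f <- sigma2 / sum_b2
  var_sigma <- sigma2 / (2 * n)
  loglik <- if (sigma2 > 0)
    sum(-0.5 * log(2 * pi * sigma2) - resid^2 / (2 * sigma2)) else Inf
  if (f_hat < 0 || f_hat > 1)
    warning(sprintf("maximum-likelihood fraction %.4f lies outside [0, 1]; %s",
                    f_hat, "reported value is clipped"))
  structure(list(f_hat = min(1, max(0, f_hat)), f_hat_raw = f_hat,
                 sigma_hat = sigma_hat, var_f = var_f, var_sigma = var_sigma,
                 se_f = sqrt(var_f), n_residues = n, log_likelihood = loglik),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate>\n")
  cat(sprintf("  fraction closed : %.4f +/- %.4f (n = %d residues)\n",
              x$f_hat, x$se_f, x$n_residues))
  cat(sprintf("  fraction open   : %.4f\n", 1 - x$f_hat))
  cat(sprintf("  model noise     : %.5f ppm\n", x$sigma_hat))
  invisible(x)
}

#' Open/closed equilibrium constant from the closed fraction
#'
#' \eqn{K_{open/close} = k_{open}/k_{close} = p_{open}/p_{closed}
#'   = (1 - f_{closed})/f_{closed}}.
#'
#' @param f_closed Closed-state fraction, strictly inside (0, 1).
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_from_population <- function(f_closed) {
  stopifnot(is.numeric(f_closed), all(is.finite(f_closed)))
  if (any(f_closed <= 0 | f_closed >= 1))
    abort("f_closed must lie strictly between 0 and 1", "confsel_boundary")
  (1 - f_closed) / f_closed
}
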