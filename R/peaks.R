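#' Default down-weight of the 15N chemical-shift axis
#'
#' Amide 15N shifts disperse over a ~10-fold wider ppm range than 1H shifts,
#' so combined 1H/15N metrics scale the nitrogen axis by 0.15 before any
#' distance or projection is computed. All projection and perturbation
#' functions take this as their `n_weight` argument with this value as
#' default.
#'
#' @export
NITROGEN_WEIGHT <- 0.15

#' Construct a single amide peak
#'
#' A peak is one cross peak in a 2D [1H-15N] correlation spectrum: a residue,
#' which NH group it belongs to, and its 1H and 15N chemical shifts.
#'
#' @param residue_id Integer sequence position (>= 1).
#' @param delta_h 1H chemical shift, ppm.
#' @param delta_n 15N chemical shift, ppm.
#' @param atom_group `"backbone-NH"` or `"sidechain-NHe"` (tryptophan indole
#'   NHs are followed as reporters alongside backbone amides).
#' @return A list of class `"peak"`.
#' @export
peak <- function(residue_id, delta_h, delta_n, atom_group = "backbone-NH") {
  stopifnot(is_number(residue_id), residue_id >= 1,
            is_number(delta_h), is_number(delta_n))
  atom_group <- match.arg(atom_group, c("backbone-NH", "sidechain-NHe"))
  structure(list(residue_id = as.integer(residue_id),
                 atom_group = atom_group,
                 delta_h = delta_h, delta_n = delta_n),
            class = "peak")
}

#' Construct a peak set (one labeled state)
#'
#' A peak set is a peak list for one sample: the query protein, the
#' open-state reference, or the closed-state reference. Peaks are keyed by
#' `(residue_id, atom_group)` and duplicate keys are rejected.
#'
#' @param x A data.frame with columns `residue_id`, `atom_group`,
#'   `delta_h_ppm`, `delta_n_ppm` (`atom_group` may be omitted and defaults
#'   to `"backbone-NH"`).
#' @param label State name, e.g. `"query"`, `"open_ref"`, `"closed_ref"`.
#' @return The validated data.frame with class `"peak_set"` and a `label`
#'   attribute.
#' @export
peak_set <- function(x, label = "query") {
  x <- as.data.frame(x)
  if (is.null(x$atom_group)) x$atom_group <- "backbone-NH"
  need <- c("residue_id", "atom_group", "delta_h_ppm", "delta_n_ppm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(sprintf("peak set is missing column(s): %s",
                  paste(miss, collapse = ", ")), "confsel_parse_error")
  x <- x[need]
  x$residue_id <- as.integer(x$residue_id)
  if (any(!is.finite(x$delta_h_ppm)) || any(!is.finite(x$delta_n_ppm)))
    abort("chemical shifts must be finite", "confsel_parse_error")
  if (any(x$residue_id < 1L))
    abort("residue_id must be >= 1", "confsel_parse_error")
  key <- paste(x$residue_id, x$atom_group)
  if (anyDuplicated(key))
    abort(sprintf("duplicate peak key(s): %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")),
          "confsel_parse_error")
  structure(x, class = c("peak_set", "data.frame"), label = label)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s'> %d peaks\n", attr(x, "label") %||% "?", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

peak_fields <- function(p) {
  if (inherits(p, "peak")) return(p)
  p <- as.list(p)
  list(residue_id = p$residue_id, atom_group = p$atom_group,
       delta_h = p$delta_h %||% p$delta_h_ppm,
       delta_n = p$delta_n %||% p$delta_n_ppm)
}

check_same_key <- function(a, b) {
  if (!is.null(a$residue_id) && !is.null(b$residue_id) &&
      (a$residue_id != b$residue_id ||
       !identical(a$atom_group %||% "backbone-NH",
                  b$atom_group %||% "backbone-NH")))
    abort(sprintf("peaks belong to different keys: (%s,%s) vs (%s,%s)",
                  a$residue_id, a$atom_group %||% "", b$residue_id,
                  b$atom_group %||% ""), "confsel_key_mismatch")
  invisible(TRUE)
}

#' Combined 1H/15N chemical-shift perturbation
#'
#' CSP between two peaks of the same residue:
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (w\,\Delta\delta_N)^2}}
#' with the nitrogen weight \eqn{w} defaulting to 0.15.
#'
#' @param peak_a,peak_b Peaks ([peak()] objects, one-row data.frames, or
#'   named lists with `delta_h`/`delta_n` or `delta_h_ppm`/`delta_n_ppm`).
#'   If both carry residue keys they must match.
#' @param n_weight 15N axis weight.
#' @return Non-negative CSP in ppm.
#' @export
csp <- function(peak_a, peak_b, n_weight = NITROGEN_WEIGHT) {
  a <- peak_fields(peak_a); b <- peak_fields(peak_b)
  check_same_key(a, b)
  sqrt((a$delta_h - b$delta_h)^2 + (n_weight * (a$delta_n - b$delta_n))^2)
}
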