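# Readers/writers for the delimited-text exchange formats and the pipeline
# composition that chains populations -> equilibrium -> kinetics -> apparent
# affinity -> coupled predictions into one JSON-serialisable report.

detect_sep <- function(header_line) if (grepl("\t", header_line)) "\t" else ","

#' Read a delimited table with schema validation
#'
#' Delimiter (comma or tab) is auto-detected from the header; header names
#' are matched case-insensitively against the required schema and renamed
#' to their canonical form; numeric columns are validated cell by cell with
#' the offending line number in the error message.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers (default: all
#'   required columns except `atom_group`).
#' @return A validated data.frame.
#' @export
read_table_schema <- function(path, required,
                              numeric_cols = setdiff(required, "atom_group")) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "confsel_parse_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    abort(sprintf("%s: empty file (need a header and data rows)", path),
          "confsel_parse_error")
  sep <- detect_sep(lines[1])
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(tolower(required), names(df))
  if (length(miss))
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(miss, collapse = ", ")), "confsel_parse_error")
  df <- df[tolower(required)]
  names(df) <- required
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(trimws(df[[col]]) %in% c("NA", "")))
    if (length(bad))
      abort(sprintf("%s: non-numeric value '%s' in column '%s' at line %d",
                    path, df[[col]][bad[1]], col, bad[1] + 1L),
            "confsel_parse_error")
    df[[col]] <- v
  }
  df
}

#' Read a peak list
#'
#' Expected columns: `residue_id, atom_group, delta_h_ppm, delta_n_ppm`
#' (comma- or tab-separated).
#'
#' @param path File path.
#' @param label State label for the resulting [peak_set()].
#' @return A [peak_set()].
#' @export
read_peak_list <- function(path, label = "query") {
  df <- read_table_schema(path, c("residue_id", "atom_group",
                                  "delta_h_ppm", "delta_n_ppm"))
  peak_set(df, label)
}

#' Write a peak list
#'
#' @param x A [peak_set()] or compatible data.frame.
#' @param path Output path (comma-separated).
#' @export
write_peak_list <- function(x, path) {
  utils::write.csv(as.data.frame(peak_set(x)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a two-column assignment/shift list into a peak set
#'
#' Simple dialect with columns `assignment, shift_ppm`, where assignments
#' look like `278HN` / `278N` (residue number followed by the atom, `HN`
#' for the proton and `N` for the nitrogen of the amide). Rows are paired
#' by residue into peaks; residues missing either atom are dropped with a
#' message.
#'
#' @param path File path.
#' @param label State label.
#' @return A [peak_set()].
#' @export
read_assignment_list <- function(path, label = "query") {
  df <- read_table_schema(path, c("assignment", "shift_ppm"),
                          numeric_cols = "shift_ppm")
  m <- regmatches(df$assignment,
                  regexec("^([0-9]+)(HN|N)$", trimws(df$assignment)))
  ok <- lengths(m) == 3
  if (!all(ok))
    abort(sprintf("%s: unparseable assignment '%s'", path,
                  df$assignment[which(!ok)[1]]), "confsel_parse_error")
  res <- as.integer(vapply(m, `[`, "", 2))
  atom <- vapply(m, `[`, "", 3)
  h <- stats::setNames(df$shift_ppm[atom == "HN"], res[atom == "HN"])
  n <- stats::setNames(df$shift_ppm[atom == "N"], res[atom == "N"])
  shared <- intersect(names(h), names(n))
  dropped <- length(union(names(h), names(n))) - length(shared)
  if (dropped > 0)
    message(sprintf("dropped %d residue(s) missing one of the HN/N shifts",
                    dropped))
  peak_set(data.frame(residue_id = as.integer(shared),
                      atom_group = "backbone-NH",
                      delta_h_ppm = as.numeric(h[shared]),
                      delta_n_ppm = as.numeric(n[shared])), label)
}

#' Read an exclusion list (one residue_id per line)
#'
#' @param path File path; blank lines and `#` comments are ignored.
#' @return Integer vector of residue ids.
#' @export
read_exclusions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.integer(lines))
  if (any(is.na(v)))
    abort(sprintf("%s: non-integer residue id '%s'", path,
                  lines[which(is.na(v))[1]]), "confsel_parse_error")
  v
}

#' Read a stopped-flow trace (`time_s, signal`)
#'
#' @param path File path.
#' @return data.frame with `time_s`, `signal`.
#' @export
read_trace <- function(path) {
  df <- read_table_schema(path, c("time_s", "signal"))
  trace_fields(df)  # validates monotone time
  df
}

#' Write a stopped-flow trace
#' @param x data.frame with `time_s`, `signal`.
#' @param path Output path.
#' @export
write_trace <- function(x, path) {
  tf <- trace_fields(x)
  utils::write.csv(data.frame(time_s = tf$t, signal = tf$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rate-versus-concentration table
#'
#' Columns: `ligand_uM, k_fast_s, k_fast_se, k_slow_s, k_slow_se` (the SE
#' and slow-phase columns optional).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_rate_table <- function(path) {
  base <- read_table_schema(path, c("ligand_uM", "k_fast_s"))
  opt <- c("k_fast_se", "k_slow_s", "k_slow_se")
  lines <- readLines(path, warn = FALSE, n = 1)
  have <- intersect(opt, tolower(strsplit(lines, "[,\t]")[[1]]))
  if (length(have)) {
    full <- read_table_schema(path, c("ligand_uM", "k_fast_s", have))
    return(full)
  }
  base
}

#' Read a steady-state activity table (`substrate_uM, k_obs_s[, sd_s]`)
#' @param path File path.
#' @return data.frame.
#' @export
read_activity_table <- function(path) {
  first <- tolower(readLines(path, warn = FALSE, n = 1))
  cols <- c("substrate_uM", "k_obs_s")
  if (grepl("sd_s", first)) cols <- c(cols, "sd_s")
  read_table_schema(path, cols)
}

#' Read a dose-response table (`inhibitor_uM, pct_inhibition[, sd]`)
#' @param path File path.
#' @return data.frame.
#' @export
read_dose_table <- function(path) {
  first <- tolower(readLines(path, warn = FALSE, n = 1))
  cols <- c("inhibitor_uM", "pct_inhibition")
  if (grepl("(^|[,\t])sd($|[,\t])", first)) cols <- c(cols, "sd")
  read_table_schema(path, cols)
}

pipeline_known_keys <- c("populations", "kinetics", "engine", "coupled",
                         "seed", "output", "verbose")

#' Read and validate a pipeline configuration file
#'
#' YAML with the sections `populations` (paths `query`, `open_ref`,
#' `closed_ref`, optional `exclude`, `angle_tol_deg`, `min_b_ppm`,
#' `convention`), `kinetics` (path `rates`, optional `k_off`/`k_off_se`
#' from a dissociation fit or a `dissociation_trace` path), `engine`
#' (`kcat1`, `kcat2`, `kd1`, `kd2`), `coupled` (`k_close`, optional
#' `substrate_uM` grid, `drug: {k_on, k_off}`, `enzyme_uM`, `doses`),
#' plus optional `seed` and `verbose`. Unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return The validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), pipeline_known_keys)
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s; known keys are: %s",
                  paste(unknown, collapse = ", "),
                  paste(pipeline_known_keys, collapse = ", ")),
          "confsel_usage_error")
  cfg
}

stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Chains the stages of the landscape analysis: (1) closed-state population
#' from the three peak lists, (2) open/close equilibrium constant, (3)
#' fast/slow-phase rate extraction from a rate table (and, if provided, an
#' off-rate from a dissociation trace), (4) apparent dissociation constant
#' with propagated uncertainty, (5) coupled steady-state activity and
#' inhibition predictions. Stages whose inputs are absent from the config
#' are skipped. Logging (`verbose`) never touches the numbers.
#'
#' @param config A config list as returned by [read_config()], or a path to
#'   a YAML file. In-memory data.frames may be supplied in place of file
#'   paths for every input.
#' @return A report list (class `"confsel_report"`) embedding the resolved
#'   config, package version and seed alongside every stage's outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config) || !length(config))
    abort("empty pipeline config", "confsel_usage_error")
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown))
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          "confsel_usage_error")
  verbose <- isTRUE(config$verbose)
  seed <- config$seed %||% 1L
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("confsel")),
                 seed = seed,
                 config = config[setdiff(names(config), "verbose")])
  as_tbl <- function(x, reader) if (is.character(x)) reader(x) else x

  if (!is.null(config$populations)) {
    pc <- config$populations
    report$populations <- stage("populations", verbose, {
      excl <- if (is.null(pc$exclude)) integer()
        else if (is.character(pc$exclude)) read_exclusions(pc$exclude)
        else as.integer(pc$exclude)
      proj <- project_peak_sets(as_tbl(pc$query, function(p) read_peak_list(p, "query")),
                                as_tbl(pc$open_ref, function(p) read_peak_list(p, "open_ref")),
                                as_tbl(pc$closed_ref, function(p) read_peak_list(p, "closed_ref")),
                                convention = pc$convention %||% "closed")
      filt <- filter_residues(proj, excl,
                              angle_tol_deg = pc$angle_tol_deg %||% 10,
                              min_b_ppm = pc$min_b_ppm %||% 0.03)
      est <- estimate_population(filt)
      list(f_hat = est$f_hat, f_hat_raw = est$f_hat_raw, se_f = est$se_f,
           sigma_hat = est$sigma_hat, n_used = est$n_residues,
           p_open = 1 - est$f_hat,
           n_excluded = sum(!filt$passed_filters),
           exclusion_reasons = table(filt$reason[!filt$passed_filters]),
           residues = as.data.frame(filt))
    })
    report$equilibrium <- stage("equilibrium", verbose, {
      f <- report$populations$f_hat
      list(K_open_close = equilibrium_from_population(f),
           K_close_open = 1 / equilibrium_from_population(f))
    })
  }

  if (!is.null(config$kinetics)) {
    kc <- config$kinetics
    report$kinetics <- stage("kinetics", verbose, {
      Koc <- report$equilibrium$K_open_close %||% kc$k_open_close
      if (is.null(Koc))
        abort("kinetics stage needs K_open_close (populations stage or kinetics$k_open_close)",
              "confsel_usage_error")
      rates <- as_tbl(kc$rates, read_rate_table)
      fast <- fit_fast_phase(rates, Koc)
      k_off <- fast$k_off; k_off_se <- fast$k_off_se
      if (!is.null(kc$dissociation_trace)) {
        dis <- fit_dissociation(as_tbl(kc$dissociation_trace, read_trace))
        k_off <- dis$k_off; k_off_se <- dis$k_off_se
      } else if (!is.null(kc$k_off)) {
        k_off <- kc$k_off; k_off_se <- kc$k_off_se %||% 0
      }
      out <- list(k_on = fast$k_on, k_on_se = fast$k_on_se,
                  k_off = k_off, k_off_se = k_off_se,
                  slope_observed = fast$slope_observed,
                  K_open_close = Koc)
      if (!is.null(rates$k_slow_s)) {
        slow <- fit_slow_phase(rates, fast$k_on, k_off)
        out$k_close <- slow$k_close; out$k_close_se <- slow$k_close_se
        out$k_open <- slow$k_open; out$k_open_se <- slow$k_open_se
      } else {
        out$k_close <- kc$k_close
        out$k_open <- if (!is.null(kc$k_close)) Koc * kc$k_close else NULL
      }
      out
    })
    if (!is.null(report$kinetics$k_close)) {
      report$affinity <- stage("apparent_kd", verbose, {
        kin <- report$kinetics
        # opening rate from the equilibrium constant and the fitted closing
        # rate (the hyperbola's half-saturation constrains it only weakly)
        k_open_eq <- kin$K_open_close * kin$k_close
        sch <- conf_sel_scheme(k_open_eq, kin$k_close, kin$k_on, kin$k_off,
                               se = list(k_open = kin$k_open_se %||% 0,
                                         k_close = kin$k_close_se %||% 0,
                                         k_on = kin$k_on_se,
                                         k_off = kin$k_off_se))
        kd <- apparent_kd(sch, n_mc = 2000, seed = seed)
        list(K_D_obs = kd$kd_obs, se = kd$se_linear, se_mc = kd$se_mc,
             K_D = sch$K_D, scheme = sch[c("k_open", "k_close", "k_on", "k_off")])
      })
    }
  }

  if (!is.null(config$engine) && !is.null(config$coupled)) {
    report$coupled <- stage("coupled", verbose, {
      en <- config$engine
      engine <- two_site_params(en$kcat1, en$kcat2, en$kd1,
                                en$kd2 %||% Inf)
      cc <- config$coupled
      Koc <- report$equilibrium$K_open_close %||% cc$k_open_close
      drug <- cc$drug
      if (is.null(drug) && !is.null(report$kinetics))
        drug <- list(k_on = report$kinetics$k_on,
                     k_off = report$kinetics$k_off)
      cfg2 <- coupled_config(engine, k_close = cc$k_close,
                             k_open_close = Koc, drug = drug,
                             enzyme_uM = cc$enzyme_uM %||% 1e-3)
      s_grid <- cc$substrate_uM %||% 10^seq(0, 3.3, length.out = 12)
      act <- steady_state_activity(cfg2, s_grid)
      out <- list(substrate_uM = s_grid,
                  k_obs_s = act$grid$k_obs_s,
                  engine_s = two_site_rate(s_grid, engine),
                  p_open_ensemble = act$grid$p_open_ensemble)
      if (!is.null(drug)) {
        doses <- cc$doses %||% 10^seq(-3, 3, length.out = 13)
        inh <- inhibition_curve(cfg2, doses,
                                substrate = cc$inhibition_substrate_uM %||% 500)
        out$inhibition <- inh$curve
        out$ic50 <- inh$ic50
        out$basal <- inh$basal
      }
      out
    })
  }
  structure(report, class = "confsel_report")
}

#' @export
print.confsel_report <- function(x, ...) {
  cat("<confsel_report>\n")
  if (!is.null(x$populations))
    cat(sprintf("  populations: f_closed = %.4f +/- %.4f (n = %d)\n",
                x$populations$f_hat, x$populations$se_f, x$populations$n_used))
  if (!is.null(x$equilibrium))
    cat(sprintf("  equilibrium: K_open/close = %.4g\n",
                x$equilibrium$K_open_close))
  if (!is.null(x$kinetics))
    cat(sprintf("  kinetics: k_on = %.4g, k_off = %.4g, k_close = %s\n",
                x$kinetics$k_on, x$kinetics$k_off,
                if (is.null(x$kinetics$k_close)) "NA" else
                  sprintf("%.4g", x$kinetics$k_close)))
  if (!is.null(x$affinity))
    cat(sprintf("  affinity: K_D_obs = %.4g +/- %.2g uM\n",
                x$affinity$K_D_obs, x$affinity$se))
  if (!is.null(x$coupled) && !is.null(x$coupled$ic50))
    cat(sprintf("  coupled: predicted IC50 = %.4g uM\n", x$coupled$ic50))
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Numbers are written at full precision; the resolved config, package
#' version and seed are embedded for provenance.
#'
#' @param report A `"confsel_report"`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  clean <- rapply(unclass(report), function(x)
    if (inherits(x, "table")) as.list(x) else x, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}
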