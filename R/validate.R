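#' Configuration for a full validation run
#'
#' @param input Either a [cohort_spec()] (synthetic cohort) or a path to
#'   a raw cohort CSV.
#' @param coefficient_paths Named list of coefficient file paths per
#'   version; defaults to the bundled files.
#' @param smoking_mode `"all_nonsmokers"` (primary) or `"all_smokers"`
#'   (sensitivity); affects v3.0 only.
#' @param horizons Subset of `c(5, 10)`.
#' @param subgroups Cells to evaluate, subset of
#'   `c("All", "Luminal", "HER2+", "TNBC", "N0", "N+")`.
#' @param bootstrap_B Bootstrap replications (>= 2).
#' @param seed Integer seed governing every random element of the run.
#' @param basis [cal_basis()] for the calibration fits.
#' @param cutpoints Optional fixed expansion cutpoints (default:
#'   event-time deciles per cell).
#' @param registry_cutoff End of registry follow-up.
#' @param age_range Eligibility age bounds.
#' @param run_bootstrap Compute bootstrap CIs and paired differences?
#'   (Point estimates are always computed.)
#' @param sp_mode Smoothing-parameter handling inside the bootstrap.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input,
                       coefficient_paths = list(
                         "v2.2" = predict_coefficients_path("v2.2"),
                         "v3.0" = predict_coefficients_path("v3.0")),
                       smoking_mode = "all_nonsmokers",
                       horizons = c(5, 10),
                       subgroups = c("All", "Luminal", "HER2+", "TNBC",
                                     "N0", "N+"),
                       bootstrap_B = 200, seed = 1,
                       basis = cal_basis(), cutpoints = NULL,
                       registry_cutoff = "2021-03-09",
                       age_range = c(25, 40),
                       run_bootstrap = TRUE,
                       sp_mode = "reestimate") {
  if (!inherits(input, "cohort_spec") &&
      !(is.character(input) && file.exists(input))) {
    stop("input must be a cohort_spec or an existing CSV path")
  }
  if (bootstrap_B < 2) stop("bootstrap_B must be >= 2")
  for (v in names(coefficient_paths)) {
    if (!file.exists(coefficient_paths[[v]])) {
      stop("coefficient file for ", v, " not found")
    }
  }
  structure(list(input = input, coefficient_paths = coefficient_paths,
                 smoking_mode = smoking_mode, horizons = horizons,
                 subgroups = subgroups, bootstrap_B = bootstrap_B,
                 seed = seed, basis = basis, cutpoints = cutpoints,
                 registry_cutoff = registry_cutoff, age_range = age_range,
                 run_bootstrap = run_bootstrap, sp_mode = sp_mode),
            class = "run_config")
}

# rbind data frames with possibly different column sets (NA-filled)
.rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  rbind(a, b[names(a)])
}

.subgroup_subset <- function(records, subgroup) {
  if (subgroup == "All") return(records)
  if (subgroup %in% c("N0", "N+")) {
    return(records[records$nodal_group == subgroup, , drop = FALSE])
  }
  records[records$subtype == subgroup, , drop = FALSE]
}

# one (subgroup x horizon x outcome) cell: ICI and tdAUC for both
# versions plus paired differences; undefined cells reported as NA
.validate_cell <- function(rec, subgroup, horizon, outcome, cfg, coeffs,
                           cell_seed) {
  row <- data.frame(subgroup = subgroup, horizon = horizon,
                    outcome = outcome, n = nrow(rec),
                    n_events = sum(rec$event_cause != "censored"),
                    stringsAsFactors = FALSE)
  versions <- names(cfg$coefficient_paths)
  co <- if (outcome == "all_cause") "all_cause" else "bc_death"
  enough <- nrow(rec) > 0 &&
    sum(rec$event_cause %in% c("bc_death", "other_death")) > 0
  for (ver in versions) {
    vtag <- gsub("[.]", "", ver)
    ici <- tdv <- NA_real_
    if (enough) {
      ici <- tryCatch({
        f <- .metric_fit_full(rec, ver, horizon, outcome, cfg$basis,
                              cfg$cutpoints)
        d <- calibration_data(rec, ver, horizon, outcome)
        integrated_calibration_index(f, d$p, horizon, co)$ici
      }, error = function(e) NA_real_)
      tdv <- td_auc(rec, ver, horizon, outcome)$tdauc
    }
    row[[paste0("ici_", vtag)]] <- ici
    row[[paste0("tdauc_", vtag)]] <- tdv
    if (cfg$run_bootstrap && enough && is.finite(ici)) {
      bi <- bootstrap_ci(rec,
                         .metric_fun("ici", ver, horizon, outcome,
                                     cfg$basis, cfg$cutpoints),
                         B = cfg$bootstrap_B, seed = cell_seed,
                         statistic_id = paste0("ici_", vtag))
      row[[paste0("ici_", vtag, "_lo")]] <- bi$ci_low
      row[[paste0("ici_", vtag, "_hi")]] <- bi$ci_high
      bt <- bootstrap_ci(rec,
                         .metric_fun("tdauc", ver, horizon, outcome,
                                     cfg$basis, cfg$cutpoints),
                         B = cfg$bootstrap_B, seed = cell_seed,
                         statistic_id = paste0("tdauc_", vtag))
      row[[paste0("tdauc_", vtag, "_lo")]] <- bt$ci_low
      row[[paste0("tdauc_", vtag, "_hi")]] <- bt$ci_high
    }
  }
  if (cfg$run_bootstrap && enough && length(versions) == 2 &&
      all(is.finite(unlist(row[paste0("ici_",
                                      gsub("[.]", "", versions))])))) {
    for (m in c("ici", "tdauc")) {
      dd <- tryCatch(
        paired_difference_ci(rec, m, horizon, outcome,
                             versions = versions, B = cfg$bootstrap_B,
                             seed = cell_seed, basis = cfg$basis,
                             cutpoints = cfg$cutpoints,
                             sp_mode = cfg$sp_mode),
        error = function(e) NULL)
      if (!is.null(dd)) {
        row[[paste0(m, "_diff")]] <- dd$point
        row[[paste0(m, "_diff_lo")]] <- dd$ci_low
        row[[paste0(m, "_diff_hi")]] <- dd$ci_high
        row[[paste0(m, "_diff_significant")]] <- dd$significant
      }
    }
  }
  row
}

#' Run the full external-validation pipeline
#'
#' Executes the stages in order: cohort acquisition (synthetic or CSV),
#' eligibility screening, variable mapping, horizon restriction, engine
#' predictions for every version, then per-cell calibration (ICI) and
#' discrimination (tdAUC) with optional bootstrap CIs and paired
#' version differences, and all-patients calibration curves.
#' Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return List of class `validation_run`: `table` (the subgroup x
#'   horizon x outcome results, internal probability scale), `curves`
#'   (all-patients calibration curves), `ledger` (exclusion counts),
#'   `truth` (for synthetic inputs), `log` (stage messages).
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logmsg <- character(0)
  note <- function(...) {
    logmsg <<- c(logmsg, paste0(...))
  }
  if (inherits(config$input, "cohort_spec")) {
    sim <- simulate_cohort(config$input)
    rows <- sim$rows
    truth <- sim$truth
    note("stage:input synthetic cohort n=", nrow(rows))
  } else {
    rows <- read_cohort_csv(config$input)
    truth <- NULL
    note("stage:input CSV ", config$input, " n=", nrow(rows))
  }
  elig <- apply_eligibility(rows, config$age_range)
  note("stage:eligibility retained ", nrow(elig$eligible), "/", nrow(rows))
  records <- build_records(elig$eligible, config$smoking_mode)
  coeffs <- lapply(names(config$coefficient_paths), function(v) {
    load_coefficients(v, config$coefficient_paths[[v]])
  })
  names(coeffs) <- names(config$coefficient_paths)
  records <- attach_predictions(records, coeffs, config$horizons)
  note("stage:predictions attached for ",
       paste(names(coeffs), collapse = ", "))
  tab <- NULL
  curves <- list()
  cell_i <- 0L
  for (h in config$horizons) {
    hrec <- restrict_to_horizon(records, h, config$registry_cutoff)
    note("stage:horizon ", h, "y n=", nrow(hrec), " events=",
         sum(hrec$event_cause != "censored"))
    for (sg in config$subgroups) {
      rec <- .subgroup_subset(hrec, sg)
      for (outc in c("all_cause", "bc_specific")) {
        cell_i <- cell_i + 1L
        row <- .validate_cell(rec, sg, h, outc, config, coeffs,
                              cell_seed = .substream(config$seed, cell_i))
        tab <- .rbind_fill(tab, row)
      }
    }
    # all-patients calibration curves per version and outcome
    for (ver in names(coeffs)) {
      for (outc in c("all_cause", "bc_specific")) {
        key <- paste0("All_", gsub("[.]", "", ver), "_", h, "y_",
                      ifelse(outc == "all_cause", "ac", "bc"))
        curves[[key]] <- tryCatch({
          f <- .metric_fit_full(hrec, ver, h, outc, config$basis,
                                config$cutpoints)
          calibration_curve(
            f, horizon = h,
            outcome = if (outc == "all_cause") "all_cause" else "bc_death",
            seed = .substream(config$seed, 90000L + cell_i))
        }, error = function(e) NULL)
      }
    }
  }
  out <- list(table = tab, curves = curves, ledger = elig$ledger,
              truth = truth, log = logmsg, config = config)
  class(out) <- "validation_run"
  out
}

#' Export plot-ready validation outputs
#'
#' Writes the results table, one CSV per all-patients calibration panel
#' (risk grid, observed risk, CI bounds), a point-and-CI summary for
#' forest-style figures, and the exclusion ledger. Probabilities are
#' exported in percent; re-export of the same run is byte-identical.
#'
#' @param run A [run_validation()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_figure_data <- function(run, dir) {
  stopifnot(inherits(run, "validation_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  tab <- run$table
  pc <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                c("horizon", "n", "n_events"))
  tab[pc] <- lapply(tab[pc], function(z) round(100 * z, 4))
  wr(tab, "validation_table.csv")
  for (key in names(run$curves)) {
    cv <- run$curves[[key]]
    if (is.null(cv)) next
    out <- data.frame(predicted_pct = round(100 * cv$p, 4),
                      observed_pct = round(100 * cv$observed, 4),
                      lower_pct = round(100 * cv$lower, 4),
                      upper_pct = round(100 * cv$upper, 4))
    wr(out, paste0("calibration_", key, ".csv"))
  }
  long <- NULL
  for (m in c("ici", "tdauc")) {
    for (vtag in c("v22", "v30")) {
      cols <- paste0(m, "_", vtag, c("", "_lo", "_hi"))
      if (!all(cols %in% names(tab))) next
      part <- data.frame(metric = m, version = vtag,
                         subgroup = tab$subgroup, horizon = tab$horizon,
                         outcome = tab$outcome,
                         estimate_pct = tab[[cols[1]]],
                         lower_pct = tab[[cols[2]]],
                         upper_pct = tab[[cols[3]]])
      long <- rbind(long, part)
    }
  }
  if (!is.null(long)) wr(long, "summary_points.csv")
  wr(run$ledger, "exclusion_ledger.csv")
  invisible(files)
}
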