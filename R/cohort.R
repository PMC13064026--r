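#' Column dictionary for raw cohort tables
#'
#' One row per patient. Dates are ISO-8601 strings. Percentages are
#' 0-100. Missing values are empty strings or NA.
#'
#' @return Character vector of required column names.
#' @export
raw_cohort_columns <- function() {
  c("id", "diagnosis_date", "age", "sex", "stage", "invasive_flag",
    "surgery_flag", "er_percent", "pr_percent", "ki67_percent", "her2_ihc",
    "her2_ish_amplified", "nhg", "size_mm", "nodes_positive",
    "micromets_only", "detection_mode", "laterality", "endocrine_flag",
    "chemo_regimen_text", "trastuzumab_flag", "bisphosphonate_flag",
    "radiotherapy_flag", "vital_status_date", "status", "cause_of_death")
}

#' Read / write a raw cohort CSV
#'
#' @param path CSV file path.
#' @return `read_cohort_csv`: data frame with parsed dates;
#'   `write_cohort_csv`: `path`, invisibly.
#' @export
read_cohort_csv <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(raw_cohort_columns(), names(rows))
  if (length(miss)) stop("cohort CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  num <- c("age", "er_percent", "pr_percent", "ki67_percent", "size_mm",
           "nodes_positive")
  for (v in num) rows[[v]] <- suppressWarnings(as.numeric(rows[[v]]))
  rows$nhg <- suppressWarnings(as.integer(rows$nhg))
  lgl <- c("surgery_flag", "endocrine_flag", "trastuzumab_flag",
           "bisphosphonate_flag", "radiotherapy_flag")
  for (v in lgl) rows[[v]] <- rows[[v]] %in% c("TRUE", "true", "yes", "1")
  rows
}

#' @rdname read_cohort_csv
#' @param rows Raw cohort data frame.
#' @export
write_cohort_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

# calendar-year addition; Feb 29 in a non-leap target year clamps to
# Feb 28 (documented leap-day convention)
.add_years <- function(dates, n) {
  lt <- as.POSIXlt(dates)
  y <- lt$year + 1900 + n
  m <- lt$mon + 1
  d <- lt$mday
  out <- as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(d, 28)))
  full <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  ok <- !is.na(full)
  out[ok] <- full[ok]
  out
}

.parse_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

#' Apply the study eligibility rules
#'
#' Screens raw rows through the eligibility criteria in a fixed
#' application order (female sex; age within `age_range` inclusive;
#' invasive disease, not in situ only; stage I-III; surgery for the
#' primary tumour; ER percentage recorded; histological grade recorded;
#' positive follow-up time). Each excluded row is counted under the
#' first rule it fails; rows with unparseable dates land in the ledger
#' as `unparseable`.
#'
#' @param rows Raw cohort data frame (see [raw_cohort_columns()]).
#' @param age_range Inclusive age bounds, default `c(25, 40)`.
#' @return `list(eligible = <rows>, ledger = <data frame rule/n_excluded>)`.
#' @export
apply_eligibility <- function(rows, age_range = c(25, 40)) {
  dd <- .parse_date(rows$diagnosis_date)
  vd <- .parse_date(rows$vital_status_date)
  rules <- list(
    unparseable = is.na(dd) | is.na(vd) | is.na(rows$age),
    not_female = rows$sex != "female",
    age_out_of_range = rows$age < age_range[1] | rows$age > age_range[2],
    in_situ_only = rows$invasive_flag == "in_situ_only",
    stage_not_I_III = !(rows$stage %in% c("I", "II", "III")),
    no_surgery = !rows$surgery_flag,
    missing_er = is.na(rows$er_percent),
    missing_grade = is.na(rows$nhg) | !(rows$nhg %in% 1:3),
    nonpositive_followup = !is.na(dd) & !is.na(vd) & vd <= dd
  )
  excluded_by <- rep(NA_character_, nrow(rows))
  for (nm in names(rules)) {
    hit <- rules[[nm]] & is.na(excluded_by)
    hit[is.na(hit)] <- FALSE
    excluded_by[hit] <- nm
  }
  ledger <- data.frame(
    rule = names(rules),
    n_excluded = vapply(names(rules),
                        function(nm) sum(excluded_by == nm, na.rm = TRUE),
                        integer(1)),
    row.names = NULL
  )
  list(eligible = rows[is.na(excluded_by), , drop = FALSE], ledger = ledger)
}

#' Map registry biomarker fields to PREDICT levels
#'
#' ER is positive at >= 10% stained cells, PR likewise; Ki67 is positive
#' strictly above 10%; HER2 is positive for IHC 3+ or IHC 2+ with ISH
#' amplification, negative for IHC 0/1+ or IHC 2+ without amplification,
#' otherwise unknown. Missing PR/Ki67/HER2 map to the tool's "unknown"
#' level; missing ER is an error (such rows are excluded upstream).
#'
#' @param rows Eligible raw rows.
#' @return `rows` with columns `er_status`, `pr_status`, `her2_status`,
#'   `ki67_status`, `detection` appended.
#' @export
map_biomarkers <- function(rows) {
  if (anyNA(rows$er_percent)) {
    stop("er_percent missing for ", sum(is.na(rows$er_percent)),
         " row(s); these should have been excluded by apply_eligibility")
  }
  rows$er_status <- ifelse(rows$er_percent >= 10, "positive", "negative")
  rows$pr_status <- ifelse(is.na(rows$pr_percent), "unknown",
                           ifelse(rows$pr_percent >= 10,
                                  "positive", "negative"))
  rows$ki67_status <- ifelse(is.na(rows$ki67_percent), "unknown",
                             ifelse(rows$ki67_percent > 10,
                                    "positive", "negative"))
  ihc <- as.character(rows$her2_ihc)
  ish <- as.character(rows$her2_ish_amplified)
  rows$her2_status <- ifelse(
    !is.na(ihc) & ihc == "3+", "positive",
    ifelse(!is.na(ihc) & ihc == "2+" & !is.na(ish) & ish == "yes", "positive",
    ifelse(!is.na(ihc) & ihc == "2+" & !is.na(ish) & ish == "no", "negative",
    ifelse(!is.na(ihc) & ihc %in% c("0", "1+"), "negative", "unknown"))))
  dm <- as.character(rows$detection_mode)
  rows$detection <- ifelse(!is.na(dm) & dm %in% c("screening", "symptoms"),
                           dm, "unknown")
  rows
}

.taxane_tokens <- c("paclitaxel", "docetaxel", "taxotere", "taxol", "taxane")
.anthra_tokens <- c("fec", "fac", "cef", "ec", "ac", "epirubicin",
                    "doxorubicin", "anthracycline")

# classify one regimen string; error on unrecognized tokens
.chemo_generation <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt)) ||
      tolower(trimws(txt)) == "none") {
    return("none")
  }
  toks <- tolower(strsplit(trimws(txt), "[^[:alnum:]]+")[[1]])
  toks <- toks[nzchar(toks)]
  if (any(toks %in% .taxane_tokens)) return("third_gen")
  if (any(toks %in% .anthra_tokens)) return("second_gen")
  stop("unrecognized chemotherapy regimen token(s): '",
       paste(toks, collapse = " "), "'")
}

#' Map registry treatment fields to a PREDICT treatment plan
#'
#' Regimen text containing a taxane token maps to third generation;
#' anthracycline-based regimens (FEC and relatives) map to second
#' generation; empty/none maps to no chemotherapy; anything else is an
#' explicit error naming the offending token. The registry records
#' endocrine therapy up to five years, so the endocrine flag maps to the
#' five-year option. Mean heart dose is coded 2 Gy for irradiated
#' left-sided disease, 0 Gy otherwise.
#'
#' @param rows Eligible raw rows.
#' @return `rows` with treatment-plan columns appended.
#' @export
map_treatments <- function(rows) {
  rows$endocrine <- ifelse(rows$endocrine_flag, "five_year", "none")
  rows$chemo_generation <- vapply(rows$chemo_regimen_text,
                                  .chemo_generation, character(1),
                                  USE.NAMES = FALSE)
  rows$trastuzumab <- rows$trastuzumab_flag
  rows$bisphosphonates <- rows$bisphosphonate_flag
  rows$radiotherapy <- rows$radiotherapy_flag
  rows$mean_heart_dose <- ifelse(rows$radiotherapy_flag &
                                   rows$laterality == "left", 2, 0)
  rows
}

#' Set the smoking field uniformly
#'
#' Smoking is not collected by the registry; the primary analysis codes
#' every patient as a never/ex-smoker, and a sensitivity mode codes
#' everyone as a smoker. Idempotent.
#'
#' @param records Data frame with a `smoker` column (created if absent).
#' @param mode `"all_nonsmokers"` or `"all_smokers"`.
#' @export
impute_smoking <- function(records, mode = c("all_nonsmokers",
                                             "all_smokers")) {
  mode <- match.arg(mode)
  records$smoker <- if (mode == "all_smokers") "yes" else "never_or_ex"
  records
}

#' Assign molecular subtype and nodal group
#'
#' Subtype: HER2+ whenever HER2 is positive; TNBC when ER, PR and HER2
#' are all negative; Luminal when ER-positive and HER2 non-positive
#' (HER2-unknown with ER+ counts as Luminal); everything else is an
#' explicit `unclassifiable` bucket, excluded from subtype analyses
#' only. Nodal group is N0 iff there are no positive nodes.
#'
#' @param records Data frame with `er_status`, `pr_status`,
#'   `her2_status`, `positive_nodes`.
#' @return `records` with `subtype` and `nodal_group` columns.
#' @export
assign_subgroups <- function(records) {
  er <- records$er_status
  pr <- records$pr_status
  h2 <- records$her2_status
  records$subtype <- ifelse(
    h2 == "positive", "HER2+",
    ifelse(er == "negative" & pr == "negative" & h2 == "negative", "TNBC",
    ifelse(er == "positive", "Luminal", "unclassifiable")))
  records$nodal_group <- ifelse(records$positive_nodes == 0, "N0", "N+")
  records
}

#' Build analysis records from mapped raw rows
#'
#' Runs the mapping steps, computes follow-up time
#' (`(vital status date - diagnosis date) / 365.25`), recodes the
#' four-level event cause, sets the smoking mode, and assigns
#' subgroups. Rows must already be eligible.
#'
#' @param rows Eligible raw rows.
#' @param smoking_mode Passed to [impute_smoking()].
#' @return Analysis-record data frame (one row per patient).
#' @export
build_records <- function(rows, smoking_mode = "all_nonsmokers") {
  rows <- map_biomarkers(rows)
  rows <- map_treatments(rows)
  dd <- .parse_date(rows$diagnosis_date)
  vd <- .parse_date(rows$vital_status_date)
  rec <- data.frame(
    id = rows$id,
    diagnosis_date = dd,
    age_at_diagnosis = rows$age,
    tumor_size = rows$size_mm,
    grade = rows$nhg,
    positive_nodes = rows$nodes_positive,
    micromets_only = ifelse(rows$nodes_positive >= 1 &
                              !is.na(rows$micromets_only) &
                              rows$micromets_only %in%
                                c("yes", "no", "unknown"),
                            rows$micromets_only, "no"),
    er_status = rows$er_status,
    pr_status = rows$pr_status,
    her2_status = rows$her2_status,
    ki67_status = rows$ki67_status,
    detection = rows$detection,
    postmenopausal = if ("postmenopausal" %in% names(rows))
      rows$postmenopausal else "no",
    endocrine = rows$endocrine,
    chemo_generation = rows$chemo_generation,
    trastuzumab = rows$trastuzumab,
    bisphosphonates = rows$bisphosphonates,
    radiotherapy = rows$radiotherapy,
    mean_heart_dose = rows$mean_heart_dose,
    followup_years = as.numeric(vd - dd) / 365.25,
    event_cause = ifelse(rows$status == "alive", "censored",
                  ifelse(rows$status == "emigrated", "emigrated",
                  ifelse(rows$cause_of_death == "breast_cancer",
                         "bc_death", "other_death"))),
    stringsAsFactors = FALSE
  )
  if (any(rec$followup_years <= 0)) stop("nonpositive follow-up time")
  rec <- impute_smoking(rec, smoking_mode)
  assign_subgroups(rec)
}

#' Restrict analysis records to a prediction horizon
#'
#' Keeps patients with sufficient potential follow-up -- a diagnosis
#' date at least `horizon` calendar years before the registry cut-off --
#' then censors follow-up at the horizon: events after the horizon are
#' recoded to censored-at-horizon, events exactly at the horizon remain
#' events.
#'
#' @param records Analysis records from [build_records()].
#' @param horizon 5 or 10 (years).
#' @param registry_cutoff End of registry follow-up (`Date` or ISO
#'   string).
#' @return Horizon-restricted records.
#' @export
restrict_to_horizon <- function(records, horizon, registry_cutoff) {
  cutoff <- .parse_date(registry_cutoff)
  keep <- .add_years(records$diagnosis_date, horizon) <= cutoff
  if (!any(keep)) warning("registry cut-off precedes all diagnoses + ",
                          horizon, "y; empty horizon dataset")
  out <- records[keep, , drop = FALSE]
  late <- out$followup_years > horizon
  out$event_cause[late] <- "censored"
  out$followup_years[late] <- horizon
  out$horizon <- rep(horizon, nrow(out))
  out
}

#' Prediction column name
#'
#' @param version `"v2.2"` or `"v3.0"`.
#' @param horizon 5 or 10.
#' @param outcome `"all_cause"` or `"bc_specific"`.
#' @export
pred_col <- function(version, horizon, outcome) {
  paste0("pred_", gsub("[.]", "", version), "_", horizon, "y_",
         if (outcome == "all_cause") "ac" else "bc")
}

#' Attach engine predictions to analysis records
#'
#' Runs the engine for every record under every supplied coefficient
#' set, and stores the 5- and 10-year all-cause and breast-cancer
#' -specific cumulative mortality in columns named by [pred_col()].
#' Deterministic given inputs; any engine failure aborts naming the
#' offending record.
#'
#' @param records Analysis records.
#' @param coeffs_list Named list of [load_coefficients()] results, e.g.
#'   `list("v2.2" = ..., "v3.0" = ...)`.
#' @param horizons Horizons to attach, default `c(5, 10)`.
#' @return `records` with prediction columns appended.
#' @export
attach_predictions <- function(records, coeffs_list, horizons = c(5, 10)) {
  prof_cols <- c("age_at_diagnosis", "tumor_size", "grade", "positive_nodes",
                 "micromets_only", "er_status", "pr_status", "her2_status",
                 "ki67_status", "detection", "smoker", "postmenopausal")
  plan_cols <- c("endocrine", "chemo_generation", "trastuzumab",
                 "bisphosphonates", "radiotherapy", "mean_heart_dose")
  dprof <- records[, prof_cols, drop = FALSE]
  dplan <- records[, plan_cols, drop = FALSE]
  for (ver in names(coeffs_list)) {
    m <- tryCatch(
      .risk_matrices(dprof, dplan, coeffs_list[[ver]]),
      error = function(e) {
        stop("engine failure under ", ver, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    for (h in horizons) {
      records[[pred_col(ver, h, "all_cause")]] <-
        m$cum_bc_death[, h] + m$cum_other_death[, h]
      records[[pred_col(ver, h, "bc_specific")]] <- m$cum_bc_death[, h]
    }
  }
  records
}
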