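#' Locate a bundled PREDICT coefficient file
#'
#' The package ships one JSON coefficient file per supported PREDICT
#' version. The v2.2 file is a transcription of the published algorithm;
#' the v3.0 file is a synthetic stand-in carrying the v3.0 model
#' structure (PR terms, smoking, radiotherapy benefit and heart-dose
#' harm) with literature-scale placeholder values, and is documented as
#' such in its `description` field.
#'
#' @param version `"v2.2"` or `"v3.0"`.
#' @return Path to the bundled JSON file.
#' @export
predict_coefficients_path <- function(version = c("v2.2", "v3.0")) {
  version <- match.arg(version)
  fname <- switch(version,
    "v2.2" = "predict_v2.2.json",
    "v3.0" = "predict_v3.0_synthetic.json"
  )
  path <- system.file("extdata", fname, package = "predictval")
  if (!nzchar(path)) stop("bundled coefficient file not found: ", fname)
  path
}

#' Load and validate a PREDICT coefficient set
#'
#' Reads a versioned JSON coefficient file and validates it: the declared
#' version must match the requested one, every term the prognostic index
#' references must resolve to exactly one numeric coefficient, and the
#' baseline cumulative hazards must be nonnegative and nondecreasing over
#' years 1..15. Missing required terms are an error, never a silent
#' default.
#'
#' @param version Model version tag, `"v2.2"` or `"v3.0"`.
#' @param path Coefficient file; defaults to the bundled file for
#'   `version`.
#' @return An object of class `predict_coefs`.
#' @export
load_coefficients <- function(version = c("v2.2", "v3.0"),
                              path = predict_coefficients_path(version)) {
  version <- match.arg(version)
  if (!file.exists(path)) stop("coefficient file does not exist: ", path)
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cf$version)) stop("coefficient file declares no version tag")
  if (!identical(cf$version, version)) {
    stop("coefficient file declares version '", cf$version,
         "' but '", version, "' was requested")
  }
  .validate_coefs(cf)
  class(cf) <- "predict_coefs"
  cf
}

# terms the engine dereferences, by version
.required_terms <- function(version) {
  base <- list(
    breast_er_positive = c("age_fp1", "age_fp2", "size_log", "nodes_log",
                           "grade", "screening", "her2_positive",
                           "her2_negative", "her2_unknown", "ki67_positive",
                           "ki67_negative", "ki67_unknown"),
    breast_er_negative = c("age_linear", "size_sqrt", "nodes_log",
                           "grade_high", "her2_positive", "her2_negative",
                           "her2_unknown"),
    other = "age_sq",
    treatment_breast = c("endocrine", "chemo_second_gen", "chemo_third_gen",
                         "trastuzumab", "bisphosphonates")
  )
  if (version == "v3.0") {
    base$breast_er_positive <- c(base$breast_er_positive,
                                 c("pr_positive", "pr_negative", "pr_unknown"))
    base$breast_er_negative <- c(base$breast_er_negative,
                                 c("pr_positive", "pr_negative", "pr_unknown"))
    base$other <- c(base$other, "smoker")
    base$treatment_breast <- c(base$treatment_breast, "radiotherapy")
  }
  base
}

.check_terms <- function(have, need, where) {
  miss <- setdiff(need, names(have))
  if (length(miss)) {
    stop("coefficient file is missing required term(s) in ", where, ": ",
         paste(miss, collapse = ", "))
  }
  vals <- unlist(have[need])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("non-numeric or non-finite coefficient in ", where)
  }
  invisible(TRUE)
}

.validate_coefs <- function(cf) {
  for (k in c("baseline_hazards", "coefficients", "constants",
              "treatment_effects")) {
    if (is.null(cf[[k]])) stop("coefficient file lacks top-level key '", k, "'")
  }
  req <- .required_terms(cf$version)
  .check_terms(cf$coefficients$breast$er_positive, req$breast_er_positive,
               "coefficients$breast$er_positive")
  .check_terms(cf$coefficients$breast$er_negative, req$breast_er_negative,
               "coefficients$breast$er_negative")
  .check_terms(cf$coefficients$other, req$other, "coefficients$other")
  .check_terms(cf$treatment_effects$breast, req$treatment_breast,
               "treatment_effects$breast")
  if (cf$version == "v3.0") {
    .check_terms(cf$harms,
                 c("heart_dose_per_gy", "heart_dose_smoker_multiplier",
                   "chemo_other"), "harms")
  }
  # baseline cumulative hazards: nonnegative, nondecreasing on 1..15
  yrs <- 1:15
  for (nm in c("er_positive", "er_negative")) {
    H <- .baseline_cumhaz_breast(cf, nm, yrs)
    .check_monotone_hazard(H, paste0("breast/", nm))
  }
  .check_monotone_hazard(.baseline_cumhaz_other(cf, yrs), "other")
  invisible(TRUE)
}

.check_monotone_hazard <- function(H, label) {
  if (anyNA(H) || any(!is.finite(H))) {
    stop("non-finite baseline cumulative hazard (", label, ")")
  }
  if (any(H < 0)) {
    stop("negative baseline cumulative hazard (", label, ") at year ",
         which(H < 0)[1])
  }
  if (any(diff(H) < 0)) {
    stop("non-monotone baseline cumulative hazard (", label, ") at year ",
         which(diff(H) < 0)[1] + 1)
  }
  invisible(TRUE)
}

# baseline cumulative hazard evaluations; t must be > 0
.baseline_cumhaz_breast <- function(cf, er_stratum, t) {
  b <- cf$baseline_hazards$breast[[er_stratum]]
  if (er_stratum == "er_positive") {
    exp(b$intercept + b$inv_sqrt_time / sqrt(t) +
          b$log_time_over_sqrt_time * log(t) / sqrt(t))
  } else {
    exp(b$intercept + b$inv_time_sq / t^2 + b$inv_time / t)
  }
}

.baseline_cumhaz_other <- function(cf, t) {
  b <- cf$baseline_hazards$other
  exp(b$intercept + b$log_time * log(t) + b$sqrt_time * sqrt(t))
}

#' @export
print.predict_coefs <- function(x, ...) {
  cat("PREDICT coefficient set, version", x$version, "\n")
  cat(" breast-cause terms (ER+):",
      length(x$coefficients$breast$er_positive), "\n")
  cat(" breast-cause terms (ER-):",
      length(x$coefficients$breast$er_negative), "\n")
  cat(" treatment effects:", length(x$treatment_effects$breast), "\n")
  cat(" harm terms:", length(x$harms), "\n")
  invisible(x)
}
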