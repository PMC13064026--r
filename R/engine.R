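#' Construct a patient covariate profile
#'
#' Bundles the clinicopathological covariates PREDICT consumes for one
#' patient, with validation. Categorical inputs keep the tool's explicit
#' "unknown" levels; unknowns are distinct coefficient levels, never
#' imputed.
#'
#' @param age_at_diagnosis Age in years.
#' @param tumor_size Invasive tumour size in mm (> 0).
#' @param grade Nottingham histological grade, 1, 2 or 3.
#' @param positive_nodes Number of positive axillary nodes (integer >= 0).
#' @param micromets_only `"yes"`, `"no"` or `"unknown"`; only meaningful
#'   when `positive_nodes >= 1`, must be `"no"` when there are no
#'   positive nodes.
#' @param er_status `"positive"` or `"negative"`.
#' @param pr_status,her2_status,ki67_status `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @param detection `"screening"`, `"symptoms"` or `"unknown"`.
#' @param smoker `"yes"` or `"never_or_ex"` (used by v3.0 only).
#' @param postmenopausal `"yes"`, `"no"` or `"unknown"`.
#' @return A list of class `covariate_profile`.
#' @export
covariate_profile <- function(age_at_diagnosis, tumor_size, grade,
                              positive_nodes, micromets_only = "no",
                              er_status, pr_status = "unknown",
                              her2_status = "unknown",
                              ki67_status = "unknown",
                              detection = "unknown",
                              smoker = "never_or_ex",
                              postmenopausal = "unknown") {
  p <- list(age_at_diagnosis = age_at_diagnosis, tumor_size = tumor_size,
            grade = grade, positive_nodes = positive_nodes,
            micromets_only = micromets_only, er_status = er_status,
            pr_status = pr_status, her2_status = her2_status,
            ki67_status = ki67_status, detection = detection,
            smoker = smoker, postmenopausal = postmenopausal)
  .validate_profiles(as.data.frame(p, stringsAsFactors = FALSE))
  class(p) <- "covariate_profile"
  p
}

#' Construct an adjuvant treatment plan
#'
#' @param endocrine `"none"`, `"five_year"` or `"ten_year"` (the ten-year
#'   option exists from v2.2 on and only alters outputs beyond year 10).
#' @param chemo_generation `"none"`, `"second_gen"` (standard-dose
#'   anthracycline-based) or `"third_gen"` (taxane-containing or
#'   high-dose anthracycline).
#' @param trastuzumab,bisphosphonates,radiotherapy Logical flags.
#' @param mean_heart_dose Mean heart dose in Gy; must be 0 without
#'   radiotherapy; used by v3.0 only.
#' @return A list of class `treatment_plan`.
#' @export
treatment_plan <- function(endocrine = "none", chemo_generation = "none",
                           trastuzumab = FALSE, bisphosphonates = FALSE,
                           radiotherapy = FALSE, mean_heart_dose = 0) {
  p <- list(endocrine = endocrine, chemo_generation = chemo_generation,
            trastuzumab = trastuzumab, bisphosphonates = bisphosphonates,
            radiotherapy = radiotherapy, mean_heart_dose = mean_heart_dose)
  .validate_plans(as.data.frame(p, stringsAsFactors = FALSE))
  class(p) <- "treatment_plan"
  p
}

.chk_levels <- function(x, levels, what) {
  bad <- !(x %in% levels)
  if (any(bad)) {
    stop(what, " must be one of ", paste(levels, collapse = "/"),
         "; got '", x[bad][1], "'")
  }
}

.validate_profiles <- function(d) {
  stopifnot(is.numeric(d$age_at_diagnosis), is.numeric(d$tumor_size),
            is.numeric(d$positive_nodes))
  if (any(!is.finite(d$age_at_diagnosis))) stop("non-finite age")
  if (any(d$tumor_size <= 0)) stop("tumor_size must be > 0")
  if (any(d$positive_nodes < 0) ||
      any(d$positive_nodes != round(d$positive_nodes))) {
    stop("positive_nodes must be a nonnegative integer")
  }
  if (!all(d$grade %in% c(1, 2, 3))) stop("grade must be 1, 2 or 3")
  .chk_levels(d$micromets_only, c("yes", "no", "unknown"), "micromets_only")
  if (any(d$micromets_only == "yes" & d$positive_nodes == 0)) {
    stop("micromets_only = 'yes' requires positive_nodes >= 1")
  }
  .chk_levels(d$er_status, c("positive", "negative"), "er_status")
  .chk_levels(d$pr_status, c("positive", "negative", "unknown"), "pr_status")
  .chk_levels(d$her2_status, c("positive", "negative", "unknown"),
              "her2_status")
  .chk_levels(d$ki67_status, c("positive", "negative", "unknown"),
              "ki67_status")
  .chk_levels(d$detection, c("screening", "symptoms", "unknown"), "detection")
  .chk_levels(d$smoker, c("yes", "never_or_ex"), "smoker")
  .chk_levels(d$postmenopausal, c("yes", "no", "unknown"), "postmenopausal")
  invisible(TRUE)
}

.validate_plans <- function(d) {
  .chk_levels(d$endocrine, c("none", "five_year", "ten_year"), "endocrine")
  .chk_levels(d$chemo_generation, c("none", "second_gen", "third_gen"),
              "chemo_generation")
  stopifnot(is.logical(d$trastuzumab), is.logical(d$bisphosphonates),
            is.logical(d$radiotherapy), is.numeric(d$mean_heart_dose))
  if (any(d$mean_heart_dose < 0)) stop("mean_heart_dose must be >= 0")
  if (any(!d$radiotherapy & d$mean_heart_dose != 0)) {
    stop("mean_heart_dose must be 0 when radiotherapy is FALSE")
  }
  invisible(TRUE)
}

.profile_df <- function(profile) {
  if (inherits(profile, "covariate_profile")) {
    as.data.frame(unclass(profile), stringsAsFactors = FALSE)
  } else {
    as.data.frame(profile, stringsAsFactors = FALSE)
  }
}

.plan_df <- function(plan) {
  if (inherits(plan, "treatment_plan")) {
    as.data.frame(unclass(plan), stringsAsFactors = FALSE)
  } else {
    as.data.frame(plan, stringsAsFactors = FALSE)
  }
}

.check_age_support <- function(age, coeffs) {
  rng <- coeffs$supported_age_range
  if (!is.null(rng) && (any(age < rng[1]) || any(age > rng[2]))) {
    stop("age outside the coefficient set's supported range [",
         rng[1], ", ", rng[2], "]")
  }
}

# Vectorized cause-specific prognostic indices (log-hazard scale,
# relative to the coefficient file's reference level). Returns a list
# with pi_breast and pi_other, length nrow(d).
.prognostic_index_vec <- function(d, coeffs) {
  n <- nrow(d)
  .check_age_support(d$age_at_diagnosis, coeffs)
  cs <- coeffs$constants
  pos <- d$er_status == "positive"
  nodes_eff <- ifelse(d$micromets_only == "yes" & d$positive_nodes >= 1,
                      cs$micromets_node_value, d$positive_nodes)
  screen_w <- ifelse(d$detection == "screening", 1,
                     ifelse(d$detection == "symptoms", 0,
                            cs$detection_unknown_weight))
  lvl <- function(tab, prefix, status) {
    unlist(tab[paste0(prefix, "_", status)], use.names = FALSE)
  }
  pi_bc <- numeric(n)
  if (any(pos)) {
    b <- coeffs$coefficients$breast$er_positive
    k <- cs$er_positive
    age <- d$age_at_diagnosis[pos]
    pi_bc[pos] <-
      b$age_fp1 * ((age / 10)^-2 - k$age_fp1_center) +
      b$age_fp2 * ((age / 10)^-2 * log(age / 10) - k$age_fp2_center) +
      b$size_log * (log(d$tumor_size[pos] / 100) - k$size_log_center) +
      b$nodes_log * (log((nodes_eff[pos] + 1) / 10) - k$nodes_log_center) +
      b$grade * (d$grade[pos] - k$grade_center) +
      b$screening * screen_w[pos] +
      lvl(b, "her2", d$her2_status[pos]) +
      lvl(b, "ki67", d$ki67_status[pos])
    if (!is.null(b$pr_positive)) {
      pi_bc[pos] <- pi_bc[pos] + lvl(b, "pr", d$pr_status[pos])
    }
  }
  if (any(!pos)) {
    b <- coeffs$coefficients$breast$er_negative
    k <- cs$er_negative
    neg <- !pos
    pi_bc[neg] <-
      b$age_linear * (d$age_at_diagnosis[neg] - k$age_center) +
      b$size_sqrt * (sqrt(d$tumor_size[neg] / 100) - k$size_sqrt_center) +
      b$nodes_log * (log((nodes_eff[neg] + 1) / 10) - k$nodes_log_center) +
      b$grade_high * as.numeric(d$grade[neg] >= 2) +
      lvl(b, "her2", d$her2_status[neg])
    if (!is.null(b$pr_positive)) {
      pi_bc[neg] <- pi_bc[neg] + lvl(b, "pr", d$pr_status[neg])
    }
  }
  bo <- coeffs$coefficients$other
  pi_oth <- bo$age_sq *
    ((d$age_at_diagnosis / 10)^2 - cs$other$age_sq_center)
  if (!is.null(bo$smoker)) {
    pi_oth <- pi_oth + bo$smoker * as.numeric(d$smoker == "yes")
  }
  list(pi_breast = pi_bc, pi_other = pi_oth)
}

# Vectorized treatment log-hazard-ratio sums per cause.
# tx_breast applies to all years; tx_breast_late is the additional
# log-HR for years beyond `late_after` (extended endocrine therapy).
.treatment_effects_vec <- function(dprof, dplan, coeffs) {
  te <- coeffs$treatment_effects$breast
  hm <- coeffs$harms
  n <- nrow(dprof)
  tx <- numeric(n)
  endo <- dplan$endocrine != "none" & dprof$er_status == "positive"
  tx <- tx + ifelse(endo, te$endocrine, 0)
  tx <- tx + ifelse(dplan$chemo_generation == "second_gen",
                    te$chemo_second_gen,
                    ifelse(dplan$chemo_generation == "third_gen",
                           te$chemo_third_gen, 0))
  tx <- tx + ifelse(dplan$trastuzumab & dprof$her2_status == "positive",
                    te$trastuzumab, 0)
  tx <- tx + ifelse(dplan$bisphosphonates & dprof$postmenopausal == "yes",
                    te$bisphosphonates, 0)
  if (!is.null(te$radiotherapy)) {
    tx <- tx + ifelse(dplan$radiotherapy, te$radiotherapy, 0)
  }
  tx_late <- numeric(n)
  late_after <- 15L
  if (!is.null(te$endocrine_ten_year_extra)) {
    ex <- te$endocrine_ten_year_extra
    late_after <- as.integer(ex$applies_after_year)
    tx_late <- ifelse(endo & dplan$endocrine == "ten_year", ex$log_hr, 0)
  } else if (any(dplan$endocrine == "ten_year")) {
    stop("coefficient set '", coeffs$version,
         "' has no ten-year endocrine term")
  }
  tx_oth <- numeric(n)
  if (length(hm)) {
    if (!is.null(hm$heart_dose_per_gy)) {
      mult <- ifelse(dprof$smoker == "yes", hm$heart_dose_smoker_multiplier, 1)
      tx_oth <- tx_oth + ifelse(dplan$radiotherapy,
                                hm$heart_dose_per_gy *
                                  dplan$mean_heart_dose * mult, 0)
    }
    if (!is.null(hm$chemo_other)) {
      tx_oth <- tx_oth + ifelse(dplan$chemo_generation != "none",
                                hm$chemo_other, 0)
    }
  } else if (any(dplan$mean_heart_dose > 0)) {
    warning("coefficient set '", coeffs$version,
            "' has no heart-dose harm term; mean_heart_dose ignored")
  }
  list(tx_breast = tx, tx_breast_late = tx_late, late_after = late_after,
       tx_other = tx_oth)
}

# Vectorized engine core: yearly cumulative mortality by cause for a
# data frame of profiles + plans. Deaths within a year are apportioned
# to causes by their hazard-increment share. Returns a list of n x 15
# matrices (years 1..15).
.risk_matrices <- function(dprof, dplan, coeffs) {
  .validate_profiles(dprof)
  .validate_plans(dplan)
  stopifnot(nrow(dprof) == nrow(dplan))
  n <- nrow(dprof)
  yrs <- 1:15
  pis <- .prognostic_index_vec(dprof, coeffs)
  txs <- .treatment_effects_vec(dprof, dplan, coeffs)

  base_bc <- matrix(0, n, 15)
  pos <- dprof$er_status == "positive"
  if (any(pos)) {
    base_bc[pos, ] <- matrix(.baseline_cumhaz_breast(coeffs, "er_positive",
                                                     yrs),
                             sum(pos), 15, byrow = TRUE)
  }
  if (any(!pos)) {
    base_bc[!pos, ] <- matrix(.baseline_cumhaz_breast(coeffs, "er_negative",
                                                      yrs),
                              sum(!pos), 15, byrow = TRUE)
  }
  base_oth <- matrix(.baseline_cumhaz_other(coeffs, yrs), n, 15, byrow = TRUE)

  inc <- function(H) H - cbind(0, H[, -15, drop = FALSE])
  db <- inc(base_bc) * exp(pis$pi_breast + txs$tx_breast)
  if (any(txs$tx_breast_late != 0)) {
    late <- yrs > txs$late_after
    db[, late] <- db[, late, drop = FALSE] * exp(txs$tx_breast_late)
  }
  do <- inc(base_oth) * exp(pis$pi_other + txs$tx_other)
  if (any(!is.finite(db)) || any(!is.finite(do))) {
    stop("non-finite intermediate hazard in risk computation")
  }
  Hb <- t(apply(db, 1, cumsum))
  Ho <- t(apply(do, 1, cumsum))
  if (n == 1) { Hb <- matrix(Hb, 1); Ho <- matrix(Ho, 1) }
  S <- exp(-(Hb + Ho))
  Sprev <- cbind(1, S[, -15, drop = FALSE])
  m <- Sprev - S
  tot <- db + do
  fb <- ifelse(tot > 0, db / tot, 0)
  cum_bc <- t(apply(m * fb, 1, cumsum))
  cum_oth <- t(apply(m * (1 - fb), 1, cumsum))
  if (n == 1) { cum_bc <- matrix(cum_bc, 1); cum_oth <- matrix(cum_oth, 1) }
  list(cum_bc_death = cum_bc, cum_other_death = cum_oth,
       overall_survival = S)
}

#' Cause-specific prognostic index
#'
#' Linear predictor (log-hazard scale) for one patient under a loaded
#' coefficient set, relative to the file's reference level. Deterministic
#' and additive in the coefficient table given the fixed covariate
#' transforms.
#'
#' @param profile A [covariate_profile()].
#' @param coeffs A [load_coefficients()] result.
#' @param cause `"breast"` or `"other"`.
#' @return A single real number.
#' @export
prognostic_index <- function(profile, coeffs, cause = c("breast", "other")) {
  cause <- match.arg(cause)
  stopifnot(inherits(coeffs, "predict_coefs"))
  d <- .profile_df(profile)
  .validate_profiles(d)
  pis <- .prognostic_index_vec(d, coeffs)
  if (cause == "breast") pis$pi_breast else pis$pi_other
}

#' Yearly risk curve for one patient
#'
#' Runs the PREDICT engine for one patient: yearly (1..15) baseline
#' cause-specific cumulative hazards are scaled by
#' `exp(prognostic index + treatment log hazard ratios)` per cause, and
#' within-year deaths are apportioned to causes in proportion to the
#' cause-specific hazard increments. A year-0 row (all risks zero,
#' survival one) anchors the grid. An all-`"none"` treatment plan
#' reproduces the untreated baseline prognosis.
#'
#' @param profile A [covariate_profile()].
#' @param plan A [treatment_plan()].
#' @param coeffs A [load_coefficients()] result.
#' @return Data frame of class `risk_curve` with columns `year`,
#'   `cum_bc_death`, `cum_other_death`, `cum_all_cause_death`,
#'   `overall_survival`.
#' @export
risk_curve <- function(profile, plan, coeffs) {
  stopifnot(inherits(coeffs, "predict_coefs"))
  dprof <- .profile_df(profile)
  dplan <- .plan_df(plan)
  m <- .risk_matrices(dprof, dplan, coeffs)
  out <- data.frame(
    year = 0:15,
    cum_bc_death = c(0, m$cum_bc_death[1, ]),
    cum_other_death = c(0, m$cum_other_death[1, ]),
    overall_survival = c(1, m$overall_survival[1, ])
  )
  out$cum_all_cause_death <- out$cum_bc_death + out$cum_other_death
  out <- out[, c("year", "cum_bc_death", "cum_other_death",
                 "cum_all_cause_death", "overall_survival")]
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Read a predicted risk off a risk curve
#'
#' @param curve A [risk_curve()].
#' @param horizon Horizon in years; must lie on the curve's yearly grid.
#' @param outcome `"all_cause"` or `"bc_specific"`.
#' @return Cumulative mortality probability at the horizon.
#' @export
predicted_risk <- function(curve, horizon,
                           outcome = c("all_cause", "bc_specific")) {
  outcome <- match.arg(outcome)
  i <- match(horizon, curve$year)
  if (is.na(i)) stop("horizon ", horizon, " is not on the curve grid")
  if (outcome == "all_cause") curve$cum_all_cause_death[i]
  else curve$cum_bc_death[i]
}
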