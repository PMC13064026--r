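#' Distortion functions linking predicted and true risk
#'
#' A distortion maps the engine's predicted risk to the ground-truth
#' risk used to simulate outcomes, so calibration statistics can be
#' checked against a known answer: `identity` (perfect calibration),
#' `proportional(k)` (true risk `k * p`), and `cloglog_shift(delta)`
#' (shift by `delta` on the complementary log-log scale, i.e. a
#' proportional-hazards miscalibration).
#'
#' @param k Proportionality constant in `[0, 1]`.
#' @param delta Shift on the cloglog scale.
#' @return Object of class `distortion_fn` with elements `name`,
#'   `params` and `fn`.
#' @export
distortion_identity <- function() {
  structure(list(name = "identity", params = list(), fn = function(p) p),
            class = "distortion_fn")
}

#' @rdname distortion_identity
#' @export
distortion_proportional <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k <= 1)
  structure(list(name = "proportional", params = list(k = k),
                 fn = function(p) k * p),
            class = "distortion_fn")
}

#' @rdname distortion_identity
#' @export
distortion_cloglog_shift <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1)
  structure(list(name = "cloglog_shift", params = list(delta = delta),
                 fn = function(p) {
                   p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
                   1 - exp(-exp(log(-log(1 - p)) + delta))
                 }),
            class = "distortion_fn")
}

# deterministic substream seeds derived from (seed, stream index);
# kept below 2^31 - 1
.substream <- function(seed, k) {
  v <- ((as.double(seed) %% 94906265) * 22695477 + 1 +
          7919 * as.double(k)) %% 2147483647
  as.integer(v)
}

#' Specification of a synthetic registry cohort
#'
#' Defaults emulate the validation cohort's covariate mix: ~74%
#' ER-positive, ~55% grade 3, ~60% node-negative, subtype shares of
#' roughly 59% Luminal / 21% HER2+ / 20% TNBC, tumour size log-normal
#' around a 20 mm median, diagnoses uniform over 2008-2019, and an
#' administrative registry cut-off of 2021-03-09. Treatment assignment
#' follows clinical coherence rules (trastuzumab only if HER2+,
#' endocrine therapy predominantly if ER+). A distortion function links
#' engine predictions to the simulated ground truth.
#'
#' @param n Number of patients.
#' @param seed Integer seed; one global seed governs all draws through
#'   documented substreams.
#' @param distortion A `distortion_fn`.
#' @param other_cause_hazard,emigration_hazard Constant yearly rates for
#'   the competing causes.
#' @param registry_cutoff Administrative censoring date.
#' @param version Engine version that defines the predicted (and via
#'   the distortion, true) breast-cancer risks.
#' @param smoking_mode Smoking imputation used when generating truth.
#' @param diagnosis_window Two dates bounding the diagnosis dates.
#' @param ... Overrides for the marginal tables (see source for names).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L,
                        distortion = distortion_identity(),
                        other_cause_hazard = 0.001,
                        emigration_hazard = 0.002,
                        registry_cutoff = "2021-03-09",
                        version = "v3.0",
                        smoking_mode = "all_nonsmokers",
                        diagnosis_window = c("2008-01-01", "2019-12-31"),
                        ...) {
  spec <- list(
    n = as.integer(n), seed = as.integer(seed), distortion = distortion,
    other_cause_hazard = other_cause_hazard,
    emigration_hazard = emigration_hazard,
    registry_cutoff = registry_cutoff, version = version,
    smoking_mode = smoking_mode, diagnosis_window = diagnosis_window,
    subtype_mix = c("Luminal" = 0.59, "HER2+" = 0.21, "TNBC" = 0.20),
    her2pos_er_positive_prob = 0.72,
    pr_positive_prob_er_pos = 0.89,
    pr_positive_prob_er_neg = 0.05,
    grade_mix_by_subtype = list(
      "Luminal" = c(0.17, 0.47, 0.36),
      "HER2+"   = c(0.023, 0.285, 0.692),
      "TNBC"    = c(0.006, 0.037, 0.957)
    ),
    ki67_mix = c(positive = 0.46, negative = 0.05, unknown = 0.49),
    detection_mix = c(screening = 0.141, symptoms = 0.855, unknown = 0.004),
    nodes_probs = c(0.60, 0.17, 0.081, 0.046, 0.023),  # 0..4; rest 5..15
    size_meanlog = log(20), size_sdlog = 0.55,
    age_beta = c(5, 1.6),
    micromets_prob = 0.10,
    postmenopausal_prob = 0.02,
    endocrine_prob_er_pos = 0.73, endocrine_prob_er_neg = 0.03,
    chemo_mix_by_subtype = list(
      "Luminal" = c(none = 0.48, second_gen = 0.36, third_gen = 0.16),
      "HER2+"   = c(none = 0.27, second_gen = 0.51, third_gen = 0.22),
      "TNBC"    = c(none = 0.32, second_gen = 0.47, third_gen = 0.21)
    ),
    trastuzumab_prob_her2pos = 0.74,
    radiotherapy_prob = c(N0 = 0.49, Npos = 0.69),
    bisphosphonate_prob = 0.006
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown cohort_spec field(s): ",
                        paste(bad, collapse = ", "))
  spec[names(dots)] <- dots
  .validate_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

.validate_spec <- function(spec) {
  if (spec$n < 1) stop("n must be >= 1")
  if (spec$other_cause_hazard < 0 || spec$emigration_hazard < 0) {
    stop("hazards must be >= 0")
  }
  if (!inherits(spec$distortion, "distortion_fn")) {
    stop("distortion must be a distortion_fn")
  }
  chk1 <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8) stop(what, " must sum to 1")
    if (any(p < 0)) stop(what, " must be nonnegative")
  }
  chk1(spec$subtype_mix, "subtype_mix")
  chk1(spec$ki67_mix, "ki67_mix")
  chk1(spec$detection_mix, "detection_mix")
  for (g in spec$grade_mix_by_subtype) chk1(g, "grade mix")
  for (g in spec$chemo_mix_by_subtype) chk1(g, "chemo mix")
  if (sum(spec$nodes_probs) > 1 + 1e-8) stop("nodes_probs exceed 1")
  invisible(TRUE)
}

#' Generate registry-style covariate rows
#'
#' Draws raw patient rows (the CSV dialect the cohort pipeline reads)
#' from a [cohort_spec()]. Reproducible given the seed; empirical
#' marginals converge to the spec as `n` grows. Outcome fields are
#' placeholders until [generate_outcomes()] fills them.
#'
#' @param spec A `cohort_spec`.
#' @return Raw cohort data frame.
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(.substream(spec$seed, 1L))
  n <- spec$n
  subtype <- sample(names(spec$subtype_mix), n, TRUE, spec$subtype_mix)
  er_pos <- ifelse(subtype == "Luminal", TRUE,
                   ifelse(subtype == "TNBC", FALSE,
                          stats::runif(n) < spec$her2pos_er_positive_prob))
  pr_pos <- ifelse(subtype == "TNBC", FALSE,
                   stats::runif(n) < ifelse(er_pos,
                                            spec$pr_positive_prob_er_pos,
                                            spec$pr_positive_prob_er_neg))
  her2_pos <- subtype == "HER2+"
  grade <- vapply(subtype, function(s) {
    sample(1:3, 1, prob = spec$grade_mix_by_subtype[[s]])
  }, integer(1))
  ki67 <- sample(names(spec$ki67_mix), n, TRUE, spec$ki67_mix)
  detection <- sample(names(spec$detection_mix), n, TRUE, spec$detection_mix)
  nodes_hi_p <- max(0, 1 - sum(spec$nodes_probs))
  nodes_pool <- c(0:4, 5:15)
  nodes_prob <- c(spec$nodes_probs,
                  nodes_hi_p * stats::dgeom(0:10, 0.35) /
                    sum(stats::dgeom(0:10, 0.35)))
  nodes <- sample(nodes_pool, n, TRUE, nodes_prob)
  size <- pmax(1, round(stats::rlnorm(n, spec$size_meanlog,
                                      spec$size_sdlog), 1))
  age <- round(25 + 15 * stats::rbeta(n, spec$age_beta[1],
                                      spec$age_beta[2]), 1)
  micromets <- ifelse(nodes >= 1 & stats::runif(n) < spec$micromets_prob,
                      "yes", "no")
  postmeno <- ifelse(stats::runif(n) < spec$postmenopausal_prob, "yes", "no")
  endocrine <- stats::runif(n) < ifelse(er_pos, spec$endocrine_prob_er_pos,
                                        spec$endocrine_prob_er_neg)
  chemo <- vapply(subtype, function(s) {
    sample(names(spec$chemo_mix_by_subtype[[s]]), 1,
           prob = spec$chemo_mix_by_subtype[[s]])
  }, character(1))
  regimen <- ifelse(chemo == "none", "",
                    ifelse(chemo == "second_gen",
                           sample(c("FEC", "EC", "AC"), n, TRUE),
                           sample(c("FEC + docetaxel", "paclitaxel",
                                    "EC + paclitaxel", "docetaxel"),
                                  n, TRUE)))
  trastuzumab <- her2_pos & stats::runif(n) < spec$trastuzumab_prob_her2pos
  radio <- stats::runif(n) < ifelse(nodes == 0,
                                    spec$radiotherapy_prob[["N0"]],
                                    spec$radiotherapy_prob[["Npos"]])
  bisph <- stats::runif(n) < spec$bisphosphonate_prob
  laterality <- sample(c("left", "right"), n, TRUE)
  win <- .parse_date(spec$diagnosis_window)
  diagnosis <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n,
                                   TRUE) - 1L
  # registry-style assay percentages consistent with the drawn statuses
  er_pct <- ifelse(er_pos, sample(10:100, n, TRUE), sample(0:9, n, TRUE))
  pr_pct <- ifelse(pr_pos, sample(10:100, n, TRUE), sample(0:9, n, TRUE))
  ki67_pct <- ifelse(ki67 == "positive", sample(11:100, n, TRUE),
                     ifelse(ki67 == "negative", sample(0:10, n, TRUE), NA))
  ihc3 <- stats::runif(n) < 0.7
  her2_ihc <- ifelse(her2_pos, ifelse(ihc3, "3+", "2+"),
                     sample(c("0", "1+", "2+"), n, TRUE,
                            prob = c(0.5, 0.35, 0.15)))
  her2_ish <- ifelse(her2_ihc == "2+", ifelse(her2_pos, "yes", "no"), "")
  stage <- ifelse(nodes >= 4 | size > 50, "III",
                  ifelse(nodes >= 1 | size > 20, "II", "I"))
  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    diagnosis_date = as.character(diagnosis),
    age = age, sex = "female", stage = stage, invasive_flag = "invasive",
    surgery_flag = TRUE, er_percent = er_pct, pr_percent = pr_pct,
    ki67_percent = ki67_pct, her2_ihc = her2_ihc,
    her2_ish_amplified = her2_ish, nhg = grade, size_mm = size,
    nodes_positive = nodes, micromets_only = micromets,
    detection_mode = detection, laterality = laterality,
    endocrine_flag = endocrine, chemo_regimen_text = regimen,
    trastuzumab_flag = trastuzumab, bisphosphonate_flag = bisph,
    radiotherapy_flag = radio,
    vital_status_date = as.character(.parse_date(spec$registry_cutoff)),
    status = "alive", cause_of_death = "n/a",
    stringsAsFactors = FALSE
  )
}

# invert a two-piece constant cumulative hazard (pieces [0,5), [5,Inf)
# with rates l1, l2) at exponential draws e
.invert_two_piece <- function(e, l1, l2) {
  t <- rep(Inf, length(e))
  brk <- 5 * l1
  lo <- e < brk | (l2 == 0 & l1 > 0 & e < brk)
  lo <- e < brk
  t[lo & l1 > 0] <- e[lo & l1 > 0] / l1[lo & l1 > 0]
  hi <- !lo & l2 > 0
  t[hi] <- 5 + (e[hi] - brk[hi]) / l2[hi]
  t
}

#' Simulate follow-up and cause of death for generated rows
#'
#' For each patient the engine's predicted 5- and 10-year breast-cancer
#' -specific risks are transformed by the spec's distortion into true
#' risks; a two-piece constant cause-specific hazard on `[0,5)` /
#' `[5,10)` is solved in closed form so the cumulative risks at 5 and 10
#' years equal the truth (the second-piece rate also extends beyond year
#' 10). Other-cause death and emigration times are exponential with the
#' spec's rates, and administrative censoring follows from the diagnosis
#' date and registry cut-off. Ground truth is returned alongside.
#'
#' @param rows Output of [generate_covariates()].
#' @param coeffs Coefficient set for `spec$version` (loaded if `NULL`).
#' @param spec The `cohort_spec`.
#' @return `list(rows, truth)`: `rows` with outcome fields filled,
#'   `truth` holding predicted and true risks and the latent times.
#' @export
generate_outcomes <- function(rows, coeffs = NULL, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(coeffs)) coeffs <- load_coefficients(spec$version)
  set.seed(.substream(spec$seed, 2L))
  n <- nrow(rows)
  rec <- build_records(rows, spec$smoking_mode)
  prof_cols <- c("age_at_diagnosis", "tumor_size", "grade", "positive_nodes",
                 "micromets_only", "er_status", "pr_status", "her2_status",
                 "ki67_status", "detection", "smoker", "postmenopausal")
  plan_cols <- c("endocrine", "chemo_generation", "trastuzumab",
                 "bisphosphonates", "radiotherapy", "mean_heart_dose")
  m <- .risk_matrices(rec[, prof_cols], rec[, plan_cols], coeffs)
  p5 <- m$cum_bc_death[, 5]
  p10 <- m$cum_bc_death[, 10]
  g <- spec$distortion$fn
  true5 <- g(p5)
  true10 <- g(p10)
  if (any(true5 < 0 | true5 > 1 | true10 < 0 | true10 > 1)) {
    stop("distortion maps a risk outside [0, 1]")
  }
  if (any(true10 < true5 - 1e-12)) {
    stop("infeasible hazard calibration: true 10-year risk below ",
         "true 5-year risk")
  }
  cl <- function(p) pmin(p, 1 - 1e-12)
  l1 <- -log(1 - cl(true5)) / 5
  l2 <- pmax(0, (-log(1 - cl(true10)) + log(1 - cl(true5))) / 5)
  t_bc <- .invert_two_piece(stats::rexp(n), l1, l2)
  t_oth <- if (spec$other_cause_hazard > 0) {
    stats::rexp(n, spec$other_cause_hazard)
  } else rep(Inf, n)
  t_em <- if (spec$emigration_hazard > 0) {
    stats::rexp(n, spec$emigration_hazard)
  } else rep(Inf, n)
  diag_d <- .parse_date(rows$diagnosis_date)
  admin <- as.numeric(.parse_date(spec$registry_cutoff) - diag_d) / 365.25
  t_obs <- pmin(t_bc, t_oth, t_em, admin)
  cause <- ifelse(t_obs == admin, "censored",
                  ifelse(t_obs == t_bc, "bc_death",
                         ifelse(t_obs == t_oth, "other_death", "emigrated")))
  rows$status <- ifelse(cause == "censored", "alive",
                        ifelse(cause == "emigrated", "emigrated", "dead"))
  rows$cause_of_death <- ifelse(cause == "bc_death", "breast_cancer",
                                ifelse(cause == "other_death", "other",
                                       "n/a"))
  # event dates carried at day resolution, at least one day of follow-up
  rows$vital_status_date <- as.character(diag_d +
                                           pmax(1, round(t_obs * 365.25)))
  truth <- data.frame(id = rows$id, predicted_5y = p5, predicted_10y = p10,
                      true_5y = true5, true_10y = true10,
                      lambda1 = l1, lambda2 = l2, t_bc = t_bc,
                      t_other = t_oth, t_emigration = t_em,
                      admin_censor_years = admin,
                      stringsAsFactors = FALSE)
  list(rows = rows, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_covariates()] then
#' [generate_outcomes()].
#'
#' @inheritParams generate_outcomes
#' @return `list(rows, truth, spec)`.
#' @export
simulate_cohort <- function(spec, coeffs = NULL) {
  rows <- generate_covariates(spec)
  out <- generate_outcomes(rows, coeffs, spec)
  list(rows = out$rows, truth = out$truth, spec = spec)
}

# template raw row for handcrafted fixtures
.raw_row <- function(...) {
  base <- list(
    id = "X", diagnosis_date = "2010-06-15", age = 35, sex = "female",
    stage = "II", invasive_flag = "invasive", surgery_flag = TRUE,
    er_percent = 80, pr_percent = 60, ki67_percent = 30, her2_ihc = "0",
    her2_ish_amplified = "", nhg = 2L, size_mm = 22, nodes_positive = 0,
    micromets_only = "no", detection_mode = "symptoms",
    laterality = "right", endocrine_flag = TRUE, chemo_regimen_text = "",
    trastuzumab_flag = FALSE, bisphosphonate_flag = FALSE,
    radiotherapy_flag = FALSE, vital_status_date = "2021-03-09",
    status = "alive", cause_of_death = "n/a"
  )
  ov <- list(...)
  base[names(ov)] <- ov
  as.data.frame(base, stringsAsFactors = FALSE)
}

#' Handcrafted fixture cohorts with enumerated expectations
#'
#' Small deterministic cohorts covering eligibility and mapping edge
#' cases, together with the expected downstream state.
#'
#' `"eligibility_edges"`: one row per exclusion rule plus retained rows;
#' `expected_ledger` enumerates the per-rule exclusion counts.
#' `"biomarker_edges"`: threshold rows for ER (10% boundary), Ki67
#' (strictly above 10%), and the HER2 IHC/ISH decision table;
#' `expected$er_status` etc. give the mapped levels in row order.
#' `"horizon_edges"`: diagnosis dates straddling the registry cut-off
#' minus 5/10 years; `expected$in_5y`/`in_10y` flag horizon membership.
#'
#' @param name Preset tag.
#' @return `list(rows, expected_ledger, expected)` (fields as relevant).
#' @export
fixture_cohort <- function(name = c("eligibility_edges", "biomarker_edges",
                                    "horizon_edges")) {
  name <- match.arg(name)
  if (name == "eligibility_edges") {
    rows <- rbind(
      .raw_row(id = "keep1"),
      .raw_row(id = "keep2", age = 25, nodes_positive = 2,
               chemo_regimen_text = "FEC"),
      .raw_row(id = "male", sex = "male"),
      .raw_row(id = "age41", age = 41),
      .raw_row(id = "age24", age = 24.9),
      .raw_row(id = "insitu", invasive_flag = "in_situ_only"),
      .raw_row(id = "stage4", stage = "IV"),
      .raw_row(id = "nosurg", surgery_flag = FALSE),
      .raw_row(id = "noer", er_percent = NA),
      .raw_row(id = "nonhg", nhg = NA),
      .raw_row(id = "badfu", vital_status_date = "2010-06-15"),
      .raw_row(id = "baddate", diagnosis_date = "not-a-date")
    )
    expected_ledger <- data.frame(
      rule = c("unparseable", "not_female", "age_out_of_range",
               "in_situ_only", "stage_not_I_III", "no_surgery",
               "missing_er", "missing_grade", "nonpositive_followup"),
      n_excluded = c(1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)
    )
    return(list(rows = rows, expected_ledger = expected_ledger,
                expected = list(retained_ids = c("keep1", "keep2"))))
  }
  if (name == "biomarker_edges") {
    rows <- rbind(
      .raw_row(id = "er10", er_percent = 10),
      .raw_row(id = "er9", er_percent = 9),
      .raw_row(id = "ki10", ki67_percent = 10),
      .raw_row(id = "ki11", ki67_percent = 11),
      .raw_row(id = "kina", ki67_percent = NA),
      .raw_row(id = "h3", her2_ihc = "3+"),
      .raw_row(id = "h2amp", her2_ihc = "2+", her2_ish_amplified = "yes"),
      .raw_row(id = "h2no", her2_ihc = "2+", her2_ish_amplified = "no"),
      .raw_row(id = "h2na", her2_ihc = "2+", her2_ish_amplified = ""),
      .raw_row(id = "h1", her2_ihc = "1+"),
      .raw_row(id = "hna", her2_ihc = "")
    )
    expected <- list(
      er_status = c("positive", "negative", rep("positive", 9)),
      ki67_status = c("positive", "positive", "negative", "positive",
                      "unknown", rep("positive", 6)),
      her2_status = c("negative", "negative", "negative", "negative",
                      "negative", "positive", "positive", "negative",
                      "unknown", "negative", "unknown")
    )
    return(list(rows = rows, expected = expected))
  }
  # horizon_edges
  rows <- rbind(
    .raw_row(id = "late5", diagnosis_date = "2016-03-10"),
    .raw_row(id = "edge5", diagnosis_date = "2016-03-09"),
    .raw_row(id = "early", diagnosis_date = "2010-01-01"),
    .raw_row(id = "edge10", diagnosis_date = "2011-03-09"),
    .raw_row(id = "late10", diagnosis_date = "2011-03-10")
  )
  expected <- list(
    in_5y = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    in_10y = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    cutoff = "2021-03-09"
  )
  list(rows = rows, expected = expected)
}
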