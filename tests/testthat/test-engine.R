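test_that("profile and plan constructors enforce invariants", {
  expect_error(covariate_profile(35, -1, 2, 0, er_status = "positive"),
               "tumor_size")
  expect_error(covariate_profile(35, 20, 4, 0, er_status = "positive"),
               "grade")
  expect_error(covariate_profile(35, 20, 2, 0, micromets_only = "yes",
                                 er_status = "positive"),
               "micromets_only")
  expect_error(treatment_plan(radiotherapy = FALSE, mean_heart_dose = 2),
               "mean_heart_dose")
  expect_s3_class(h_ref_profile(), "covariate_profile")
})

test_that("prognostic index is zero at the reference level and additive", {
  toy <- h_toy_coeffs()
  expect_equal(prognostic_index(h_ref_profile(), toy, "breast"), 0)
  expect_equal(prognostic_index(h_ref_profile(), toy, "other"), 0)
  # additivity: doubling one coefficient shifts the PI by exactly that
  # term's contribution, recomputed term-by-term as the oracle
  cf2 <- h_cf2()
  prof <- covariate_profile(34, 28, 2, 3, er_status = "positive",
                            pr_status = "positive",
                            her2_status = "negative",
                            ki67_status = "positive",
                            detection = "screening")
  pi0 <- prognostic_index(prof, cf2, "breast")
  p_dbl <- h_modified_coeffs("v2.2", function(cf) {
    cf$coefficients$breast$er_positive$size_log <-
      2 * cf$coefficients$breast$er_positive$size_log
    cf
  })
  cf_dbl <- load_coefficients("v2.2", p_dbl)
  contrib <- cf2$coefficients$breast$er_positive$size_log *
    (log(28 / 100) - cf2$constants$er_positive$size_log_center)
  expect_equal(prognostic_index(prof, cf_dbl, "breast"), pi0 + contrib,
               tolerance = 1e-12)
})

test_that("higher grade raises the breast-cause prognostic index", {
  for (cf in list(h_cf2(), h_cf3())) {
    for (er in c("positive", "negative")) {
      lo <- covariate_profile(35, 20, 1, 0, er_status = er)
      hi <- covariate_profile(35, 20, 3, 0, er_status = er)
      expect_gt(prognostic_index(hi, cf, "breast"),
                prognostic_index(lo, cf, "breast"))
    }
  }
})

test_that("risk curve matches the exponential closed form on a toy set", {
  toy <- h_toy_coeffs(H5 = 0.10)
  rc <- risk_curve(h_ref_profile(), treatment_plan(), toy)
  # year 0 row: empty integration
  expect_equal(rc$cum_all_cause_death[rc$year == 0], 0)
  expect_equal(rc$overall_survival[rc$year == 0], 1)
  # H_bc(5) = 0.10, negligible other-cause hazard
  expect_equal(predicted_risk(rc, 5, "all_cause"), 1 - exp(-0.10),
               tolerance = 1e-8)
  expect_equal(predicted_risk(rc, 5, "bc_specific"), 1 - exp(-0.10),
               tolerance = 1e-8)
})

test_that("risk curves conserve probability and are monotone", {
  set.seed(42)
  cf3 <- h_cf3()
  for (i in 1:20) {
    prof <- covariate_profile(
      runif(1, 25, 40), runif(1, 3, 60), sample(1:3, 1),
      rpois(1, 1.5), er_status = sample(c("positive", "negative"), 1),
      pr_status = sample(c("positive", "negative", "unknown"), 1),
      her2_status = sample(c("positive", "negative", "unknown"), 1),
      ki67_status = sample(c("positive", "negative", "unknown"), 1),
      detection = sample(c("screening", "symptoms", "unknown"), 1))
    plan <- treatment_plan(
      endocrine = sample(c("none", "five_year"), 1),
      chemo_generation = sample(c("none", "second_gen", "third_gen"), 1),
      trastuzumab = sample(c(TRUE, FALSE), 1),
      radiotherapy = TRUE, mean_heart_dose = sample(c(0, 2), 1))
    rc <- risk_curve(prof, plan, cf3)
    expect_lt(max(abs(rc$cum_bc_death + rc$cum_other_death +
                        rc$overall_survival - 1)), 1e-10)
    expect_true(all(diff(rc$cum_bc_death) >= 0))
    expect_true(all(diff(rc$cum_other_death) >= 0))
    expect_true(all(rc$cum_all_cause_death >= 0 &
                      rc$cum_all_cause_death <= 1))
  }
})

test_that("risk ordering is monotone in size, nodes and grade", {
  set.seed(7)
  for (cf in list(h_cf2(), h_cf3())) {
    for (i in 1:10) {
      base <- list(age_at_diagnosis = runif(1, 25, 40),
                   tumor_size = runif(1, 5, 40),
                   grade = sample(1:2, 1),
                   positive_nodes = sample(0:3, 1),
                   er_status = sample(c("positive", "negative"), 1))
      mk <- function(ov) {
        a <- base
        a[names(ov)] <- ov
        do.call(covariate_profile, a)
      }
      pl <- treatment_plan()
      r0 <- risk_curve(mk(list()), pl, cf)
      for (h in c(5, 10)) {
        p0 <- predicted_risk(r0, h, "bc_specific")
        up_size <- risk_curve(mk(list(tumor_size = base$tumor_size + 15)),
                              pl, cf)
        up_nodes <- risk_curve(mk(list(positive_nodes =
                                         base$positive_nodes + 4)), pl, cf)
        up_grade <- risk_curve(mk(list(grade = base$grade + 1)), pl, cf)
        expect_gte(predicted_risk(up_size, h, "bc_specific"), p0)
        expect_gte(predicted_risk(up_nodes, h, "bc_specific"), p0)
        expect_gte(predicted_risk(up_grade, h, "bc_specific"), p0)
      }
    }
  }
})

test_that("treatment never increases breast-cancer-specific mortality", {
  set.seed(11)
  for (cf in list(h_cf2(), h_cf3())) {
    for (i in 1:10) {
      prof <- covariate_profile(runif(1, 25, 40), runif(1, 5, 50),
                                sample(1:3, 1), sample(0:5, 1),
                                er_status = "positive",
                                her2_status = "positive")
      none <- risk_curve(prof, treatment_plan(), cf)
      trt <- risk_curve(prof, treatment_plan(endocrine = "five_year",
                                             chemo_generation = "third_gen",
                                             trastuzumab = TRUE), cf)
      for (h in 1:15) {
        expect_lte(predicted_risk(trt, h, "bc_specific"),
                   predicted_risk(none, h, "bc_specific"))
      }
    }
  }
})

test_that("an all-none plan reproduces the untreated baseline", {
  cf3 <- h_cf3()
  prof <- covariate_profile(32, 25, 3, 1, er_status = "positive",
                            her2_status = "positive")
  rc <- risk_curve(prof, treatment_plan(), cf3)
  pi_bc <- prognostic_index(prof, cf3, "breast")
  H5 <- predictval:::.baseline_cumhaz_breast(cf3, "er_positive", 1:5)
  # with no treatment the year-wise bc hazard is baseline * exp(PI)
  pi_ot <- prognostic_index(prof, cf3, "other")
  Ho5 <- predictval:::.baseline_cumhaz_other(cf3, 1:5)
  S <- exp(-(H5[5] * exp(pi_bc) + Ho5[5] * exp(pi_ot)))
  expect_equal(rc$overall_survival[rc$year == 5], S, tolerance = 1e-12)
})

test_that("versions differ, and smoking only acts through v3.0 terms", {
  set.seed(3)
  cf2 <- h_cf2()
  cf3 <- h_cf3()
  diffs <- numeric(0)
  for (i in 1:10) {
    prof <- covariate_profile(runif(1, 25, 40), runif(1, 5, 50),
                              sample(1:3, 1), sample(0:4, 1),
                              er_status = sample(c("positive",
                                                   "negative"), 1))
    r2 <- predicted_risk(risk_curve(prof, treatment_plan(), cf2), 5,
                         "bc_specific")
    r3 <- predicted_risk(risk_curve(prof, treatment_plan(), cf3), 5,
                         "bc_specific")
    expect_true(is.finite(r2) && is.finite(r3))
    diffs <- c(diffs, abs(r2 - r3))
  }
  expect_gt(max(diffs), 0)
  # smoker vs never differ under v3.0; identical once the smoking
  # coefficient is zeroed (term isolation)
  smoker <- covariate_profile(35, 20, 2, 0, er_status = "positive",
                              smoker = "yes")
  never <- covariate_profile(35, 20, 2, 0, er_status = "positive",
                             smoker = "never_or_ex")
  pl <- treatment_plan()
  c_s <- risk_curve(smoker, pl, cf3)
  c_n <- risk_curve(never, pl, cf3)
  expect_gt(max(abs(c_s$cum_other_death - c_n$cum_other_death)), 0)
  cf3z <- load_coefficients("v3.0", h_modified_coeffs("v3.0", function(cf) {
    cf$coefficients$other$smoker <- 0
    cf$harms$heart_dose_smoker_multiplier <- 1
    cf
  }))
  expect_equal(risk_curve(smoker, pl, cf3z), risk_curve(never, pl, cf3z))
})

test_that("heart dose is ignored with a warning under v2.2", {
  prof <- covariate_profile(35, 20, 2, 0, er_status = "positive")
  pl <- treatment_plan(radiotherapy = TRUE, mean_heart_dose = 2)
  expect_warning(risk_curve(prof, pl, h_cf2()), "mean_heart_dose ignored")
})

test_that("predicted_risk reads the curve and is monotone in horizon", {
  rc <- risk_curve(h_ref_profile(), treatment_plan(), h_cf2())
  expect_equal(predicted_risk(rc, 5, "all_cause"),
               rc$cum_bc_death[rc$year == 5] +
                 rc$cum_other_death[rc$year == 5])
  expect_gte(predicted_risk(rc, 10, "bc_specific"),
             predicted_risk(rc, 5, "bc_specific"))
  expect_gte(predicted_risk(rc, 10, "all_cause"),
             predicted_risk(rc, 5, "all_cause"))
  expect_error(predicted_risk(rc, 7.5, "all_cause"), "not on the curve")
})
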