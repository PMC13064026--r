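test_that("eligibility fixture reproduces its enumerated ledger", {
  fx <- fixture_cohort("eligibility_edges")
  res <- apply_eligibility(fx$rows)
  expect_equal(res$ledger[order(res$ledger$rule), ],
               fx$expected_ledger[order(fx$expected_ledger$rule), ],
               ignore_attr = TRUE)
  expect_setequal(res$eligible$id, fx$expected$retained_ids)
  # ledger counts sum to input - output
  expect_equal(sum(res$ledger$n_excluded),
               nrow(fx$rows) - nrow(res$eligible))
})

test_that("biomarker thresholds map to the tool's levels", {
  fx <- fixture_cohort("biomarker_edges")
  m <- map_biomarkers(fx$rows)
  expect_equal(m$er_status, fx$expected$er_status)
  expect_equal(m$ki67_status, fx$expected$ki67_status)
  expect_equal(m$her2_status, fx$expected$her2_status)
  # missing ER should have been excluded upstream
  bad <- fx$rows
  bad$er_percent[1] <- NA
  expect_error(map_biomarkers(bad), "er_percent missing")
})

test_that("treatment mapping classifies regimens and codes heart dose", {
  rows <- fixture_cohort("biomarker_edges")$rows[1:4, ]
  rows$chemo_regimen_text <- c("FEC", "EC + docetaxel", "", "paclitaxel")
  rows$radiotherapy_flag <- c(TRUE, TRUE, FALSE, TRUE)
  rows$laterality <- c("left", "right", "left", "left")
  m <- map_treatments(rows)
  expect_equal(m$chemo_generation,
               c("second_gen", "third_gen", "none", "third_gen"))
  expect_equal(m$mean_heart_dose, c(2, 0, 0, 2))
  expect_equal(m$endocrine, rep("five_year", 4))  # registry: up to 5 years
  rows$chemo_regimen_text[1] <- "mystery-drug"
  expect_error(map_treatments(rows), "mystery")
})

test_that("smoking imputation is uniform, mode-switchable, idempotent", {
  rec <- data.frame(id = 1:3)
  a <- impute_smoking(rec, "all_nonsmokers")
  expect_equal(a$smoker, rep("never_or_ex", 3))
  b <- impute_smoking(a, "all_smokers")
  expect_equal(b$smoker, rep("yes", 3))
  expect_identical(impute_smoking(b, "all_smokers"), b)
})

test_that("subgroups follow the subtype definitions and partition", {
  d <- data.frame(
    er_status = c("positive", "negative", "negative", "positive",
                  "negative"),
    pr_status = c("positive", "negative", "negative", "negative",
                  "positive"),
    her2_status = c("negative", "negative", "positive", "unknown",
                    "unknown"),
    positive_nodes = c(0, 3, 1, 0, 2))
  s <- assign_subgroups(d)
  expect_equal(s$subtype, c("Luminal", "TNBC", "HER2+", "Luminal",
                            "unclassifiable"))
  expect_equal(s$nodal_group, c("N0", "N+", "N+", "N0", "N+"))
  # partition: every record in exactly one subtype bucket
  expect_true(all(s$subtype %in% c("Luminal", "TNBC", "HER2+",
                                   "unclassifiable")))
})

test_that("horizon restriction honours the registry cut-off and truncates", {
  fx <- fixture_cohort("horizon_edges")
  rec <- build_records(apply_eligibility(fx$rows)$eligible)
  h5 <- restrict_to_horizon(rec, 5, fx$expected$cutoff)
  h10 <- restrict_to_horizon(rec, 10, fx$expected$cutoff)
  expect_setequal(h5$id, fx$rows$id[fx$expected$in_5y])
  expect_setequal(h10$id, fx$rows$id[fx$expected$in_10y])
  # horizon nesting: every 10-year-eligible record is 5-year-eligible
  expect_true(all(h10$id %in% h5$id))
  # an event beyond the horizon is recoded to censored-at-horizon
  rows <- fx$rows[3, ]
  rows$status <- "dead"
  rows$cause_of_death <- "breast_cancer"
  rows$vital_status_date <-
    as.character(as.Date(rows$diagnosis_date) + round(6.2 * 365.25))
  r <- build_records(rows)
  rh <- restrict_to_horizon(r, 5, "2021-03-09")
  expect_equal(rh$event_cause, "censored")
  expect_equal(rh$followup_years, 5)
  # an empty horizon dataset warns
  expect_warning(restrict_to_horizon(rec, 10, "2012-01-01"), "empty")
})

test_that("attach_predictions fills the full version/horizon/outcome grid", {
  fx <- fixture_cohort("horizon_edges")
  rec <- build_records(apply_eligibility(fx$rows)$eligible)[1:3, ]
  rec <- suppressWarnings(
    attach_predictions(rec, list("v2.2" = h_cf2(), "v3.0" = h_cf3())))
  cols <- c(t(outer(c("v2.2", "v3.0"), c(5, 10), function(v, h) {
    paste0(pred_col(v, h, "all_cause"), ";", pred_col(v, h, "bc_specific"))
  })))
  cols <- unlist(strsplit(cols, ";"))
  expect_true(all(cols %in% names(rec)))
  expect_equal(sum(!is.na(unlist(rec[cols]))), 3 * 8)  # 24 probabilities
  # identical twins get identical predictions
  twin <- rbind(rec[1, ], rec[1, ])
  twin$id <- c("a", "b")
  tw <- suppressWarnings(
    attach_predictions(twin[, setdiff(names(twin), cols)],
                       list("v3.0" = h_cf3())))
  expect_equal(unname(unlist(tw[1, grep("^pred_", names(tw))])),
               unname(unlist(tw[2, grep("^pred_", names(tw))])))
  # all-cause dominates cause-specific risk everywhere
  for (v in c("v2.2", "v3.0")) {
    for (h in c(5, 10)) {
      expect_true(all(rec[[pred_col(v, h, "all_cause")]] >=
                        rec[[pred_col(v, h, "bc_specific")]]))
    }
  }
})

test_that("cohort CSV round-trips through the documented dialect", {
  fx <- fixture_cohort("eligibility_edges")
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(fx$rows, path)
  back <- read_cohort_csv(path)
  expect_equal(back$id, fx$rows$id)
  expect_equal(back$er_percent, fx$rows$er_percent)
  expect_equal(back$surgery_flag, fx$rows$surgery_flag)
  expect_error(suppressWarnings(read_cohort_csv(tempfile())),
               "cannot open|No such|lacks")
})
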