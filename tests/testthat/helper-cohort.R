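# shared fixtures: loaded coefficient sets and small synthetic cohorts

h_cf2 <- function() {
  if (is.null(.h_env$cf2)) .h_env$cf2 <- load_coefficients("v2.2")
  .h_env$cf2
}
h_cf3 <- function() {
  if (is.null(.h_env$cf3)) .h_env$cf3 <- load_coefficients("v3.0")
  .h_env$cf3
}
.h_env <- new.env()

# horizon-restricted records with predictions, no competing hazards and
# administrative censoring pushed past the horizon unless asked for
h_records <- function(n, seed, horizon = 5,
                      distortion = distortion_identity(),
                      versions = c("v3.0"),
                      other_cause_hazard = 0, emigration_hazard = 0,
                      registry_cutoff = "2035-01-01") {
  spec <- cohort_spec(n = n, seed = seed, distortion = distortion,
                      other_cause_hazard = other_cause_hazard,
                      emigration_hazard = emigration_hazard,
                      registry_cutoff = registry_cutoff)
  sim <- simulate_cohort(spec)
  rec <- build_records(apply_eligibility(sim$rows)$eligible)
  cfs <- list()
  for (v in versions) cfs[[v]] <- if (v == "v2.2") h_cf2() else h_cf3()
  rec <- suppressWarnings(attach_predictions(rec, cfs,
                                             horizons = horizon))
  h <- restrict_to_horizon(rec, horizon, registry_cutoff)
  attr(h, "truth") <- sim$truth
  h
}

# write a modified copy of a bundled coefficient file and load it
h_modified_coeffs <- function(version, mutate) {
  cf <- jsonlite::read_json(predict_coefficients_path(version),
                            simplifyVector = TRUE)
  cf <- mutate(cf)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cf, path, auto_unbox = TRUE, digits = NA)
  path
}

# toy single-cause coefficient set: constant breast-cause baseline
# cumulative hazard H(t) = H5 for all t (all hazard in year one),
# negligible other-cause hazard, all level coefficients zero, centering
# constants at a reachable reference profile (age 30, 20 mm, grade 1,
# 0 nodes, ER-negative)
h_toy_coeffs <- function(H5 = 0.10) {
  path <- h_modified_coeffs("v2.2", function(cf) {
    cf$baseline_hazards$breast$er_negative <-
      list(intercept = log(H5), inv_time_sq = 0, inv_time = 0)
    cf$baseline_hazards$other <-
      list(intercept = -60, log_time = 0, sqrt_time = 0)
    cf$coefficients$breast$er_negative <- list(
      age_linear = 0.0089827, size_sqrt = 2.093446, nodes_log = 0.6260541,
      grade_high = 1.129091, her2_positive = 0.2413,
      her2_negative = 0, her2_unknown = 0)
    cf$constants$er_negative <- list(
      age_center = 30, size_sqrt_center = sqrt(20 / 100),
      nodes_log_center = log(1 / 10))
    cf$constants$other$age_sq_center <- 9
    cf
  })
  load_coefficients("v2.2", path)
}

h_ref_profile <- function(...) {
  args <- list(age_at_diagnosis = 30, tumor_size = 20, grade = 1,
               positive_nodes = 0, er_status = "negative",
               her2_status = "negative", detection = "symptoms")
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(covariate_profile, args)
}

# minimal records table for discrimination tests (no pipeline needed)
h_score_records <- function(time, cause, score, version = "v3.0",
                            horizon = 5, outcome = "bc_specific") {
  d <- data.frame(id = seq_along(time), followup_years = time,
                  event_cause = cause, stringsAsFactors = FALSE)
  d[[pred_col(version, horizon, outcome)]] <- score
  d
}
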