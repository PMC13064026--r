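test_that("piecewise expansion splits exposure correctly", {
  d <- data.frame(id = c("a", "b", "c"),
                  time = c(2.5, 0.3, 5),
                  cause = c("censored", "bc_death", "censored"),
                  p = c(0.1, 0.2, 0.3))
  d$x <- risk_cloglog(d$p)
  pem <- expand_piecewise(d, 1:5)
  a <- pem[pem$id == "a", ]
  expect_equal(a$exposure, c(1, 1, 0.5))
  expect_equal(sum(a$event), 0)
  b <- pem[pem$id == "b", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$exposure, 0.3)
  expect_equal(b$event, 1)
  expect_equal(b$cause, "bc_death")
  # the hazard evaluation point is shared across the interval
  expect_equal(b$interval_mid, 0.5)
  # conservation: total exposure equals total follow-up
  expect_equal(sum(pem$exposure), sum(d$time))
  expect_error(expand_piecewise(d, 1:4), "cover")
  expect_error(expand_piecewise(transform(d, time = c(2, 0, 1)), 1:5),
               "nonpositive")
})

test_that("intercept-only fit recovers log(events/exposure) exactly", {
  set.seed(8)
  for (i in 1:3) {
    n <- 150
    d <- data.frame(id = seq_len(n), time = runif(n, 0.2, 5),
                    cause = ifelse(runif(n) < 0.25, "bc_death",
                                   "censored"), p = runif(n, 0.02, 0.4))
    d$x <- risk_cloglog(d$p)
    pem <- expand_piecewise(d, 1:5)
    fit <- fit_calibration_gam(pem, cal_basis(intercept_only = TRUE))
    expect_equal(unname(coef(fit$gam)[1]),
                 log(sum(pem$event) / sum(pem$exposure)),
                 tolerance = 1e-8)
    # and the whole machinery reduces to the exponential closed form
    h <- sum(pem$event) / sum(pem$exposure)
    expect_equal(observed_risk(fit, 0.1, 5, "bc_death"),
                 1 - exp(-5 * h), tolerance = 1e-8)
    expect_equal(observed_risk(fit, 0.1, 5, "all_cause"),
                 1 - exp(-5 * h), tolerance = 1e-8)
  }
})

test_that("row duplication (weights) leaves rate estimates unchanged", {
  set.seed(9)
  n <- 300
  d <- data.frame(id = seq_len(n), time = pmin(5, rexp(n, 0.2)),
                  cause = "censored", p = runif(n, 0.02, 0.4))
  d$time <- pmax(d$time, 0.05)
  d$cause[runif(n) < 0.2] <- "bc_death"
  d$x <- risk_cloglog(d$p)
  pem <- expand_piecewise(d, 1:5)
  # duplicating every person-time row leaves the occurrence/exposure
  # rate (intercept-only fit) unchanged
  pem2 <- pem
  pem2$id <- paste0(pem$id, "b")
  dup <- rbind(pem, pem2)
  attr(dup, "cutpoints") <- attr(pem, "cutpoints")
  attr(dup, "horizon") <- attr(pem, "horizon")
  f0a <- fit_calibration_gam(pem, cal_basis(intercept_only = TRUE))
  f0b <- fit_calibration_gam(dup, cal_basis(intercept_only = TRUE))
  expect_equal(coef(f0a$gam), coef(f0b$gam), tolerance = 1e-10)
  # prior weights are exactly equivalent to duplicated rows at fixed
  # smoothing parameters
  b <- cal_basis(k_time = 4, k_x = 4, use_tensor = FALSE)
  f1 <- fit_calibration_gam(pem, b, engine = "gam")
  fd <- fit_calibration_gam(dup, b, engine = "gam", sp = f1$gam$sp)
  fw <- fit_calibration_gam(pem, b, weights = rep(2, nrow(pem)),
                            engine = "gam", sp = f1$gam$sp)
  expect_equal(as.numeric(coef(fd$gam)), as.numeric(coef(fw$gam)),
               tolerance = 1e-7)
})

test_that("constant-hazard simulation is recovered within 2%", {
  set.seed(10)
  n <- 6000
  lambda <- 0.08
  t_ev <- rexp(n, lambda)
  d <- data.frame(id = seq_len(n), time = pmin(t_ev, 5),
                  cause = ifelse(t_ev <= 5, "bc_death", "censored"),
                  p = runif(n, 0.05, 0.5))  # x truly unrelated
  d$x <- risk_cloglog(d$p)
  pem <- expand_piecewise(d, 1:5)
  fit <- fit_calibration_gam(pem, cal_basis(k_time = 5, k_x = 5,
                                            use_tensor = FALSE))
  h_hat <- sum(pem$event) / sum(pem$exposure)
  expect_lt(abs(h_hat - lambda) / lambda, 0.02)
  # fitted observed risk ~ constant-hazard risk at any p
  o <- observed_risk(fit, c(0.1, 0.3), 5, "bc_death")
  expect_equal(o, rep(1 - exp(-5 * lambda), 2), tolerance = 0.05)
})

test_that("cause-specific machinery respects competing-risk structure", {
  # deterministic check on the cumulative-incidence evaluator
  nq <- 400
  hb <- matrix(0.05, nq, 1)
  risk1 <- predictval:::.risk_from_hazards(hb, matrix(0.02, nq, 1),
                                           5 / nq, "bc_death")
  risk2 <- predictval:::.risk_from_hazards(hb, matrix(0.20, nq, 1),
                                           5 / nq, "bc_death")
  # closed form: CIF = (1 - exp(-(hb+ho)t)) * hb/(hb+ho)
  cf <- function(hb, ho) (1 - exp(-(hb + ho) * 5)) * hb / (hb + ho)
  expect_equal(drop(risk1), cf(0.05, 0.02), tolerance = 1e-10)
  expect_equal(drop(risk2), cf(0.05, 0.20), tolerance = 1e-10)
  # raising the other-cause hazard lowers the bc cumulative incidence
  expect_lt(risk2, risk1)
  # sub-distribution bound: bc-specific <= all-cause at the same p
  all1 <- predictval:::.risk_from_hazards(hb, matrix(0.02, nq, 1),
                                          5 / nq, "all_cause")
  expect_lt(risk1, all1)
})

test_that("three-cause fits estimate each cause's hazard", {
  set.seed(12)
  n <- 4000
  tb <- rexp(n, 0.05)
  to <- rexp(n, 0.02)
  te <- rexp(n, 0.01)
  tm <- pmin(tb, to, te, 5)
  cause <- ifelse(tm == 5, "censored",
                  ifelse(tm == tb, "bc_death",
                         ifelse(tm == to, "other_death", "emigrated")))
  d <- data.frame(id = seq_len(n), time = pmax(tm, 1e-3), cause = cause,
                  p = runif(n, 0.05, 0.5))
  d$x <- risk_cloglog(d$p)
  pem <- expand_piecewise(d, 1:5)
  fit <- fit_calibration_gam(pem, cal_basis(k_time = 4, k_x = 4,
                                            use_tensor = FALSE))
  expect_setequal(fit$causes, c("bc_death", "other_death", "emigrated"))
  # per-cause occurrence/exposure oracle
  for (cs in c("bc_death", "other_death")) {
    rate <- sum(pem$event[pem$cause == cs]) / sum(pem$exposure)
    hz <- predictval:::.hazard_grid(fit, risk_cloglog(0.2), 5, nquad = 32)
    h_fit <- if (cs == "bc_death") mean(hz$h_bc) else mean(hz$h_other)
    expect_lt(abs(h_fit - rate) / rate, 0.25)
  }
  # emigration contributes no mortality to observed risk
  o_all <- observed_risk(fit, 0.2, 5, "all_cause")
  expect_lt(o_all, 1 - exp(-5 * (0.05 + 0.02 + 0.01)) + 0.02)
})

test_that("no-event and empty datasets are rejected", {
  d <- data.frame(id = 1:5, time = rep(5, 5), cause = "censored",
                  p = runif(5))
  d$x <- risk_cloglog(d$p)
  pem <- expand_piecewise(d, 1:5)
  expect_error(fit_calibration_gam(pem), "no events")
  expect_error(fit_calibration_gam(pem[0, ]), "empty")
})

test_that("ICI matches hand arithmetic and its quadrature form", {
  set.seed(13)
  n <- 400
  d <- data.frame(id = seq_len(n), time = pmax(pmin(rexp(n, 0.1), 5),
                                               0.01),
                  cause = "censored", p = runif(n, 0.05, 0.5))
  d$cause[runif(n) < 0.3] <- "bc_death"
  d$x <- risk_cloglog(d$p)
  fit <- fit_calibration_gam(expand_piecewise(d, 1:5),
                             cal_basis(intercept_only = TRUE))
  # intercept-only: observed risk is one constant, ICI is hand arithmetic
  o <- observed_risk(fit, 0.123, 5, "bc_death")
  ps <- c(0.1, 0.2, 0.3)
  ici <- integrated_calibration_index(fit, ps, 5, "bc_death",
                                      method = "direct")
  expect_equal(ici$ici, mean(abs(o - ps)), tolerance = 1e-10)
  # patient-average vs quadrature against the empirical distribution of
  # predicted risk (weighted sum over distinct values)
  pdup <- c(0.1, 0.1, 0.2, 0.3, 0.3, 0.3)
  direct <- integrated_calibration_index(fit, pdup, 5, "bc_death",
                                         method = "direct")$ici
  up <- unique(pdup)
  w <- as.numeric(table(match(pdup, up)))
  ou <- observed_risk(fit, up, 5, "bc_death", nquad = 256)
  expect_equal(direct, sum(w * abs(ou - up)) / sum(w), tolerance = 1e-6)
  # weighted form equals duplication
  wtd <- integrated_calibration_index(fit, up, 5, "bc_death",
                                      weights = w, method = "direct")$ici
  expect_equal(wtd, direct, tolerance = 1e-12)
})

test_that("the tensor stays irrelevant under proportional-hazards truth", {
  set.seed(21)
  n <- 8000
  p <- runif(n, 0.02, 0.5)
  lam <- -log(1 - p) / 5   # proportional hazards in x, constant in t
  t_ev <- rexp(n, lam)
  d <- data.frame(id = seq_len(n), time = pmax(pmin(t_ev, 5), 1e-3),
                  cause = ifelse(t_ev <= 5, "bc_death", "censored"),
                  p = p)
  d$x <- risk_cloglog(p)
  pem <- expand_piecewise(d, 1:5)
  f_ti <- fit_calibration_gam(pem, cal_basis(k_time = 5, k_x = 5))
  f_no <- fit_calibration_gam(pem, cal_basis(k_time = 5, k_x = 5,
                                             use_tensor = FALSE))
  dg <- calibration_diagnostics(f_ti)
  edf_ti <- dg$edf_per_smooth[grep("^ti", dg$smooth_labels)]
  # the doubly-penalized interaction keeps most of its 16 coefficients
  # suppressed and changes the observed-risk functional only marginally
  expect_lt(edf_ti, 4)
  gr <- seq(0.05, 0.45, by = 0.05)
  expect_lt(max(abs(observed_risk(f_ti, gr, 5, "bc_death") -
                      observed_risk(f_no, gr, 5, "bc_death"))), 0.015)
})

test_that("calibration curves are bounded, ordered and tighten with n", {
  h <- h_records(1200, seed = 61)
  fit <- cell_calibration_fit(h, "v3.0", 5, "bc_specific",
                              basis = cal_basis(k_time = 5, k_x = 5,
                                                use_tensor = FALSE),
                              cutpoints = 1:5)
  cv <- calibration_curve(fit, seed = 1, ndraws = 100)
  expect_true(all(cv$lower <= cv$observed + 1e-9 &
                    cv$observed <= cv$upper + 1e-9))
  expect_true(all(cv$observed >= 0 & cv$observed <= 1))
  expect_warning(cvt <- calibration_curve(fit, grid = c(0.2, 0.9999),
                                          seed = 1, ndraws = 10),
                 "outside")
  expect_equal(cvt$p, 0.2)
  h4 <- h_records(4800, seed = 62)
  fit4 <- cell_calibration_fit(h4, "v3.0", 5, "bc_specific",
                               basis = cal_basis(k_time = 5, k_x = 5,
                                                 use_tensor = FALSE),
                               cutpoints = 1:5)
  cv4 <- calibration_curve(fit4, grid = cv$p[5:20], seed = 1,
                           ndraws = 100)
  w1 <- mean(cv$upper[5:20] - cv$lower[5:20])
  w4 <- mean(cv4$upper - cv4$lower)
  expect_lt(w4, w1)
})
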