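#' Basis configuration for the calibration model
#'
#' Defaults: cubic regression splines with 10 knots for the time smooth
#' and 10 for the cloglog-risk smooth, a 5 x 5 tensor-product
#' interaction carrying an extra null-space (shrinkage) penalty so it
#' can vanish when the data support proportional hazards, and
#' shrinkage-penalized cause interactions. Smaller settings are useful
#' inside bootstrap loops.
#'
#' @param k_time,k_x Basis dimensions of the marginal smooths.
#' @param k_tensor Marginal dimensions of the tensor interaction.
#' @param use_tensor Include the time-by-risk interaction?
#' @param intercept_only Drop every smooth (constant hazard per cause);
#'   mainly for oracle tests.
#' @export
cal_basis <- function(k_time = 10, k_x = 10, k_tensor = c(5, 5),
                      use_tensor = TRUE, intercept_only = FALSE) {
  structure(list(k_time = k_time, k_x = k_x, k_tensor = k_tensor,
                 use_tensor = use_tensor, intercept_only = intercept_only),
            class = "cal_basis")
}

# cap a basis dimension by the number of unique covariate values
.k_fit <- function(k, nuniq) max(3, min(k, nuniq))

#' Fit the competing-cause piecewise-exponential calibration GAM
#'
#' Poisson regression of interval event counts with log-exposure offset
#' (the piecewise-exponential likelihood), with cubic-spline smooths of
#' interval time (baseline hazard) and of the cloglog of predicted risk,
#' a doubly-penalized tensor-product interaction relaxing proportional
#' hazards, and -- when more than one event cause is present -- a
#' parametric cause term plus shrinkage-penalized cause-by-smooth
#' interactions. Smoothing parameters are selected by REML. Fitting is
#' delegated to \pkg{mgcv} (`gam`, or `bam` with discretized covariates
#' for large expansions).
#'
#' @param pem A [expand_piecewise()] dataset.
#' @param basis A [cal_basis()].
#' @param sp Optional fixed smoothing parameters (skips REML selection);
#'   used to freeze smoothing across bootstrap resamples.
#' @param weights Optional nonnegative prior weights (e.g. bootstrap
#'   multiplicities per row); the weighted fit equals a fit to the
#'   correspondingly duplicated rows.
#' @param engine `"auto"` (default: `bam` above 50k stacked rows),
#'   `"gam"` or `"bam"`.
#' @return Object of class `calibration_fit`.
#' @export
fit_calibration_gam <- function(pem, basis = cal_basis(), sp = NULL,
                                weights = NULL, engine = c("auto", "gam",
                                                           "bam")) {
  engine <- match.arg(engine)
  stopifnot(inherits(pem, "pem_dataset") || is.data.frame(pem))
  if (nrow(pem) == 0) stop("empty piecewise-exponential dataset")
  if (sum(pem$event) == 0) stop("no events in the dataset")
  cause_order <- c("bc_death", "other_death", "emigrated")
  causes <- intersect(cause_order, unique(pem$cause[pem$event == 1]))
  # stack one copy of the person-time per cause, each with its own
  # event indicator: joint likelihood over cause-specific hazards
  stk <- do.call(rbind, lapply(causes, function(cs) {
    z <- pem
    z$events <- as.integer(pem$event == 1 & pem$cause == cs)
    z$cause_lvl <- cs
    z
  }))
  stk$cause_lvl <- factor(stk$cause_lvl, levels = causes)
  stk$cause_ord <- as.ordered(stk$cause_lvl)
  stk$tmid <- if (!is.null(stk$interval_mid)) stk$interval_mid else
    (stk$tstart + stk$tstop) / 2
  stk$log_exposure <- log(stk$exposure)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(pem))
    stk$.w <- rep(weights, length(causes))
  } else {
    stk$.w <- rep(1, nrow(stk))
  }

  terms <- character(0)
  if (!basis$intercept_only) {
    kt <- .k_fit(basis$k_time, length(unique(stk$tmid)))
    kx <- .k_fit(basis$k_x, length(unique(stk$x)))
    if (length(unique(stk$tmid)) >= 3) {
      terms <- c(terms, sprintf("s(tmid, bs = 'cr', k = %d)", kt))
    }
    if (length(unique(stk$x)) >= 3) {
      terms <- c(terms, sprintf("s(x, bs = 'cr', k = %d)", kx))
    }
    if (basis$use_tensor && length(unique(stk$tmid)) >= 3 &&
        length(unique(stk$x)) >= 3) {
      terms <- c(terms, sprintf(
        "ti(tmid, x, bs = c('cs', 'cs'), k = c(%d, %d))",
        .k_fit(basis$k_tensor[1], length(unique(stk$tmid))),
        .k_fit(basis$k_tensor[2], length(unique(stk$x)))))
    }
    if (length(causes) > 1) {
      terms <- c(terms, "cause_lvl")
      if (length(unique(stk$tmid)) >= 3) {
        terms <- c(terms, sprintf(
          "s(tmid, by = cause_ord, bs = 'cs', k = %d)", kt))
      }
      if (length(unique(stk$x)) >= 3) {
        terms <- c(terms, sprintf(
          "s(x, by = cause_ord, bs = 'cs', k = %d)", kx))
      }
    }
  } else if (length(causes) > 1) {
    terms <- c(terms, "cause_lvl")
  }
  rhs <- paste(c("offset(log_exposure)", terms), collapse = " + ")
  fml <- stats::as.formula(paste("events ~", rhs))

  has_smooth <- any(grepl("^(s|ti)\\(", terms))
  use_bam <- has_smooth &&
    (engine == "bam" || (engine == "auto" && nrow(stk) > 50000))
  fit <- if (use_bam) {
    mgcv::bam(fml, family = stats::poisson(), data = stk, weights = .w,
              sp = sp, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(fml, family = stats::poisson(), data = stk, weights = .w,
              sp = sp, method = "REML")
  }
  conv <- isTRUE(fit$converged) ||
    isTRUE(fit$mgcv.conv$fully.converged) || is.null(fit$converged)
  if (!conv) warning("calibration GAM did not fully converge")
  out <- list(
    gam = fit, basis = basis, causes = causes,
    horizon = attr(pem, "horizon"),
    cutpoints = attr(pem, "cutpoints"),
    x_range = range(pem$x), n_events = sum(pem$event),
    total_exposure = sum(pem$exposure * (if (is.null(weights)) 1
                                         else weights)),
    converged = conv, engine = if (use_bam) "bam" else "gam"
  )
  class(out) <- "calibration_fit"
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Piecewise-exponential calibration fit (", x$engine, ", ",
      length(x$causes), " cause(s): ", paste(x$causes, collapse = ", "),
      ")\n", sep = "")
  cat(" horizon:", x$horizon, "years;", x$n_events, "events over",
      round(x$total_exposure, 1), "person-years\n")
  invisible(x)
}

#' Fit diagnostics as a list (serializable to JSON)
#'
#' @param fit A `calibration_fit`.
#' @export
calibration_diagnostics <- function(fit) {
  g <- fit$gam
  list(converged = fit$converged, engine = fit$engine,
       n_events = fit$n_events, total_exposure = fit$total_exposure,
       smoothing_parameters = as.numeric(g$sp),
       edf_per_smooth = if (length(g$smooth))
         vapply(seq_along(g$smooth), function(i) {
           idx <- g$smooth[[i]]$first.para:g$smooth[[i]]$last.para
           sum(g$edf[idx])
         }, numeric(1)) else numeric(0),
       smooth_labels = if (length(g$smooth))
         vapply(g$smooth, function(s) s$label, character(1))
         else character(0))
}

# fitted hazards on a quadrature grid for a vector of x values.
# Returns list(h_bc, h_other): nquad x length(x) matrices (h_other all
# zero when that cause is absent from the fit). `beta` optionally
# overrides the fitted coefficients (for CI resampling); `Xp` caches
# the prediction design matrix.
.hazard_grid <- function(fit, x, horizon, nquad = 512, beta = NULL,
                         Xp = NULL) {
  tq <- horizon * (seq_len(nquad) - 0.5) / nquad
  want <- intersect(c("bc_death", "other_death"), fit$causes)
  nd <- expand.grid(tmid = tq, x = x, cause_chr = want,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nd$cause_lvl <- factor(nd$cause_chr, levels = fit$causes)
  nd$cause_ord <- as.ordered(nd$cause_lvl)
  nd$log_exposure <- 0
  if (is.null(Xp)) {
    Xp <- stats::predict(fit$gam, newdata = nd, type = "lpmatrix")
  }
  eta <- drop(Xp %*% (if (is.null(beta)) stats::coef(fit$gam) else beta))
  h <- exp(eta)
  G <- length(x)
  per <- nquad * G
  h_bc <- matrix(0, nquad, G)
  h_ot <- matrix(0, nquad, G)
  for (i in seq_along(want)) {
    m <- matrix(h[(i - 1) * per + seq_len(per)], nquad, G)
    if (want[i] == "bc_death") h_bc <- m else h_ot <- m
  }
  list(h_bc = h_bc, h_other = h_ot, Xp = Xp, delta = horizon / nquad)
}

# cumulative mortality from cause-specific hazards treated as piecewise
# constant on the quadrature grid (product-integral; exact for constant
# hazards). hb, ho: nquad x G.
.risk_from_hazards <- function(hb, ho, delta,
                               outcome = c("all_cause", "bc_death")) {
  outcome <- match.arg(outcome)
  htot <- hb + ho
  if (outcome == "all_cause") {
    return(1 - exp(-delta * colSums(htot)))
  }
  Hstart <- apply(htot, 2, function(cz) c(0, cumsum(cz)[-length(cz)]))
  if (is.null(dim(Hstart))) Hstart <- matrix(Hstart, ncol = ncol(htot))
  Sstart <- exp(-delta * Hstart)
  share <- ifelse(htot > 0, hb / htot, 0)
  colSums(Sstart * share * (1 - exp(-htot * delta)))
}

#' Model-based observed risk at a predicted-risk value
#'
#' Evaluates the fitted cause-specific hazards along time at
#' `x = cloglog(p)` and integrates: all-cause observed risk is
#' `1 - exp(-(H_bc + H_other))`; breast-cancer-specific observed risk is
#' the competing-risks cumulative incidence
#' `integral of S(u) h_bc(u) du`, with `S` the all-cause survival.
#' Hazards are treated as piecewise constant over a 512-point grid
#' (product-integral evaluation, exact when the fitted hazard is
#' constant).
#'
#' @param fit A `calibration_fit`.
#' @param p Predicted risk(s) in (0, 1); clamped before cloglog.
#' @param horizon Defaults to the fit's horizon.
#' @param outcome `"all_cause"` or `"bc_death"`.
#' @param nquad Quadrature intervals.
#' @return Observed risk(s), same length as `p`.
#' @export
observed_risk <- function(fit, p, horizon = fit$horizon,
                          outcome = c("all_cause", "bc_death"),
                          nquad = 512) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(fit, "calibration_fit"))
  hz <- .hazard_grid(fit, risk_cloglog(p), horizon, nquad)
  .risk_from_hazards(hz$h_bc, hz$h_other, hz$delta, outcome)
}

#' Smooth calibration curve with pointwise confidence band
#'
#' Observed risk evaluated over a grid of predicted risks, with
#' pointwise intervals obtained by resampling the fitted coefficient
#' vector from its Gaussian posterior (mean `coef`, covariance `Vp`) and
#' propagating each draw through the observed-risk functional.
#'
#' @param fit A `calibration_fit`.
#' @param grid Predicted-risk grid; defaults to 40 points spanning the
#'   fitted risk range. Values outside the supported range are dropped
#'   with a warning.
#' @param horizon,outcome As in [observed_risk()].
#' @param level Confidence level (default 0.95).
#' @param ndraws Posterior draws for the band.
#' @param nquad Quadrature intervals.
#' @param seed Optional seed for the coefficient draws.
#' @return Data frame of class `calibration_curve`: `p`, `observed`,
#'   `lower`, `upper`.
#' @export
calibration_curve <- function(fit, grid = NULL, horizon = fit$horizon,
                              outcome = c("all_cause", "bc_death"),
                              level = 0.95, ndraws = 200, nquad = 256,
                              seed = NULL) {
  outcome <- match.arg(outcome)
  p_rng <- 1 - exp(-exp(fit$x_range))
  if (is.null(grid)) {
    grid <- seq(p_rng[1], p_rng[2], length.out = 40)
  } else {
    ok <- grid >= p_rng[1] - 1e-12 & grid <= p_rng[2] + 1e-12
    if (!all(ok)) {
      warning("grid value(s) outside the fitted risk range dropped")
      grid <- grid[ok]
    }
    if (!length(grid)) stop("no grid values inside the fitted risk range")
  }
  hz <- .hazard_grid(fit, risk_cloglog(grid), horizon, nquad)
  est <- .risk_from_hazards(hz$h_bc, hz$h_other, hz$delta, outcome)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  B <- mgcv::rmvn(ndraws, as.numeric(stats::coef(fit$gam)),
                  fit$gam$Vp)
  draws <- matrix(NA_real_, ndraws, length(grid))
  for (b in seq_len(ndraws)) {
    hzb <- .hazard_grid(fit, risk_cloglog(grid), horizon, nquad,
                        beta = B[b, ], Xp = hz$Xp)
    draws[b, ] <- .risk_from_hazards(hzb$h_bc, hzb$h_other, hzb$delta,
                                     outcome)
  }
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(p = grid, observed = pmin(pmax(est, 0), 1),
                    lower = pmin(pmax(qs[1, ], 0), 1),
                    upper = pmin(pmax(qs[2, ], 0), 1))
  out$outcome <- outcome
  out$horizon <- horizon
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Integrated calibration index
#'
#' Mean absolute difference between model-based observed risk and
#' predicted risk over the analysis records' predictions (internal
#' probability scale; multiply by 100 to report in percent).
#'
#' `method = "interp"` evaluates the observed-risk functional on a grid
#' of cloglog-risk values spanning the data and interpolates to each
#' patient (fast, used inside bootstrap loops); `method = "direct"`
#' evaluates it at every distinct predicted risk.
#'
#' @param fit A `calibration_fit`.
#' @param p Predicted risks of the analysis records.
#' @param horizon,outcome As in [observed_risk()].
#' @param weights Optional patient weights (e.g. bootstrap
#'   multiplicities).
#' @param method `"interp"` or `"direct"`.
#' @param grid_size Grid size for `"interp"`.
#' @param nquad Quadrature intervals.
#' @return List of class `ici_result` with elements `ici`, `horizon`,
#'   `outcome`, `n`.
#' @export
integrated_calibration_index <- function(fit, p, horizon = fit$horizon,
                                         outcome = c("all_cause",
                                                     "bc_death"),
                                         weights = NULL,
                                         method = c("interp", "direct"),
                                         grid_size = 128, nquad = 256) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  if (!length(p)) stop("empty predicted-risk vector")
  if (is.null(weights)) weights <- rep(1, length(p))
  x <- risk_cloglog(p)
  if (method == "direct" || length(unique(x)) <= grid_size) {
    ux <- sort(unique(x))
    hz <- .hazard_grid(fit, ux, horizon, nquad)
    ou <- .risk_from_hazards(hz$h_bc, hz$h_other, hz$delta, outcome)
    o <- ou[match(x, ux)]
  } else {
    xg <- seq(min(x), max(x), length.out = grid_size)
    hz <- .hazard_grid(fit, xg, horizon, nquad)
    og <- .risk_from_hazards(hz$h_bc, hz$h_other, hz$delta, outcome)
    o <- stats::approx(xg, og, xout = x)$y
  }
  ici <- sum(weights * abs(o - p)) / sum(weights)
  structure(list(ici = ici, horizon = horizon, outcome = outcome,
                 n = length(p)),
            class = "ici_result")
}

#' @export
print.ici_result <- function(x, ...) {
  cat(sprintf("ICI = %.4f (%.2f%%), %s, %g-year horizon, n = %d\n",
              x$ici, 100 * x$ici, x$outcome, x$horizon, x$n))
  invisible(x)
}
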