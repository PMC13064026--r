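# per-replicate substream seed; documented scheme (seed, replicate)
.replicate_seed <- function(seed, b) .substream(seed, 100000L + b)

#' Percentile bootstrap confidence interval
#'
#' Resamples patients (rows) with replacement `B` times, recomputes the
#' statistic on every resample, and returns the empirical 2.5/97.5
#' percentile interval (for `level = 0.95`). Resamples on which the
#' statistic fails (e.g. a non-convergent refit) are logged and redrawn,
#' up to 10% of `B`; more failures abort with diagnostics. Replicates
#' are kept on the result for audit; the CI endpoints are order
#' statistics of that vector.
#'
#' @param records Analysis records (resampling unit: patient row).
#' @param statistic `function(records) -> single numeric`.
#' @param B Replications (default 200).
#' @param seed Integer seed; replicate `b` draws from a substream
#'   derived from `(seed, b)`.
#' @param level Confidence level.
#' @param statistic_id Optional label.
#' @return Object of class `bootstrap_result`: `point`, `ci_low`,
#'   `ci_high`, `B`, `seed`, `replicates`, `n_failed`, `statistic_id`.
#' @export
bootstrap_ci <- function(records, statistic, B = 200, seed = 1,
                         level = 0.95, statistic_id = "statistic") {
  stopifnot(B >= 2)
  point <- statistic(records)
  n <- nrow(records)
  reps <- numeric(B)
  failures <- character(0)
  max_fail <- ceiling(0.1 * B)
  b <- 1L
  draw <- 1L
  while (b <= B) {
    if (length(failures) > max_fail) {
      stop("more than 10% of bootstrap resamples failed; first errors: ",
           paste(utils::head(failures, 3), collapse = " | "))
    }
    set.seed(.replicate_seed(seed, draw))
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(records[idx, , drop = FALSE]),
                    error = function(e) e)
    draw <- draw + 1L
    if (inherits(val, "error")) {
      failures <- c(failures, conditionMessage(val))
      next
    }
    reps[b] <- val
    b <- b + 1L
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(reps, probs = c(a, 1 - a), type = 1, names = FALSE)
  out <- list(point = point, ci_low = ci[1], ci_high = ci[2], B = B,
              seed = seed, replicates = reps,
              n_failed = length(failures), statistic_id = statistic_id)
  class(out) <- "bootstrap_result"
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s: %.4f [%.4f, %.4f] (percentile bootstrap, B = %d%s)\n",
              x$statistic_id, x$point, x$ci_low, x$ci_high, x$B,
              if (x$n_failed) paste0(", ", x$n_failed, " redrawn") else ""))
  invisible(x)
}

# metric evaluators shared by the paired machinery; cal_basis/cutpoints
# control the inner calibration refit cost
.metric_fun <- function(metric, version, horizon, outcome, basis,
                        cutpoints, sp = NULL, ici_grid = 128,
                        ici_nquad = 256) {
  force(list(metric, version, horizon, outcome, basis, cutpoints, sp,
             ici_grid, ici_nquad))
  if (metric == "tdauc") {
    return(function(records) {
      td_auc(records, version, horizon, outcome)$tdauc
    })
  }
  function(records) {
    d <- calibration_data(records, version, horizon, outcome)
    cuts <- if (is.null(cutpoints)) {
      default_cutpoints(d$time, d$cause, horizon)
    } else cutpoints
    pem <- expand_piecewise(d, cuts)
    fit <- fit_calibration_gam(pem, basis = basis, sp = sp, engine = "gam")
    co <- if (outcome == "all_cause") "all_cause" else "bc_death"
    integrated_calibration_index(fit, d$p, horizon, co,
                                 grid_size = ici_grid,
                                 nquad = ici_nquad)$ici
  }
}

#' Paired bootstrap CI for a version difference
#'
#' Computes a metric (ICI or tdAUC) for two model versions on the same
#' patient resamples and bootstraps the difference
#' `versions[1] - versions[2]` (by default v3.0 - v2.2). The
#' `significant` flag is set iff the percentile CI excludes zero.
#'
#' By default the calibration refit inside every resample re-estimates
#' its smoothing parameters; `sp_mode = "frozen"` freezes them at the
#' full-data fit, trading some uncertainty propagation for a much
#' cheaper refit.
#'
#' @param records Analysis records with both versions' predictions.
#' @param metric `"ici"` or `"tdauc"`.
#' @param horizon,outcome Cell identifiers.
#' @param versions Length-2 character vector, difference is
#'   `first - second`.
#' @param B,seed,level As in [bootstrap_ci()].
#' @param basis,cutpoints Calibration controls for `metric = "ici"`.
#' @param sp_mode `"reestimate"` or `"frozen"`.
#' @return A `bootstrap_result` for the difference, with the per-version
#'   points attached as `point_by_version`.
#' @export
paired_difference_ci <- function(records, metric = c("ici", "tdauc"),
                                 horizon, outcome,
                                 versions = c("v3.0", "v2.2"),
                                 B = 200, seed = 1, level = 0.95,
                                 basis = cal_basis(), cutpoints = NULL,
                                 sp_mode = c("reestimate", "frozen")) {
  metric <- match.arg(metric)
  sp_mode <- match.arg(sp_mode)
  stopifnot(length(versions) == 2)
  sps <- list(NULL, NULL)
  if (metric == "ici" && sp_mode == "frozen") {
    for (i in 1:2) {
      f0 <- .metric_fit_full(records, versions[i], horizon, outcome,
                             basis, cutpoints)
      sps[[i]] <- f0$gam$sp
    }
  }
  f1 <- .metric_fun(metric, versions[1], horizon, outcome, basis,
                    cutpoints, sps[[1]])
  f2 <- .metric_fun(metric, versions[2], horizon, outcome, basis,
                    cutpoints, sps[[2]])
  stat <- function(rec) f1(rec) - f2(rec)
  res <- bootstrap_ci(records, stat, B = B, seed = seed, level = level,
                      statistic_id = paste0(metric, "_diff_", versions[1],
                                            "-", versions[2]))
  res$point_by_version <- c(f1(records), f2(records))
  names(res$point_by_version) <- versions
  res$significant <- res$ci_low > 0 || res$ci_high < 0
  res$metric <- metric
  res$horizon <- horizon
  res$outcome <- outcome
  res
}

#' Bootstrap statistic factories and per-cell calibration fit
#'
#' `ici_statistic()` and `tdauc_statistic()` return
#' `function(records) -> numeric` closures suitable for
#' [bootstrap_ci()]; `cell_calibration_fit()` fits the calibration GAM
#' for one (version, horizon, outcome) cell, e.g. to freeze its
#' smoothing parameters via `sp = fit$gam$sp` in the statistic.
#'
#' @param records Analysis records with predictions attached.
#' @param version,horizon,outcome Cell identifiers.
#' @param basis A [cal_basis()].
#' @param cutpoints Expansion cutpoints (default: event-time deciles).
#' @param sp Optional frozen smoothing parameters.
#' @param ici_grid,ici_nquad Evaluation grid size and quadrature
#'   intervals for the observed-risk functional inside the statistic.
#' @export
ici_statistic <- function(version, horizon, outcome,
                          basis = cal_basis(), cutpoints = NULL,
                          sp = NULL, ici_grid = 128, ici_nquad = 256) {
  .metric_fun("ici", version, horizon, outcome, basis, cutpoints, sp,
              ici_grid, ici_nquad)
}

#' @rdname ici_statistic
#' @export
tdauc_statistic <- function(version, horizon, outcome) {
  .metric_fun("tdauc", version, horizon, outcome, NULL, NULL, NULL)
}

#' @rdname ici_statistic
#' @export
cell_calibration_fit <- function(records, version, horizon, outcome,
                                 basis = cal_basis(), cutpoints = NULL) {
  .metric_fit_full(records, version, horizon, outcome, basis, cutpoints)
}

# assembled penalty matrix Sum_j sp_j * S_j on the coefficient scale
.total_penalty <- function(g) {
  p <- length(stats::coef(g))
  St <- matrix(0, p, p)
  k <- 0
  for (sm in g$smooth) {
    idx <- sm$first.para:sm$last.para
    for (i in seq_along(sm$S)) {
      k <- k + 1
      St[idx, idx] <- St[idx, idx] + g$sp[k] * sm$S[[i]]
    }
  }
  St
}

# penalized IRLS for a Poisson fit with fixed penalty; equivalent to
# gam(..., sp = fixed) on the same design (equivalence-tested)
.pirls_fixed <- function(X, y, offset, St, w, beta0, tol = 1e-8,
                         maxit = 50) {
  beta <- beta0
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- w * mu
    z <- eta - offset + (y - mu) / mu
    A <- crossprod(X, W * X) + St
    b <- crossprod(X, W * z)
    beta <- as.numeric(solve(A, b))
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    dev <- -2 * sum(w * (y * eta - mu)) + drop(t(beta) %*% St %*% beta)
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  beta
}

# precomputed context for the fast ICI refit path: design matrix,
# penalty at the full-data REML smoothing parameters, evaluation-grid
# design and patient lookups
.fast_ici_ctx <- function(records, version, horizon, outcome, basis,
                          cutpoints, ici_grid, ici_nquad) {
  d <- calibration_data(records, version, horizon, outcome)
  cuts <- if (is.null(cutpoints)) {
    default_cutpoints(d$time, d$cause, horizon)
  } else cutpoints
  pem <- expand_piecewise(d, cuts)
  fit <- fit_calibration_gam(pem, basis = basis, engine = "gam")
  g <- fit$gam
  offset <- g$offset
  if (is.null(offset)) offset <- rep(0, length(g$y))
  if (anyDuplicated(records$id)) stop("records$id must be unique")
  xg <- seq(fit$x_range[1], fit$x_range[2], length.out = ici_grid)
  hz0 <- .hazard_grid(fit, xg, horizon, ici_nquad)
  list(fit = fit, X = stats::model.matrix(g), y = g$y, offset = offset,
       St = .total_penalty(g), beta0 = as.numeric(stats::coef(g)),
       row_patient = match(rep(pem$id, length(fit$causes)), records$id),
       xg = xg, Xp = hz0$Xp, delta = hz0$delta,
       want = intersect(c("bc_death", "other_death"), fit$causes),
       co = if (outcome == "all_cause") "all_cause" else "bc_death",
       grid = ici_grid, nquad = ici_nquad, x_pat = d$x, p_pat = d$p,
       hz0 = hz0)
}

# ICI for one multiplicity vector (NULL = full data)
.fast_ici_eval <- function(ctx, mult = NULL, idx = NULL) {
  if (is.null(mult)) {
    hb <- ctx$hz0$h_bc
    ho <- ctx$hz0$h_other
    xo <- ctx$x_pat
    po <- ctx$p_pat
  } else {
    beta <- .pirls_fixed(ctx$X, ctx$y, ctx$offset, ctx$St,
                         mult[ctx$row_patient], ctx$beta0)
    h <- exp(drop(ctx$Xp %*% beta))
    per <- ctx$nquad * ctx$grid
    hb <- ho <- matrix(0, ctx$nquad, ctx$grid)
    for (i in seq_along(ctx$want)) {
      m <- matrix(h[(i - 1) * per + seq_len(per)], ctx$nquad, ctx$grid)
      if (ctx$want[i] == "bc_death") hb <- m else ho <- m
    }
    xo <- ctx$x_pat[idx]
    po <- ctx$p_pat[idx]
  }
  og <- .risk_from_hazards(hb, ho, ctx$delta, ctx$co)
  o <- stats::approx(ctx$xg, og,
                     xout = pmin(pmax(xo, min(ctx$xg)), max(ctx$xg)))$y
  mean(abs(o - po))
}

#' Fast percentile bootstrap for the ICI (frozen smoothing parameters)
#'
#' Optimized equivalent of [bootstrap_ci()] with an
#' [ici_statistic()]: because a patient resample is a
#' multiplicity-weighted copy of the original rows, the piecewise
#' expansion, the model matrix, the penalty (at the full-data REML
#' smoothing parameters) and the evaluation-grid design are all built
#' once, and each replicate reduces to a penalized IRLS with patient
#' multiplicity weights. The evaluation grid spans the full-data risk
#' range. `fast_paired_ici_diff()` applies the same machinery to both
#' versions on shared resamples and bootstraps the difference
#' `versions[1] - versions[2]`.
#'
#' @inheritParams ici_statistic
#' @param records Analysis records with predictions attached.
#' @param B,seed,level As in [bootstrap_ci()].
#' @param versions Length-2 version vector for the paired difference.
#' @return A `bootstrap_result`.
#' @export
fast_ici_bootstrap <- function(records, version, horizon, outcome,
                               basis = cal_basis(), cutpoints = NULL,
                               B = 200, seed = 1, level = 0.95,
                               ici_grid = 64, ici_nquad = 64) {
  ctx <- .fast_ici_ctx(records, version, horizon, outcome, basis,
                       cutpoints, ici_grid, ici_nquad)
  n <- nrow(records)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(.replicate_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- .fast_ici_eval(ctx, tabulate(idx, nbins = n), idx)
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(reps, probs = c(a, 1 - a), type = 1, names = FALSE)
  out <- list(point = .fast_ici_eval(ctx), ci_low = ci[1],
              ci_high = ci[2], B = B, seed = seed, replicates = reps,
              n_failed = 0L,
              statistic_id = paste0("ici_", version, "_", horizon, "y_",
                                    outcome, "_fast"))
  class(out) <- "bootstrap_result"
  out
}

#' @rdname fast_ici_bootstrap
#' @export
fast_paired_ici_diff <- function(records, horizon, outcome,
                                 versions = c("v3.0", "v2.2"),
                                 basis = cal_basis(), cutpoints = NULL,
                                 B = 200, seed = 1, level = 0.95,
                                 ici_grid = 64, ici_nquad = 64) {
  stopifnot(length(versions) == 2)
  ctx1 <- .fast_ici_ctx(records, versions[1], horizon, outcome, basis,
                        cutpoints, ici_grid, ici_nquad)
  ctx2 <- .fast_ici_ctx(records, versions[2], horizon, outcome, basis,
                        cutpoints, ici_grid, ici_nquad)
  n <- nrow(records)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(.replicate_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    mult <- tabulate(idx, nbins = n)
    reps[b] <- .fast_ici_eval(ctx1, mult, idx) -
      .fast_ici_eval(ctx2, mult, idx)
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(reps, probs = c(a, 1 - a), type = 1, names = FALSE)
  pt <- .fast_ici_eval(ctx1) - .fast_ici_eval(ctx2)
  out <- list(point = pt, ci_low = ci[1], ci_high = ci[2], B = B,
              seed = seed, replicates = reps, n_failed = 0L,
              statistic_id = paste0("ici_diff_", versions[1], "-",
                                    versions[2], "_fast"),
              significant = ci[1] > 0 || ci[2] < 0,
              point_by_version = c(.fast_ici_eval(ctx1),
                                   .fast_ici_eval(ctx2)))
  class(out) <- "bootstrap_result"
  out
}

# full-data calibration fit for a cell (used to freeze sp)
.metric_fit_full <- function(records, version, horizon, outcome, basis,
                             cutpoints) {
  d <- calibration_data(records, version, horizon, outcome)
  cuts <- if (is.null(cutpoints)) {
    default_cutpoints(d$time, d$cause, horizon)
  } else cutpoints
  fit_calibration_gam(expand_piecewise(d, cuts), basis = basis,
                      engine = "gam")
}
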