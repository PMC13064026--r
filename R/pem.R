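#' Complementary log-log of a risk, with clamping
#'
#' Risks are clamped to `[1e-6, 1 - 1e-6]` before the transform so that
#' degenerate predictions of exactly 0 or 1 remain usable.
#'
#' @param p Probabilities.
#' @export
risk_cloglog <- function(p) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  log(-log(1 - p))
}

#' Assemble per-patient calibration data for one model/horizon/outcome
#'
#' Extracts follow-up, four-level event cause, and the cloglog of the
#' matching predicted risk from horizon-restricted analysis records.
#'
#' @param records Records with predictions attached
#'   ([attach_predictions()]) and restricted to `horizon`.
#' @param version,horizon,outcome Which prediction column to use.
#' @return Data frame with `id`, `time`, `cause`, `p`, `x` (and subgroup
#'   labels carried through).
#' @export
calibration_data <- function(records, version, horizon,
                             outcome = c("all_cause", "bc_specific")) {
  outcome <- match.arg(outcome)
  col <- pred_col(version, horizon, outcome)
  if (is.null(records[[col]])) stop("records lack prediction column ", col)
  d <- data.frame(id = records$id, time = records$followup_years,
                  cause = records$event_cause, p = records[[col]],
                  stringsAsFactors = FALSE)
  d$x <- risk_cloglog(d$p)
  for (v in c("subtype", "nodal_group")) {
    if (!is.null(records[[v]])) d[[v]] <- records[[v]]
  }
  if (any(d$time <= 0)) stop("record(s) with nonpositive follow-up")
  d
}

#' Default time cutpoints for piecewise-exponential expansion
#'
#' Deciles of the observed event times within `(0, horizon]`, union the
#' horizon itself; falls back to a yearly grid when there are too few
#' events to define deciles.
#'
#' @param time Follow-up times.
#' @param cause Four-level event cause.
#' @param horizon Horizon in years.
#' @param k Number of quantile bins (default 10).
#' @export
default_cutpoints <- function(time, cause, horizon, k = 10) {
  ev <- time[cause != "censored" & time > 0 & time <= horizon]
  if (length(ev) < k) return(unique(c(seq_len(ceiling(horizon)), horizon)))
  cuts <- unique(stats::quantile(ev, probs = seq_len(k) / k, type = 1,
                                 names = FALSE))
  sort(unique(c(cuts, horizon)))
}

#' Expand survival records into piecewise-exponential person-time
#'
#' Standard survival split: each patient contributes one row per time
#' interval at risk, with the interval exposure, an event indicator in
#' the interval containing the event time, and the event's cause.
#' Per patient, exposures sum to the follow-up time and at most the last
#' row carries the event.
#'
#' @param d Data from [calibration_data()] (columns `id`, `time`,
#'   `cause`, `x`, ...).
#' @param cutpoints Strictly increasing positive cut times covering
#'   `(0, horizon]`; the maximum must be at least the longest follow-up.
#' @return A `pem_dataset` data frame with columns `id`, `interval`,
#'   `tstart`, `tstop`, `exposure`, `event`, `cause`, `x`, ...
#' @export
expand_piecewise <- function(d, cutpoints) {
  if (any(d$time <= 0)) stop("record(s) with nonpositive follow-up")
  cutpoints <- sort(unique(cutpoints))
  if (any(cutpoints <= 0)) stop("cutpoints must be positive")
  if (max(d$time) > max(cutpoints) + 1e-12) {
    stop("cutpoints do not cover the longest follow-up")
  }
  d$.event <- as.integer(d$cause != "censored")
  ss <- survival::survSplit(Surv(time, .event) ~ ., data = d,
                            cut = cutpoints, start = "tstart", end = "tstop",
                            event = ".event", episode = "interval")
  ss$exposure <- ss$tstop - ss$tstart
  ss <- ss[ss$exposure > 0, , drop = FALSE]
  ss$event <- ss$.event
  ss$cause <- ifelse(ss$event == 1, ss$cause, "censored")
  ss$.event <- NULL
  # hazard evaluation point: midpoint of the FULL grid interval, shared
  # by every row in the interval (a row truncated at its event time must
  # not get its own time value, or the time smooth chases event times)
  grid <- c(0, cutpoints)
  j <- findInterval(ss$tstart + 1e-9, grid)
  ss$interval_mid <- (grid[j] + grid[j + 1]) / 2
  out <- ss[order(ss$id, ss$tstart),
            c("id", "interval", "tstart", "tstop", "exposure",
              "interval_mid", "event", "cause",
              setdiff(names(d), c("id", "time", "cause", ".event")))]
  rownames(out) <- NULL
  attr(out, "cutpoints") <- cutpoints
  attr(out, "horizon") <- max(cutpoints)
  class(out) <- c("pem_dataset", "data.frame")
  out
}
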