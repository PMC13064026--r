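#' Kaplan-Meier censoring survival for IPCW
#'
#' Estimates the survival function of the administrative censoring
#' distribution: censoring ("censored" cause) is the event, and deaths
#' or emigrations are censored observations for this estimator.
#'
#' @param time Follow-up times.
#' @param cause Four-level event cause.
#' @return A left-continuous step function `G(t)`; `G(t-)` is obtained
#'   by evaluating at `t - eps` internally where needed.
#' @export
censoring_survival <- function(time, cause) {
  if (!length(time)) stop("no records")
  cens <- as.integer(cause == "censored")
  if (all(time <= 0)) stop("all records censored at time 0")
  km <- survival::survfit(survival::Surv(time, cens) ~ 1)
  sfun <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  # right = FALSE makes the step land at the event time; G(t-) needs the
  # value just before t
  structure(sfun, class = c("censoring_survival", class(sfun)))
}

.G_minus <- function(G, t) G(t - 1e-10)

# shared case/control construction for the cumulative/dynamic AUC.
# Competing-cause deaths before the horizon are controls (observed not
# to die of the target cause by the horizon); emigration before the
# horizon is censoring for this estimator; ties between event time and
# horizon count as cases (closed interval at the horizon).
.auc_sets <- function(time, cause, horizon,
                      outcome = c("all_cause", "bc_specific")) {
  outcome <- match.arg(outcome)
  if (outcome == "all_cause") {
    target <- cause %in% c("bc_death", "other_death")
    competing <- rep(FALSE, length(cause))
  } else {
    target <- cause == "bc_death"
    competing <- cause == "other_death"
  }
  is_case <- target & time <= horizon
  past_horizon <- time >= horizon & !(target & time <= horizon)
  is_control <- (past_horizon | (competing & time < horizon)) & !is_case
  list(case = is_case, control = is_control)
}

# weighted pairwise exceedance probability with half credit for ties
.wauc <- function(score_case, w_case, score_ctrl, w_ctrl) {
  os <- order(score_ctrl)
  sc <- score_ctrl[os]
  wc <- w_ctrl[os]
  cw <- c(0, cumsum(wc))
  n_lt <- findInterval(score_case, sc, left.open = TRUE)  # sc < case
  n_le <- findInterval(score_case, sc)                    # sc <= case
  wins <- cw[n_lt + 1]
  ties <- cw[n_le + 1] - wins
  num <- sum(w_case * (wins + 0.5 * ties))
  num / (sum(w_case) * sum(wc))
}

#' Time-dependent AUC with competing risks (IPCW)
#'
#' Cumulative/dynamic AUC at a fixed horizon: cases are events of the
#' target cause in `(0, horizon]`; controls are subjects event-free past
#' the horizon plus (for the cause-specific outcome) competing-cause
#' deaths before it; each subject is weighted by
#' `1 / G(min(T, horizon)-)` with `G` the Kaplan-Meier censoring
#' survival. Ties in scores receive half credit. With zero cases or
#' zero controls the estimate is undefined and returned as `NA` (never
#' 0.5).
#'
#' @param records Analysis records with predictions attached.
#' @param version,horizon,outcome Select the score column
#'   (see [pred_col()]).
#' @param weights Optional per-record multiplicity weights (bootstrap).
#' @return List of class `tdauc_result`: `tdauc`, `n_cases`,
#'   `n_controls`, plus the identifiers.
#' @export
td_auc <- function(records, version, horizon,
                   outcome = c("all_cause", "bc_specific"),
                   weights = NULL) {
  outcome <- match.arg(outcome)
  score <- records[[pred_col(version, horizon, outcome)]]
  if (is.null(score)) stop("records lack the requested prediction column")
  time <- records$followup_years
  cause <- records$event_cause
  if (is.null(weights)) weights <- rep(1, length(time))
  G <- censoring_survival(time, cause)
  sets <- .auc_sets(time, cause, horizon, outcome)
  ca <- sets$case
  co <- sets$control
  if (!any(ca) || !any(co)) {
    out <- list(tdauc = NA_real_, n_cases = sum(ca), n_controls = sum(co),
                version = version, horizon = horizon, outcome = outcome)
    class(out) <- "tdauc_result"
    return(out)
  }
  w <- weights / pmax(.G_minus(G, pmin(time, horizon)), 1e-12)
  auc <- .wauc(score[ca], w[ca], score[co], w[co])
  out <- list(tdauc = auc, n_cases = sum(ca), n_controls = sum(co),
              version = version, horizon = horizon, outcome = outcome)
  class(out) <- "tdauc_result"
  out
}

#' @export
print.tdauc_result <- function(x, ...) {
  cat(sprintf("tdAUC = %s (%s, %g-year, %s): %d cases / %d controls\n",
              ifelse(is.na(x$tdauc), "undefined",
                     sprintf("%.3f", x$tdauc)),
              x$version, x$horizon, x$outcome, x$n_cases, x$n_controls))
  invisible(x)
}

#' Brute-force concordance oracle (uncensored data only)
#'
#' Exhaustive enumeration over all case-control pairs, with half credit
#' for score ties; valid only when no record is censored or emigrated
#' before the horizon, and refuses to run otherwise. In that regime it
#' equals [td_auc()] exactly.
#'
#' @inheritParams td_auc
#' @return The concordance proportion.
#' @export
concordance_oracle <- function(records, version, horizon,
                               outcome = c("all_cause", "bc_specific")) {
  outcome <- match.arg(outcome)
  time <- records$followup_years
  cause <- records$event_cause
  if (any((cause == "censored" | cause == "emigrated") & time < horizon)) {
    stop("concordance oracle requires no censoring or emigration before ",
         "the horizon")
  }
  score <- records[[pred_col(version, horizon, outcome)]]
  sets <- .auc_sets(time, cause, horizon, outcome)
  sc_case <- score[sets$case]
  sc_ctrl <- score[sets$control]
  if (!length(sc_case) || !length(sc_ctrl)) return(NA_real_)
  tot <- 0
  for (s in sc_case) {
    tot <- tot + sum(s > sc_ctrl) + 0.5 * sum(s == sc_ctrl)
  }
  tot / (length(sc_case) * length(sc_ctrl))
}
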