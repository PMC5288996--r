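risk_scores <- function(fit, records = NULL) {
  if (is.null(records)) records <- fit$records
  drop(stats::predict(fit$model, newdata = records, type = "lp"))
}

#' Harrell's concordance index for survival risk scores
#'
#' Pair-based c-index over usable pairs: a pair is comparable when the
#' shorter observed time belongs to an event. Concordant pairs have the
#' higher risk score on the earlier failure; risk ties count 0.5. The
#' standard error is a delete-one jackknife over subjects.
#'
#' @param risk numeric risk scores (higher = worse prognosis), or a
#'   `cox_fit` (its linear predictor is used).
#' @param time,event survival outcome; taken from the fit's records when
#'   `risk` is a `cox_fit`.
#' @return list: `c_index`, `se`, `n_pairs` (comparable pairs); `c_index`
#'   is NA with a message attribute when no pair is comparable.
#' @export
concordance_index <- function(risk, time = NULL, event = NULL) {
  if (inherits(risk, "cox_fit")) {
    time <- risk$records$time; event <- risk$records$event
    risk <- risk_scores(risk)
  }
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  dt <- outer(time, time, `<`)                       # t_i < t_j
  comparable <- dt & matrix(event == 1, n, n)        # earlier subject failed
  dr <- outer(risk, risk, `-`)
  conc <- sum(comparable & dr > 0) + 0.5 * sum(comparable & dr == 0)
  m <- sum(comparable)
  if (m == 0)
    return(list(c_index = NA_real_, se = NA_real_, n_pairs = 0L))
  ci <- conc / m
  # jackknife: remove subject i's pairs (as row and column)
  score <- (comparable & dr > 0) + 0.5 * (comparable & dr == 0)
  conc_i <- rowSums(score) + colSums(score)
  m_i <- rowSums(comparable) + colSums(comparable)
  ci_minus <- (conc - conc_i) / pmax(m - m_i, 1)
  ok <- m - m_i > 0
  se <- if (sum(ok) > 1) {
    v <- ci_minus[ok]
    sqrt((sum(ok) - 1) / sum(ok) * sum((v - mean(v))^2))
  } else NA_real_
  list(c_index = ci, se = se, n_pairs = m)
}

# Kaplan-Meier estimate of the censoring survival function G(t) = P(C > t);
# returns a function with a left-limit option for IPCW weights at event times
censoring_km <- function(time, event) {
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- cf$time; ss <- cf$surv
  function(t, left = FALSE) {
    idx <- findInterval(t, tt, left.open = left)
    c(1, ss)[idx + 1L]
  }
}

predicted_survival <- function(fit, records, eval_times) {
  # uncentered baseline hazard must pair with the uncentered linear predictor
  bh <- survival::basehaz(fit$model, centered = FALSE)
  H0 <- stats::stepfun(bh$time, c(0, bh$hazard))(eval_times)
  lp <- drop(stats::predict(fit$model, newdata = records, type = "lp",
                            reference = "zero"))
  exp(-outer(exp(lp), H0))                # n x length(eval_times)
}

#' IPCW Brier score for a survival model
#'
#' Inverse-probability-of-censoring-weighted squared prediction error of the
#' predicted survival probability at each evaluation time, with
#' Kaplan-Meier censoring weights, plus the trapezoid-integrated score.
#'
#' @param fit a `cox_fit`, or NULL when `predicted` is supplied.
#' @param records data.frame with `time`, `event` (defaults to the fit's
#'   records).
#' @param eval_times evaluation time grid within the follow-up range.
#' @param predicted optional n x length(eval_times) matrix of predicted
#'   survival probabilities P(T > t), overriding model predictions.
#' @return list: `times`, `brier` (per time; NA where the censoring weight
#'   vanishes), `integrated`.
#' @export
brier_score <- function(fit = NULL, records = NULL, eval_times,
                        predicted = NULL) {
  if (is.null(records)) records <- fit$records
  time <- records$time; event <- records$event
  if (any(eval_times > max(time)))
    stop("eval_times must lie within the follow-up range")
  if (is.null(predicted)) predicted <- predicted_survival(fit, records, eval_times)
  predicted <- as.matrix(predicted)
  stopifnot(nrow(predicted) == length(time),
            ncol(predicted) == length(eval_times))
  G <- censoring_km(time, event)
  g_left <- G(time, left = TRUE)          # G(T_i-)
  bs <- rep(NA_real_, length(eval_times))
  for (k in seq_along(eval_times)) {
    t <- eval_times[k]
    g_t <- G(t)
    died <- time <= t & event == 1
    alive <- time > t
    w <- numeric(length(time))
    ok <- TRUE
    if (any(died)) {
      if (any(g_left[died] <= 0)) ok <- FALSE else w[died] <- 1 / g_left[died]
    }
    if (any(alive)) {
      if (g_t <= 0) ok <- FALSE else w[alive] <- 1 / g_t
    }
    if (!ok) { warning(sprintf("zero censoring weight at t=%g; dropped", t)); next }
    err <- (as.numeric(alive) - predicted[, k])^2
    bs[k] <- mean(w * err)
  }
  keep <- !is.na(bs)
  integrated <- if (sum(keep) >= 2) {
    tt <- eval_times[keep]; bb <- bs[keep]
    sum(diff(tt) * (utils::head(bb, -1) + utils::tail(bb, -1)) / 2) / diff(range(tt))
  } else if (sum(keep) == 1) bs[keep] else NA_real_
  list(times = eval_times, brier = bs, integrated = integrated)
}

#' Time-dependent AUROC (cumulative cases / dynamic controls, IPCW)
#'
#' At each evaluation time t, cases are subjects with an observed event by t
#' and controls are subjects still at risk beyond t; both are weighted by
#' inverse Kaplan-Meier censoring probabilities. The summary is the
#' trapezoid-weighted mean over the grid.
#'
#' @param fit a `cox_fit`, or NULL when `risk` is supplied.
#' @param records data.frame with `time`, `event` (defaults to the fit's).
#' @param eval_times evaluation time grid.
#' @param risk optional numeric risk scores overriding the fit's linear
#'   predictor.
#' @return list: `times`, `auroc` (per time; NA when a time has no case or
#'   no control), `summary`.
#' @export
time_dependent_auroc <- function(fit = NULL, records = NULL, eval_times,
                                 risk = NULL) {
  if (is.null(records)) records <- fit$records
  time <- records$time; event <- records$event
  if (is.null(risk)) risk <- risk_scores(fit, records)
  G <- censoring_km(time, event)
  g_left <- G(time, left = TRUE)
  auc <- rep(NA_real_, length(eval_times))
  for (k in seq_along(eval_times)) {
    t <- eval_times[k]
    cases <- which(time <= t & event == 1 & g_left > 0)
    controls <- which(time > t)
    if (!length(cases) || !length(controls)) next
    g_t <- G(t)
    if (g_t <= 0) next
    w_case <- 1 / g_left[cases]
    w_ctrl <- rep(1 / g_t, length(controls))
    dr <- outer(risk[cases], risk[controls], `-`)
    wmat <- outer(w_case, w_ctrl)
    auc[k] <- sum(wmat * ((dr > 0) + 0.5 * (dr == 0))) / sum(wmat)
  }
  keep <- !is.na(auc)
  summary <- if (sum(keep) >= 2) {
    tt <- eval_times[keep]; aa <- auc[keep]
    sum(diff(tt) * (utils::head(aa, -1) + utils::tail(aa, -1)) / 2) / diff(range(tt))
  } else if (sum(keep) == 1) auc[keep] else NA_real_
  list(times = eval_times, auroc = auc, summary = summary)
}
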