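#' Fit a Cox proportional hazards model
#'
#' Wraps `survival::coxph` with the Efron tie approximation and returns a
#' tidy coefficient table with hazard ratios, Wald 95\% confidence intervals
#' and p-values, plus the partial log-likelihoods needed for nested-model
#' likelihood-ratio tests.
#'
#' @param records data.frame with columns `time` (> 0), `event` (0/1) and
#'   the covariates.
#' @param covariates character vector of covariate names to include.
#' @return list of class `cox_fit`: `table` (term, coef, hr, lower, upper,
#'   p), `loglik` (null, model), `n`, `n_events`, `converged`,
#'   `separation` (terms with |coef| > 20), `covariates`, `model` (the
#'   underlying coxph object), `records`.
#' @export
fit_cox <- function(records, covariates) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (!all(covariates %in% names(records)))
    stop("missing covariates: ",
         paste(setdiff(covariates, names(records)), collapse = ", "))
  if (any(records$time <= 0)) stop("all times must be > 0")
  if (sum(records$event) < 1) stop("need at least one event")
  const <- covariates[vapply(records[covariates],
                             function(x) length(unique(x)) < 2, TRUE)]
  if (length(const))
    stop("constant covariates: ", paste(const, collapse = ", "))
  fml <- stats::reformulate(sprintf("`%s`", covariates),
                            response = "survival::Surv(time, event)")
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (is.null(fit$coefficients))
    stop("model has no estimable coefficients")
  sm <- summary(fit)
  coef <- fit$coefficients
  se <- sqrt(diag(fit$var))
  tab <- data.frame(term = names(coef), coef = unname(coef),
                    hr = unname(exp(coef)),
                    lower = unname(exp(coef - 1.96 * se)),
                    upper = unname(exp(coef + 1.96 * se)),
                    p = unname(2 * stats::pnorm(-abs(coef / se))),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$term <- gsub("^`|`$", "", tab$term)
  iter_info <- fit$iter
  structure(list(table = tab, loglik = fit$loglik, n = fit$n,
                 n_events = fit$nevent,
                 converged = is.finite(fit$loglik[2]) &&
                   (is.null(iter_info) || iter_info < 100),
                 separation = tab$term[abs(tab$coef) > 20],
                 covariates = covariates, model = fit, records = records),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d records, %d events\n", x$n, x$n_events))
  print(x$table, digits = 3)
  invisible(x)
}

#' Test the proportional-hazards assumption via scaled Schoenfeld residuals
#'
#' Correlates the scaled Schoenfeld residuals with time (identity transform)
#' per covariate, plus the global test, via `survival::cox.zph`.
#'
#' @param fit a `cox_fit`.
#' @return data.frame: term (including GLOBAL), chisq, df, p.
#' @export
test_proportionality <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) stop("need >= 3 events to assess proportionality")
  z <- survival::cox.zph(fit$model, transform = "identity", global = TRUE)
  tab <- as.data.frame(z$table)
  data.frame(term = gsub("^`|`$", "", rownames(tab)), chisq = tab$chisq,
             df = tab$df, p = tab$p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param fit_full `cox_fit` of the larger model.
#' @param fit_nested `cox_fit` whose covariates are a subset of the full
#'   model's, fitted to the same records.
#' @return list: `statistic` (2 x delta partial log-likelihood), `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "cox_fit"), inherits(fit_nested, "cox_fit"))
  if (!all(fit_nested$covariates %in% fit_full$covariates))
    stop("models are not nested (covariate sets)")
  if (fit_full$n != fit_nested$n || fit_full$n_events != fit_nested$n_events)
    stop("models were fitted to different records")
  df <- length(fit_full$model$coefficients) - length(fit_nested$model$coefficients)
  stat <- max(0, 2 * (fit_full$loglik[2] - fit_nested$loglik[2]))
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p = p)
}

#' Kaplan-Meier curves, median survival and log-rank comparison
#'
#' @param records data.frame with `time`, `event` and optionally the
#'   grouping column.
#' @param group_by optional name of a grouping column; with two or more
#'   groups a log-rank test is reported.
#' @return list: `curves` (data.frame: group, time, n_risk, n_event,
#'   surv), `median` (named per group; NA when never reached),
#'   `logrank_p` (NULL without grouping).
#' @export
kaplan_meier <- function(records, group_by = NULL) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (is.null(group_by)) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
    groups <- rep("all", length(sf$time))
    lr_p <- NULL
  } else {
    if (!group_by %in% names(records)) stop("unknown group column: ", group_by)
    records$.group <- droplevels(as.factor(records[[group_by]]))
    if (nlevels(records$.group) < 2) {
      out <- kaplan_meier(records[setdiff(names(records), ".group")])
      lvl <- levels(records$.group)
      out$curves$group <- lvl
      names(out$median) <- lvl
      return(out)
    }
    sf <- survival::survfit(survival::Surv(time, event) ~ .group, data = records)
    groups <- rep(sub("^\\.group=", "", names(sf$strata)), sf$strata)
    lr_p <- {
      sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                               data = records)
      stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
    }
  }
  curves <- data.frame(group = groups, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  # median: earliest time at which the survival curve reaches 0.5 or below
  med <- vapply(split(curves, curves$group), function(cv) {
    hit <- cv$time[cv$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  list(curves = curves, median = med, logrank_p = lr_p)
}
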