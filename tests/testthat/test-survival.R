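# six untied records used by several fixtures (times in months)
tiny_records <- data.frame(
  time = c(3.1, 5.4, 7.2, 9.8, 12.5, 16.0),
  event = c(1, 1, 0, 1, 1, 1),
  x = c(1, 0, 1, 1, 0, 0))

test_that("Cox coefficient matches 1-D brute-force partial likelihood", {
  fit <- fit_cox(tiny_records, "x")
  b_oracle <- oracle_cox_coef(tiny_records$time, tiny_records$event,
                              tiny_records$x)
  expect_equal(fit$table$coef, b_oracle, tolerance = 1e-6)
  expect_equal(fit$table$hr, exp(b_oracle), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_events, 5)
  # CI brackets the HR
  expect_lt(fit$table$lower, fit$table$hr)
  expect_gt(fit$table$upper, fit$table$hr)

  expect_error(fit_cox(transform(tiny_records, event = 0), "x"), "event")
  expect_error(fit_cox(transform(tiny_records, x = 1), "x"), "constant")
  expect_error(fit_cox(tiny_records, "nope"), "missing")
})

test_that("planted hazard ratios are recovered and CIs cover", {
  set.seed(71)
  hrs <- c(); cover <- c()
  for (r in 1:30) {
    cov <- data.frame(g = rbinom(300, 1, 0.5))
    surv <- simulate_survival(cov, c(g = log(2)), baseline_scale = 60,
                              censor_rate = 0.2, seed = 7000 + r)
    fit <- fit_cox(cbind(surv, cov), "g")
    hrs <- c(hrs, fit$table$hr)
    cover <- c(cover, fit$table$lower <= 2 && 2 <= fit$table$upper)
  }
  expect_gt(mean(hrs), 1.8)
  expect_lt(mean(hrs), 2.2)
  expect_gte(mean(cover), 0.85)
})

test_that("proportionality test is calibrated and collapses for 1 covariate", {
  set.seed(72)
  cov <- data.frame(g = rbinom(200, 1, 0.5))
  surv <- simulate_survival(cov, c(g = log(2)), baseline_scale = 60,
                            censor_rate = 0.2, seed = 73)
  fit <- fit_cox(cbind(surv, cov), "g")
  z <- test_proportionality(fit)
  expect_identical(z$term, c("g", "GLOBAL"))
  expect_equal(z$chisq[1], z$chisq[2])
  expect_equal(z$p[1], z$p[2])

  # under exact PH the test rejects at roughly nominal rate
  rej <- 0; reps <- 100
  for (r in seq_len(reps)) {
    s <- simulate_survival(cov, c(g = log(2)), baseline_scale = 60,
                           censor_rate = 0.2, seed = 7400 + r)
    p <- test_proportionality(fit_cox(cbind(s, cov), "g"))$p[1]
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.10)
})

test_that("concordance index matches enumeration and its edge cases", {
  # risk perfectly ordered against event times, no censoring
  time <- c(10, 8, 6, 4, 2)
  risk <- 1:5
  ci <- concordance_index(risk, time, rep(1, 5))
  expect_equal(ci$c_index, 1)
  expect_equal(ci$n_pairs, 10)

  # 4-record fixture with one censored record: hand-enumerated pairs
  ci2 <- concordance_index(risk = c(3, 1, 2, 0),
                           time = c(2, 4, 6, 8),
                           event = c(1, 1, 0, 1))
  expect_equal(ci2$c_index, 0.8)  # 4 concordant of 5 comparable
  expect_equal(ci2$c_index,
               oracle_c_index(c(3, 1, 2, 0), c(2, 4, 6, 8), c(1, 1, 0, 1)))
  # no comparable pairs
  ci3 <- concordance_index(c(1, 2), c(5, 6), c(0, 0))
  expect_true(is.na(ci3$c_index))

  # independent risk scores: c about 0.5
  set.seed(74)
  cs <- replicate(100, {
    t <- rexp(80); concordance_index(rnorm(80), t, rep(1, 80))$c_index
  })
  expect_lt(abs(mean(cs) - 0.5), 0.03)
})

test_that("Brier score matches closed forms and the IPCW oracle", {
  # perfect predictions, no censoring
  rec <- data.frame(time = c(1, 2, 6, 7), event = 1)
  pred <- matrix(c(0, 0, 1, 1), ncol = 1)  # evaluated at t = 4
  bs <- brier_score(records = rec, eval_times = 4, predicted = pred)
  expect_equal(bs$brier, 0)
  # constant prediction 0.5 under no censoring
  pred2 <- matrix(0.5, 4, 1)
  bs2 <- brier_score(records = rec, eval_times = 4, predicted = pred2)
  expect_equal(bs2$brier, 0.25)
  # censored 6-record fixture vs independent IPCW computation
  pred3 <- matrix(c(0.9, 0.2, 0.7, 0.4, 0.8, 0.3), ncol = 1)
  bs3 <- brier_score(records = tiny_records, eval_times = 8, predicted = pred3)
  expect_equal(bs3$brier,
               oracle_brier(tiny_records$time, tiny_records$event,
                            drop(pred3), 8))
  expect_error(brier_score(records = rec, eval_times = 99, predicted = pred),
               "range")
})

test_that("model-based survival predictions match survfit individual curves", {
  set.seed(79)
  cov <- data.frame(g = rbinom(120, 1, 0.5), z = rnorm(120))
  surv <- simulate_survival(cov, c(g = log(2), z = 0.3), baseline_scale = 60,
                            censor_rate = 0.3, seed = 80)
  rec <- cbind(surv, cov)
  fit <- fit_cox(rec, c("g", "z"))
  t_eval <- unname(quantile(rec$time[rec$event == 1], 0.5))
  pred <- mdnlr:::predicted_survival(fit, rec[1:5, ], t_eval)
  sf <- survival::survfit(fit$model, newdata = rec[1:5, ])
  idx <- max(which(sf$time <= t_eval))
  expect_equal(unname(drop(pred)), unname(sf$surv[idx, ]), tolerance = 0.02)
  # fitted-model Brier is bounded sensibly on its own training data
  bs <- brier_score(fit, eval_times = t_eval)
  expect_lt(bs$brier, 0.3)
})

test_that("time-dependent AUROC is 1 for separating scores, 0.5 for noise", {
  rec <- data.frame(time = c(2, 3, 8, 9), event = 1)
  au <- time_dependent_auroc(records = rec, eval_times = 5,
                             risk = c(4, 3, 2, 1))
  expect_equal(au$auroc, 1)
  # equals concordance-style enumeration on an uncensored fixture at large t
  risk <- c(0.3, 1.2, 0.1, 2.4, 0.7)
  rec2 <- data.frame(time = c(1, 2, 3, 4, 5), event = 1)
  au2 <- time_dependent_auroc(records = rec2, eval_times = 4.5, risk = risk)
  cases <- 1:4; controls <- 5
  pairs <- outer(risk[cases], risk[controls], `>`)
  expect_equal(au2$auroc, mean(pairs))
  set.seed(75)
  aus <- replicate(100, {
    t <- rexp(80)
    time_dependent_auroc(records = data.frame(time = t, event = 1),
                         eval_times = median(t), risk = rnorm(80))$auroc
  })
  expect_lt(abs(mean(aus) - 0.5), 0.03)
})

test_that("likelihood-ratio test behaves for identical, nested, null models", {
  set.seed(76)
  cov <- data.frame(g = rbinom(300, 1, 0.5), z = rnorm(300))
  surv <- simulate_survival(cov, c(g = log(2)), baseline_scale = 60,
                            censor_rate = 0.2, seed = 77)
  rec <- cbind(surv, cov)
  fit_g <- fit_cox(rec, "g")
  fit_gz <- fit_cox(rec, c("g", "z"))
  same <- likelihood_ratio_test(fit_g, fit_g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # planted effect: adding g to the null-only model is highly significant
  fit_z <- fit_cox(rec, "z")
  expect_error(likelihood_ratio_test(fit_g, fit_z), "nested")
  lr <- likelihood_ratio_test(fit_gz, fit_z)
  expect_lt(lr$p, 0.05)
  # null added covariate: uniform p (calibration over reps)
  rej <- 0; reps <- 100
  for (r in seq_len(reps)) {
    s <- simulate_survival(cov, c(g = log(2)), baseline_scale = 60,
                           censor_rate = 0.2, seed = 7800 + r)
    rr <- cbind(s, cov)
    lr_r <- likelihood_ratio_test(fit_cox(rr, c("g", "z")), fit_cox(rr, "g"))
    if (lr_r$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / reps, 0.01)
  expect_lte(rej / reps, 0.10)
})

test_that("Kaplan-Meier steps, medians and log-rank match expectations", {
  rec <- data.frame(time = 1:10, event = 1)
  km <- kaplan_meier(rec)
  expect_equal(km$curves$surv, seq(0.9, 0, by = -0.1))
  expect_equal(unname(km$median), 5)

  rec2 <- data.frame(time = 1:5, event = 0)
  km2 <- kaplan_meier(rec2)
  expect_true(is.na(km2$median))

  set.seed(78)
  g <- rep(c("a", "b"), each = 200)
  t <- c(rexp(200, 1), rexp(200, 2))
  km3 <- kaplan_meier(data.frame(time = t, event = 1, grp = g),
                      group_by = "grp")
  expect_lt(km3$logrank_p, 0.05)
  expect_gt(unname(km3$median["a"]), unname(km3$median["b"]))
})
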