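test_that("lineage model flags planted myeloid surrogates with large |t|", {
  truth <- generate_reference_profiles(1000, 50, 5, seed = 61)
  pur <- simulate_purified_samples(truth, n_per_type = 9, seed = 62)
  st <- fit_lineage_model(beta_to_m(pur$beta), pur$lineage, pur$measured_props)
  rownames(st) <- st$cpg_id
  # myeloid-demethylated surrogates: strongly negative lineage coefficient
  expect_true(all(st[truth$surrogate_ids, "lineage_coef"] < 0))
  expect_true(all(abs(st[truth$surrogate_ids, "t_stat"]) > 10))
  expect_identical(sort(st$rank), seq_len(nrow(st)))
  # background (no lineage signal) CpGs rank in the bottom of the list
  bg <- setdiff(st$cpg_id, c(truth$ldmr_ids, truth$surrogate_ids))
  expect_gt(median(st[bg, "rank"]), nrow(st) / 2)

  # permutation of sample order (with aligned labels) leaves stats unchanged
  perm <- sample(ncol(pur$beta))
  st2 <- fit_lineage_model(beta_to_m(pur$beta)[, perm], pur$lineage[perm],
                           pur$measured_props[perm, ])
  expect_equal(st$t_stat, st2$t_stat)

  # collinear covariates (constant column aliases the intercept) are rejected
  bad_props <- pur$measured_props
  bad_props[, 1] <- 0.5
  expect_error(fit_lineage_model(beta_to_m(pur$beta), pur$lineage, bad_props),
               "collinear")
  expect_error(fit_lineage_model(beta_to_m(pur$beta[, 1:4]),
                                 pur$lineage[1:4], pur$measured_props[1:4, ]),
               ">= 3")
})

test_that("top-loci selection is deterministic with lexicographic ties", {
  stats <- data.frame(cpg_id = c("cg3", "cg1", "cg2", "cg4"),
                      lineage_coef = c(1, -2, 2, 0.5),
                      t_stat = c(5, -7, 7, 1),
                      rank = c(3, 1, 2, 4))
  expect_identical(select_top_loci(stats, 1), "cg1")  # tie |7| broken by id
  expect_identical(select_top_loci(stats, 3), c("cg1", "cg2", "cg3"))
  expect_error(select_top_loci(stats, 5))
})

test_that("polynomial surrogate fits recover exact, null and curved signals", {
  set.seed(63)
  m <- rnorm(30)
  fit <- fit_mdnlr_surrogate(2 * m + 1, m, degrees = 1)
  expect_equal(fit$best_adj_r2, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-8)

  # independent outcome: adjusted R^2 centered at zero
  r2 <- replicate(200, {
    x <- rnorm(100)
    fit_mdnlr_surrogate(rnorm(100), x, degrees = 1)$best_adj_r2
  })
  expect_lt(abs(mean(r2)), 0.03)

  # planted quadratic: degree 2 beats degree 1
  x <- seq(-2, 2, length.out = 60)
  y <- (x - 0.5)^2 + rnorm(60, 0, 0.1)
  f <- fit_mdnlr_surrogate(y, x, degrees = 1:2)
  expect_gt(f$adj_r2[["2"]], f$adj_r2[["1"]])
  expect_identical(f$best_degree, 2L)

  # adjusted R^2 is invariant to affine rescaling of the locus values
  f1 <- fit_mdnlr_surrogate(y, x, degrees = 1:3)
  f2 <- fit_mdnlr_surrogate(y, 3 * x - 5, degrees = 1:3)
  expect_equal(f1$adj_r2, f2$adj_r2, tolerance = 1e-8)

  # constant locus is degenerate, not selected
  fc <- fit_mdnlr_surrogate(y, rep(1, 60))
  expect_true(fc$degenerate)
  expect_true(is.na(fc$best_adj_r2))
  expect_error(fit_mdnlr_surrogate(1:3, 1:3, degrees = 3), "samples")
})

test_that("consistent-surrogate selection thresholds across datasets", {
  df <- function(ids, r2) data.frame(cpg_id = ids, best_degree = 2,
                                     best_adj_r2 = r2)
  d1 <- df(c("a", "b", "c"), c(0.95, 0.85, 0.40))
  d2 <- df(c("a", "b", "c"), c(0.90, 0.75, 0.45))
  sel <- select_consistent_surrogates(list(d1, d2), threshold = 0.8)
  expect_identical(as.character(sel), "a")
  # single dataset reduces to thresholding
  sel1 <- select_consistent_surrogates(list(d1), threshold = 0.8)
  expect_identical(as.character(sel1), c("a", "b"))
  # unattainable threshold
  expect_length(select_consistent_surrogates(list(d1, d2), threshold = 1.01), 0)
  # locus absent from one dataset is excluded and logged
  d3 <- df(c("a", "b"), c(0.99, 0.99))
  sel3 <- select_consistent_surrogates(list(d1, d3), threshold = 0.8)
  expect_identical(attr(sel3, "excluded"), "c")
})

test_that("screening three planted cohorts selects exactly the surrogates", {
  truth <- generate_reference_profiles(1000, 50, 5, seed = 64)
  pur <- simulate_purified_samples(truth, seed = 65)
  st <- fit_lineage_model(beta_to_m(pur$beta), pur$lineage, pur$measured_props)
  top <- select_top_loci(st, 100)
  expect_true(all(truth$surrogate_ids %in% top))
  screens <- lapply(1:3, function(k) {
    ch <- simulate_screening_cohort(truth, n_samples = 250, seed = 650 + 7 * k)
    screen_surrogates(ch$mdnlr, ch$m, loci = top)
  })
  sel <- select_consistent_surrogates(screens, threshold = 0.80)
  expect_setequal(as.character(sel), truth$surrogate_ids)
})

test_that("Mann-Whitney group comparison matches exact enumeration", {
  beta <- matrix(c(1, 2, 3, 4, 5, 6) / 10, nrow = 1,
                 dimnames = list("cgA", paste0("S", 1:6)))
  res <- compare_groups_by_locus(beta, c("g1", "g1", "g1", "g2", "g2", "g2"))
  # fully separated groups of 3: exact two-sided p = 2 * 1/choose(6,3) = 0.1
  expect_equal(res$p_value, 0.1)
  expect_true(res$U %in% c(0, 9))
  expect_equal(res$g1_median, 20)   # percentage scale
  expect_equal(res$g2_median, 50)

  beta2 <- matrix(c(0.2, 0.25, 0.3, 0.2, 0.25, 0.3), nrow = 1,
                  dimnames = list("cgB", paste0("S", 1:6)))
  res2 <- compare_groups_by_locus(beta2, rep(c("x", "y"), each = 3))
  expect_equal(res2$x_median, 25)
  expect_equal(res2$x_q25, 22.5)
  expect_equal(res2$x_q75, 27.5)
  expect_error(compare_groups_by_locus(beta2, rep("x", 6)), "two levels")
})

test_that("Mann-Whitney p-values are calibrated under the null", {
  set.seed(66)
  n_rej <- 0; reps <- 400
  for (r in seq_len(reps)) {
    x <- matrix(runif(16), nrow = 1, dimnames = list("cg", paste0("S", 1:16)))
    p <- compare_groups_by_locus(x, sample(rep(c("a", "b"), 8)))$p_value
    if (p < 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej / reps, 0.02)
  expect_lte(n_rej / reps, 0.08)
})
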