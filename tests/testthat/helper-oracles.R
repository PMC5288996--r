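# Independent oracles used across the suite. These are deliberately naive
# (enumeration, grids, closed forms) and never call the implementation paths
# they check.

# Cox partial log-likelihood for a single covariate, computed by direct
# summation over event times (Breslow form; fixtures use untied times, where
# Breslow and Efron coincide).
oracle_cox_loglik <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  s
}

oracle_cox_coef <- function(time, event, x) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, x),
                  interval = c(-10, 10), tol = 1e-10)$minimum
}

# Enumeration oracle for Harrell's c on small fixtures.
oracle_c_index <- function(risk, time, event) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Grid of 3-component weight vectors with w >= 0, sum(w) <= 1 (step 0.005),
# built once per test session.
simplex_grid_3 <- local({
  grid <- NULL
  function(step = 0.005) {
    if (is.null(grid)) {
      k <- round(1 / step)
      ij <- expand.grid(i = 0:k, j = 0:k)
      ij <- ij[ij$i + ij$j <= k, ]
      pts <- list()
      w12 <- cbind(ij$i, ij$j) * step
      # third coordinate ranges over the remaining mass
      rem <- k - ij$i - ij$j
      reps <- rem + 1L
      w1 <- rep(w12[, 1], reps)
      w2 <- rep(w12[, 2], reps)
      w3 <- unlist(lapply(rem, function(r) 0:r)) * step
      grid <<- cbind(w1, w2, w3)
    }
    grid
  }
})

oracle_grid_objective <- function(X, y, step = 0.005) {
  W <- simplex_grid_3(step)
  A <- crossprod(X)
  b <- drop(crossprod(X, y))
  cc <- sum(y^2)
  obj <- cc - 2 * drop(W %*% b) + rowSums((W %*% A) * W)
  min(obj)
}

# Kaplan-Meier of the censoring distribution by explicit product-limit,
# used by the IPCW Brier oracle.
oracle_censor_km <- function(time, event) {
  tt <- sort(unique(time[event == 0]))
  function(t) {
    g <- 1
    for (u in tt) {
      if (u > t) break
      at_risk <- sum(time >= u)
      d <- sum(time == u & event == 0)
      g <- g * (1 - d / at_risk)
    }
    g
  }
}

oracle_brier <- function(time, event, pred_surv, t) {
  G <- oracle_censor_km(time, event)
  n <- length(time)
  total <- 0
  for (i in seq_len(n)) {
    if (time[i] <= t && event[i] == 1) {
      total <- total + (0 - pred_surv[i])^2 / G(time[i] - 1e-9)
    } else if (time[i] > t) {
      total <- total + (1 - pred_surv[i])^2 / G(t)
    }
  }
  total / n
}

# one surrogate-screening cohort for a given reference truth: simulate,
# deconvolve, and screen every CpG as a polynomial surrogate of the mdNLR
screen_surrogates_for <- function(truth, n_samples = 300, seed) {
  ch <- simulate_screening_cohort(truth, n_samples = n_samples, seed = seed)
  screen_surrogates(ch$mdnlr, ch$m)
}

# convenience: a true_composition object from an explicit proportion matrix
manual_composition <- function(props) {
  lym <- rowSums(props[, c("CD4T", "CD8T", "B", "NK"), drop = FALSE])
  structure(list(sample_ids = rownames(props), proportions = props,
                 true_nlr = props[, "Gran"] / lym,
                 strata = rep("all", nrow(props))),
            class = "true_composition")
}
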