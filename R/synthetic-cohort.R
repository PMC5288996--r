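LEUKOCYTE_TYPES <- c("CD4T", "CD8T", "B", "NK", "Mono", "Gran")
MYELOID_TYPES <- c("Mono", "Gran")
LYMPHOID_TYPES <- c("CD4T", "CD8T", "B", "NK")

#' Generate purified leukocyte reference methylation profiles
#'
#' Builds a synthetic CpG-by-cell-type matrix of mean beta values for the six
#' leukocyte subtypes used in blood deconvolution (CD4T, CD8T, B, NK, Mono,
#' Gran). Three classes of CpG are planted: leukocyte differentially
#' methylated regions (L-DMRs, one block per cell type, each uniquely hypo- or
#' hypermethylated in its target type by at least 0.3 beta), myeloid
#' surrogate loci (demethylated in monocytes and granulocytes, methylated in
#' lymphoid cells), and background CpGs sharing a common mean across types.
#'
#' @param n_cpgs total number of CpGs in the synthetic universe.
#' @param n_ldmr_per_type number of L-DMR CpGs planted per cell type.
#' @param n_surrogates number of myeloid-demethylated surrogate CpGs.
#' @param seed integer seed; required for reproducibility.
#' @return A list of class `reference_truth` with elements `cell_types`,
#'   `profiles` (CpG x cell-type beta matrix), `ldmr_ids` (character vector),
#'   `ldmr_type` (named by CpG, which cell type each L-DMR marks),
#'   `surrogate_ids`, and `seed`.
#' @export
generate_reference_profiles <- function(n_cpgs, n_ldmr_per_type = 50,
                                        n_surrogates = 5, seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: reference generation must be reproducible")
  n_planted <- 6L * n_ldmr_per_type + n_surrogates
  if (n_planted > n_cpgs)
    stop(sprintf("planted CpGs (%d) exceed universe size (%d)", n_planted, n_cpgs))
  set.seed(seed)

  cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))
  idx <- sample.int(n_cpgs)
  ldmr_idx <- idx[seq_len(6L * n_ldmr_per_type)]
  surr_idx <- idx[6L * n_ldmr_per_type + seq_len(n_surrogates)]

  # background: one common mean per CpG, identical across cell types
  base <- stats::rbeta(n_cpgs, 2, 2)
  profiles <- matrix(base, nrow = n_cpgs, ncol = 6,
                     dimnames = list(cpg_ids, LEUKOCYTE_TYPES))

  ldmr_type <- character(0)
  for (k in seq_along(LEUKOCYTE_TYPES)) {
    rows <- ldmr_idx[(k - 1L) * n_ldmr_per_type + seq_len(n_ldmr_per_type)]
    n_hypo <- ceiling(n_ldmr_per_type / 2)
    hypo <- rows[seq_len(n_hypo)]
    hyper <- setdiff(rows, hypo)
    # target type sits >= 0.3 beta away from every other type
    delta <- stats::runif(length(rows), 0.30, 0.33)
    others_hi <- stats::runif(length(hypo), 0.65, 0.90)
    profiles[hypo, ] <- others_hi
    profiles[cbind(hypo, k)] <- others_hi - delta[seq_along(hypo)]
    others_lo <- stats::runif(length(hyper), 0.10, 0.35)
    profiles[hyper, ] <- others_lo
    profiles[cbind(hyper, k)] <- others_lo + delta[length(hypo) + seq_along(hyper)]
    ldmr_type <- c(ldmr_type, stats::setNames(rep(LEUKOCYTE_TYPES[k], length(rows)),
                                              cpg_ids[rows]))
  }

  # surrogates: demethylated across the myeloid compartment, methylated in
  # lymphoid cells (mimics myeloid-differentiation demethylation events)
  for (r in surr_idx) {
    profiles[r, MYELOID_TYPES] <- stats::runif(2, 0.08, 0.13)
    profiles[r, LYMPHOID_TYPES] <- stats::runif(4, 0.90, 0.94)
  }

  structure(list(
    cell_types = LEUKOCYTE_TYPES,
    profiles = profiles,
    ldmr_ids = cpg_ids[sort(ldmr_idx)],
    ldmr_type = ldmr_type,
    surrogate_ids = cpg_ids[sort(surr_idx)],
    seed = seed
  ), class = "reference_truth")
}

#' Dirichlet concentration vector targeting a given neutrophil-lymphocyte ratio
#'
#' Maps a target NLR to a six-part Dirichlet alpha whose mean composition has
#' granulocyte/lymphoid ratio equal to `nlr`, monocyte share `mono`, and the
#' lymphoid mass split 40/30/20/10 across CD4T/CD8T/B/NK.
#'
#' @param nlr target mean granulocyte-to-lymphocyte ratio.
#' @param mono mean monocyte fraction.
#' @param concentration total Dirichlet concentration (larger = tighter).
#' @return named numeric vector of length 6.
#' @export
alpha_for_nlr <- function(nlr, mono = 0.10, concentration = 25) {
  stopifnot(nlr > 0, mono > 0, mono < 1, concentration > 0)
  lymph <- (1 - mono) / (1 + nlr)
  gran <- nlr * lymph
  mean_comp <- c(CD4T = 0.4, CD8T = 0.3, B = 0.2, NK = 0.1) * lymph
  mean_comp <- c(mean_comp, Mono = mono, Gran = unname(gran))
  concentration * mean_comp[LEUKOCYTE_TYPES]
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g <- g / rowSums(g)
  colnames(g) <- names(alpha)
  if (is.null(colnames(g))) colnames(g) <- LEUKOCYTE_TYPES[seq_along(alpha)]
  g
}

#' Sample true leukocyte compositions from stratum-specific Dirichlet priors
#'
#' Draws per-sample cell-type proportions on the unit simplex. Case strata can
#' be shifted toward granulocytes by supplying a larger granulocyte alpha.
#' Rows whose lymphoid mass falls below `lymphoid_floor` are redrawn so the
#' true NLR is always finite.
#'
#' @param n_samples number of samples.
#' @param alpha either a numeric vector of 6 positive concentrations, or a
#'   named list of such vectors (one per stratum).
#' @param strata optional character vector of stratum labels per sample;
#'   required when `alpha` is a list.
#' @param seed integer seed.
#' @param lymphoid_floor minimum CD4T+CD8T+B+NK mass accepted in a draw.
#' @return list of class `true_composition`: `sample_ids`, `proportions`
#'   (sample x 6 matrix), `true_nlr`, `strata`.
#' @export
sample_compositions <- function(n_samples, alpha, strata = NULL, seed,
                                lymphoid_floor = 0.02) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  if (is.list(alpha)) {
    if (is.null(strata) || length(strata) != n_samples)
      stop("per-stratum alpha requires 'strata' of length n_samples")
    if (!all(strata %in% names(alpha)))
      stop("strata labels missing from names(alpha)")
    alphas <- alpha
  } else {
    strata <- rep("all", n_samples)
    alphas <- list(all = alpha)
  }
  for (a in alphas) {
    if (length(a) != 6 || any(a <= 0))
      stop("each alpha must be a positive vector of length 6")
  }
  set.seed(seed)
  props <- matrix(NA_real_, n_samples, 6,
                  dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                                  LEUKOCYTE_TYPES))
  for (s in names(alphas)) {
    rows <- which(strata == s)
    if (!length(rows)) next
    draw <- rdirichlet(length(rows), alphas[[s]])
    lymph <- rowSums(draw[, LYMPHOID_TYPES, drop = FALSE])
    bad <- which(lymph < lymphoid_floor)
    guard <- 0L
    while (length(bad)) {
      draw[bad, ] <- rdirichlet(length(bad), alphas[[s]])
      lymph <- rowSums(draw[, LYMPHOID_TYPES, drop = FALSE])
      bad <- which(lymph < lymphoid_floor)
      guard <- guard + 1L
      if (guard > 1000L) stop("could not satisfy lymphoid floor; alpha too extreme")
    }
    props[rows, ] <- draw
  }
  true_nlr <- props[, "Gran"] / rowSums(props[, LYMPHOID_TYPES])
  structure(list(sample_ids = rownames(props), proportions = props,
                 true_nlr = true_nlr, strata = strata),
            class = "true_composition")
}

#' Synthesize whole-blood methylation betas as noisy convex mixtures
#'
#' Mixes the purified reference profiles by the true compositions, adds
#' truncated Gaussian noise on the beta scale (clipped to \[0,1\]) and emits a
#' matched detection p-value matrix, optionally planting failing probes whose
#' detection p exceeds `p_threshold` in strictly more than `fail_fraction` of
#' samples.
#'
#' @param truth a `reference_truth` object.
#' @param comp a `true_composition` object.
#' @param noise_sd standard deviation of additive beta-scale noise.
#' @param n_failing number of failing probes to plant (chosen among
#'   background CpGs).
#' @param fail_fraction failure fraction the planted probes must strictly
#'   exceed.
#' @param seed integer seed.
#' @param p_threshold detection p-value threshold the failures exceed.
#' @return list: `beta` (CpG x sample), `detection_p` (same shape),
#'   `failing_ids` (character vector of planted probes).
#' @export
synthesize_betas <- function(truth, comp, noise_sd = 0.02, n_failing = 0,
                             fail_fraction = 0.3, seed, p_threshold = 1e-5) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  stopifnot(inherits(truth, "reference_truth"),
            inherits(comp, "true_composition"), noise_sd >= 0)
  set.seed(seed)
  P <- truth$profiles
  W <- comp$proportions
  beta <- P %*% t(W)
  if (noise_sd > 0)
    beta <- beta + matrix(stats::rnorm(length(beta), 0, noise_sd),
                          nrow = nrow(beta))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(rownames(P), rownames(W))
  n <- ncol(beta)

  detp <- matrix(stats::runif(length(beta), 0, p_threshold * 0.1),
                 nrow = nrow(beta), dimnames = dimnames(beta))
  failing_ids <- character(0)
  if (n_failing > 0) {
    pool <- setdiff(rownames(P), c(truth$ldmr_ids, truth$surrogate_ids))
    if (n_failing > length(pool))
      stop("n_failing exceeds available background CpGs")
    failing_ids <- sort(sample(pool, n_failing))
    min_fail <- floor(fail_fraction * n) + 1L  # strictly more than the fraction
    for (cg in failing_ids) {
      k <- sample(seq.int(min_fail, n), 1L)
      cols <- sample.int(n, k)
      detp[cg, cols] <- stats::runif(k, p_threshold * 10, 1e-2)
    }
  }
  list(beta = beta, detection_p = detp, failing_ids = failing_ids)
}

#' Simulate sorted leukocyte reference samples with donor blood compositions
#'
#' Emulates a sorted-cell reference experiment: `n_per_type` donors each
#' contribute one sorted sample per cell type. A sorted sample is dominated
#' by its own cell type (purity drawn from `purity`, remainder spread over
#' the other five types). Each donor also has a whole-blood composition
#' (Dirichlet around a healthy profile), and the flow-measured blood
#' proportions attached to every sample are the donor's composition plus
#' measurement error — the adjustment covariates of the lineage model.
#'
#' @param truth a `reference_truth` object.
#' @param n_per_type donors, i.e. sorted samples per cell type.
#' @param noise_sd beta-scale measurement noise.
#' @param purity length-2 range of the own-type fraction in a sorted sample.
#' @param flow_error_sd per-type Gaussian error of the measured blood
#'   proportions.
#' @param blood_alpha Dirichlet concentration vector of the donors'
#'   whole-blood composition.
#' @param seed integer seed.
#' @return list: `beta` (CpG x sample), `cell_type`, `lineage`
#'   (myeloid/lymphoid), `donor`, `true_props` (sorted-sample composition),
#'   `measured_props` (donor blood composition with flow error, sample x 6).
#' @export
simulate_purified_samples <- function(truth, n_per_type = 9, noise_sd = 0.02,
                                      purity = c(0.85, 0.97),
                                      flow_error_sd = 0.01,
                                      blood_alpha = alpha_for_nlr(2),
                                      seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  stopifnot(inherits(truth, "reference_truth"), n_per_type >= 2)
  set.seed(seed)
  n <- 6L * n_per_type
  cell_type <- rep(LEUKOCYTE_TYPES, each = n_per_type)
  donor <- rep(seq_len(n_per_type), times = 6)
  ids <- sprintf("P%s_%02d", cell_type, donor)
  props <- matrix(0, n, 6, dimnames = list(ids, LEUKOCYTE_TYPES))
  for (i in seq_len(n)) {
    own <- stats::runif(1, purity[1], purity[2])
    rest <- rdirichlet(1, rep(1, 5)) * (1 - own)
    row <- numeric(6)
    row[match(cell_type[i], LEUKOCYTE_TYPES)] <- own
    row[-match(cell_type[i], LEUKOCYTE_TYPES)] <- rest
    props[i, ] <- row
  }
  beta <- truth$profiles %*% t(props)
  if (noise_sd > 0)
    beta <- beta + matrix(stats::rnorm(length(beta), 0, noise_sd), nrow(beta))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(rownames(truth$profiles), ids)
  blood <- rdirichlet(n_per_type, blood_alpha)
  measured <- blood[donor, , drop = FALSE] +
    matrix(stats::rnorm(n * 6, 0, flow_error_sd), n)
  measured <- pmax(measured, 0)
  measured <- measured / rowSums(measured)
  dimnames(measured) <- list(ids, LEUKOCYTE_TYPES)
  lineage <- ifelse(cell_type %in% MYELOID_TYPES, "myeloid", "lymphoid")
  list(beta = beta, cell_type = cell_type, lineage = lineage, donor = donor,
       true_props = props, measured_props = measured)
}

#' Stratified Dirichlet design for surrogate-screening cohorts
#'
#' A six-stratum ladder of target NLR values from 0.6 to 4 with increasing
#' Dirichlet concentration toward the granulocyte-rich strata, emulating the
#' spread of blood compositions from healthy-like to case-like profiles while
#' keeping the extreme-NLR tail (tiny lymphoid fractions) controlled.
#'
#' @param mono mean monocyte fraction in every stratum.
#' @return named list of six Dirichlet alpha vectors.
#' @export
screening_alpha <- function(mono = 0.12) {
  nlr <- c(0.6, 1.2, 1.8, 2.5, 3.2, 4)
  conc <- c(45, 50, 55, 60, 65, 75)
  stats::setNames(Map(function(nl, cc) alpha_for_nlr(nl, mono = mono,
                                                     concentration = cc),
                      nlr, conc),
                  paste0("stratum", seq_along(nlr)))
}

#' Simulate a blood cohort for mdNLR surrogate screening
#'
#' Draws compositions from the [screening_alpha()] ladder (equal stratum
#' sizes), mixes betas at the given noise level, deconvolves against the true
#' L-DMR library, and returns the mdNLR scores together with the cohort
#' M-value matrix — the inputs of [screen_surrogates()].
#'
#' @param truth a `reference_truth` object.
#' @param n_samples cohort size (default 300).
#' @param noise_sd beta-scale mixture noise.
#' @param seed integer seed.
#' @return list: `mdnlr` (an `mdnlr_score` data.frame), `m` (CpG x sample
#'   M-value matrix), `composition` (the `true_composition`), `beta`.
#' @export
simulate_screening_cohort <- function(truth, n_samples = 300, noise_sd = 0.02,
                                      seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  alph <- screening_alpha()
  strata <- rep(names(alph), length.out = n_samples)
  comp <- sample_compositions(n_samples, alph, strata = strata, seed = seed)
  mix <- synthesize_betas(truth, comp, noise_sd = noise_sd, seed = seed + 1L)
  lib <- truth$profiles[truth$ldmr_ids, , drop = FALSE]
  props <- estimate_proportions(mix$beta, lib)
  score <- compute_mdnlr(props)
  list(mdnlr = score, m = beta_to_m(mix$beta), composition = comp,
       beta = mix$beta)
}

#' Simulate a cohort spanning the clinically relevant NLR range
#'
#' Draws a 50-sample-scale cohort whose true NLR ladder runs from about 0.5
#' to 12 (six strata, Dirichlet concentration increasing with the target NLR
#' so extreme ratios stay bounded; lymphoid floor 0.05), mixes betas, and
#' deconvolves against the true L-DMR library. This is the benchmark cohort
#' for fraction-recovery and mdNLR-fidelity checks.
#'
#' @param truth a `reference_truth` object.
#' @param n_samples cohort size (default 50).
#' @param noise_sd beta-scale mixture noise.
#' @param seed integer seed.
#' @return list: `composition`, `beta`, `props` (a `cell_props`), `mdnlr`
#'   (an `mdnlr_score`).
#' @export
simulate_fidelity_cohort <- function(truth, n_samples = 50, noise_sd = 0.02,
                                     seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  ladder <- c(0.7, 1.5, 2.5, 4, 7, 11)
  conc <- c(25, 30, 35, 50, 90, 150)
  alph <- stats::setNames(Map(function(nl, cc)
    alpha_for_nlr(nl, concentration = cc), ladder, conc),
    paste0("s", seq_along(ladder)))
  strata <- rep(names(alph), length.out = n_samples)
  comp <- sample_compositions(n_samples, alph, strata = strata, seed = seed,
                              lymphoid_floor = 0.05)
  mix <- synthesize_betas(truth, comp, noise_sd = noise_sd, seed = seed + 1L)
  props <- estimate_proportions(mix$beta,
                                truth$profiles[truth$ldmr_ids, , drop = FALSE])
  list(composition = comp, beta = mix$beta, props = props,
       mdnlr = compute_mdnlr(props))
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with hazard `exp(lp) / baseline_scale`, where
#' the linear predictor sums planted log hazard ratios over covariate columns.
#' Censoring is independent exponential, calibrated so the expected censored
#' fraction matches `censor_rate`.
#'
#' @param covariates data.frame of numeric (or 0/1) covariate columns.
#' @param log_hrs named numeric vector of planted log hazard ratios; names
#'   must be columns of `covariates`.
#' @param baseline_scale mean baseline survival time in months (median is
#'   `baseline_scale * log(2)`).
#' @param censor_rate target fraction of censored records, in \[0, 1).
#' @param seed integer seed.
#' @return data.frame with columns `time` (months) and `event` (0/1).
#' @export
simulate_survival <- function(covariates, log_hrs, baseline_scale = 80,
                              censor_rate = 0.4, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  stopifnot(baseline_scale > 0, censor_rate >= 0, censor_rate < 1)
  if (length(log_hrs) && !all(names(log_hrs) %in% names(covariates)))
    stop("log_hrs names must match covariate columns")
  set.seed(seed)
  n <- nrow(covariates)
  lp <- if (length(log_hrs)) {
    as.matrix(covariates[, names(log_hrs), drop = FALSE]) %*% log_hrs
  } else rep(0, n)
  rate <- exp(drop(lp)) / baseline_scale
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    mu <- censor_rate / (1 - censor_rate) * mean(rate)
    t_cens <- stats::rexp(n, mu)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  } else {
    data.frame(time = t_event, event = rep(1L, n))
  }
}

#' Simulate a complete synthetic glioma blood-methylation cohort
#'
#' End-to-end generator combining reference profiles, Dirichlet compositions
#' (grade-IV samples shifted toward granulocytes), mixture betas with planted
#' failing probes, clinical covariates, and proportional-hazards survival with
#' planted effects for the high-NLR group and TERT-only mutation.
#'
#' @param n_samples cohort size.
#' @param n_cpgs CpG universe size.
#' @param n_ldmr_per_type,n_surrogates see [generate_reference_profiles()].
#' @param noise_sd beta-scale mixture noise.
#' @param n_failing,fail_fraction planted failing probes, see
#'   [synthesize_betas()].
#' @param nlr_control,nlr_case mean NLR targeted in non-GBM / GBM strata.
#' @param concentration Dirichlet concentration for compositions.
#' @param log_hr_nlr planted log hazard ratio of the high-NLR group.
#' @param log_hr_tert planted log hazard ratio of TERT-only mutation.
#' @param baseline_scale,censor_rate see [simulate_survival()].
#' @param cutpoint NLR threshold defining the true high group.
#' @param seed integer seed.
#' @return list of class `synthetic_cohort` with `beta`, `detection_p`,
#'   `covariates` (sample_id, age, sex, grade, mutation, time, event), and
#'   `truth` (reference, composition, true NLR group, planted log-HRs,
#'   failing probe ids).
#' @export
simulate_cohort <- function(n_samples, n_cpgs = 1000, n_ldmr_per_type = 50,
                            n_surrogates = 5, noise_sd = 0.02, n_failing = 20,
                            fail_fraction = 0.3, nlr_control = 2,
                            nlr_case = 4.5, concentration = 22,
                            log_hr_nlr = log(2),
                            log_hr_tert = log(4.5), baseline_scale = 80,
                            censor_rate = 0.4, cutpoint = 4, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 4)

  truth <- generate_reference_profiles(n_cpgs, n_ldmr_per_type, n_surrogates,
                                       seed = sub_seeds[1])
  set.seed(seed)  # covariate draws
  age <- sample(40:59, n_samples, replace = TRUE)
  sex <- sample(c("M", "F"), n_samples, replace = TRUE, prob = c(0.72, 0.28))
  grade <- sample(c("GBM", "non-GBM"), n_samples, replace = TRUE,
                  prob = c(0.46, 0.54))
  mutation <- sample(c("TERT-only", "IDH-only"), n_samples, replace = TRUE,
                     prob = c(0.58, 0.42))

  alpha <- list("GBM" = alpha_for_nlr(nlr_case, concentration = concentration),
                "non-GBM" = alpha_for_nlr(nlr_control, concentration = concentration))
  comp <- sample_compositions(n_samples, alpha, strata = grade,
                              seed = sub_seeds[2])
  mix <- synthesize_betas(truth, comp, noise_sd = noise_sd,
                          n_failing = n_failing, fail_fraction = fail_fraction,
                          seed = sub_seeds[3])
  true_high <- as.integer(comp$true_nlr >= cutpoint)

  sim_cov <- data.frame(nlr_high = true_high,
                        tert = as.integer(mutation == "TERT-only"),
                        age_c = age - mean(age),
                        male = as.integer(sex == "M"),
                        gbm = as.integer(grade == "GBM"))
  log_hrs <- c(nlr_high = log_hr_nlr, tert = log_hr_tert)
  surv <- simulate_survival(sim_cov, log_hrs, baseline_scale = baseline_scale,
                            censor_rate = censor_rate, seed = sub_seeds[4])

  covariates <- data.frame(sample_id = comp$sample_ids, age = age, sex = sex,
                           grade = grade, mutation = mutation,
                           time = surv$time, event = surv$event,
                           stringsAsFactors = FALSE)
  structure(list(
    beta = mix$beta, detection_p = mix$detection_p, covariates = covariates,
    truth = list(reference = truth, composition = comp,
                 true_high = stats::setNames(true_high, comp$sample_ids),
                 log_hrs = log_hrs, failing_ids = mix$failing_ids,
                 cutpoint = cutpoint, seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.reference_truth <- function(x, ...) {
  cat(sprintf("Synthetic leukocyte reference: %d CpGs x %d cell types\n",
              nrow(x$profiles), length(x$cell_types)))
  cat(sprintf("  L-DMRs: %d  surrogates: %d  seed: %d\n",
              length(x$ldmr_ids), length(x$surrogate_ids), x$seed))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d CpGs (%d events)\n",
              ncol(x$beta), nrow(x$beta), sum(x$covariates$event)))
  invisible(x)
}
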