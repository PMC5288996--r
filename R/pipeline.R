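#' Summarize a cohort in the style of a patient-characteristics table
#'
#' @param records data.frame with columns age, sex, grade, mutation, time,
#'   event and mdnlr_group (factor low/high).
#' @param cutpoint mdNLR cut point used for the group labels (display only).
#' @return named list: n, median age (IQR), percent male, percent GBM,
#'   percent TERT-only, percent high mdNLR, follow-up range, median (IQR)
#'   survival. Percentages are rounded to whole numbers, medians to 2
#'   decimals.
#' @export
summarize_cohort <- function(records, cutpoint = 4) {
  stopifnot(nrow(records) >= 1)
  pct <- function(x) round(100 * mean(x))
  med_iqr <- function(x) round(stats::quantile(x, c(0.5, 0.25, 0.75),
                                               names = FALSE), 2)
  age <- med_iqr(records$age)
  km <- kaplan_meier(records)
  surv_med <- unname(km$median)
  list(n = nrow(records),
       age_median = age[1], age_q25 = age[2], age_q75 = age[3],
       pct_male = pct(records$sex == "M"),
       pct_gbm = pct(records$grade == "GBM"),
       pct_tert = pct(records$mutation == "TERT-only"),
       pct_mdnlr_high = pct(records$mdnlr_group == "high"),
       mdnlr_cutpoint = cutpoint,
       followup_min = round(min(records$time), 2),
       followup_max = round(max(records$time), 2),
       survival_median = round(surv_med, 2),
       n_events = sum(records$event))
}

# numeric encodings used by the survival models
encode_records <- function(covariates, mdnlr_group) {
  data.frame(sample_id = covariates$sample_id,
             time = covariates$time, event = covariates$event,
             age = covariates$age,
             male = as.integer(covariates$sex == "M"),
             gbm = as.integer(covariates$grade == "GBM"),
             tert = as.integer(covariates$mutation == "TERT-only"),
             mdnlr_high = as.integer(mdnlr_group == "high"),
             stringsAsFactors = FALSE)
}

#' Default pipeline configuration (synthetic mode)
#'
#' @param n_samples cohort size.
#' @param seed integer seed driving every random stage.
#' @param out_dir output directory.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(n_samples = 200, seed = 1, out_dir = tempfile("mdnlr_run_")) {
  list(
    synthetic = list(n_samples = n_samples, n_cpgs = 1000,
                     n_ldmr_per_type = 50, n_surrogates = 5,
                     noise_sd = 0.02, n_failing = 20, fail_fraction = 0.3,
                     seed = seed),
    qc = list(p_threshold = 1e-5, sample_fraction = 0.25),
    library = list(n_per_type = 50, n_purified_per_type = 9),
    mdnlr = list(cutpoint = 4, strict = FALSE, floor = 1e-4,
                 normalize = FALSE),
    surrogates = list(top_k = 100, threshold = 0.80, degrees = 1:3),
    out_dir = out_dir
  )
}

log_stage <- function(lines, stage, detail, seed = NA) {
  c(lines, sprintf("stage=%s\t%s\tseed=%s", stage, detail, seed))
}

#' Run the full immunomethylomic analysis pipeline
#'
#' Sequences synthetic-cohort generation (or delimited-file input), detection
#' p-value QC, reference-library selection, constrained-projection
#' deconvolution, mdNLR scoring and dichotomization, myeloid surrogate
#' screening, and Cox survival modelling with performance metrics. All
#' intermediate tables are written to `config$out_dir`; the same config and
#' seed reproduce byte-identical outputs.
#'
#' @param config nested list as produced by [default_config()], or a path to
#'   a YAML file with the same structure. Exactly one of `synthetic` (the
#'   generator block) or `paths` (beta / detection_p / reference /
#'   covariates CSV paths) must be present.
#' @return list of class `run_report`: cohort summary, deconvolution
#'   summary, mdNLR distribution by group, surrogate table, survival tables,
#'   and provenance (seed, parameters).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_syn <- !is.null(config$synthetic)
  has_paths <- !is.null(config$paths)
  if (has_syn == has_paths)
    stop("config must contain exactly one of 'synthetic' or 'paths'")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character(0)

  ## stage 1: inputs -------------------------------------------------------
  if (has_syn) {
    syn <- config$synthetic
    if (is.null(syn$seed)) stop("synthetic mode requires a seed")
    cohort <- do.call(simulate_cohort, syn)
    beta <- cohort$beta; detp <- cohort$detection_p
    covariates <- cohort$covariates
    truth <- cohort$truth
    write_matrix_csv(round(beta, 6), file.path(out_dir, "beta.csv"))
    write_matrix_csv(signif(detp, 6), file.path(out_dir, "detection_p.csv"))
    write_tsv(covariates, file.path(out_dir, "covariates.tsv"))
    set.seed(truth$seed + 1L)
    pur <- simulate_purified_samples(truth$reference,
                                     n_per_type = config$library$n_purified_per_type,
                                     seed = truth$seed + 1L)
    lines <- log_stage(lines, "synthetic",
                       sprintf("n=%d cpgs=%d", ncol(beta), nrow(beta)),
                       syn$seed)
  } else {
    p <- config$paths
    beta <- read_matrix_csv(p$beta)
    detp <- if (!is.null(p$detection_p)) read_matrix_csv(p$detection_p)
    covariates <- read_tsv(p$covariates)
    truth <- NULL
    pur <- NULL
    lines <- log_stage(lines, "input",
                       sprintf("n=%d cpgs=%d", ncol(beta), nrow(beta)))
  }

  ## stage 2: QC -----------------------------------------------------------
  if (!is.null(detp)) {
    qc <- filter_detection_p(beta, detp, config$qc$p_threshold,
                             config$qc$sample_fraction)
    beta <- qc$beta
    write_tsv(qc$log, file.path(out_dir, "qc_removal_log.tsv"))
    lines <- log_stage(lines, "qc",
                       sprintf("removed=%d kept=%d", sum(qc$log$removed),
                               nrow(beta)))
  }

  ## stage 3: reference library -------------------------------------------
  if (!is.null(pur)) {
    lib <- select_reference_library(pur$beta, pur$cell_type,
                                    n_per_type = config$library$n_per_type)
  } else {
    lib_mat <- read_matrix_csv(config$paths$reference)
    lib <- structure(list(cpg_ids = rownames(lib_mat),
                          cell_types = colnames(lib_mat), design = lib_mat),
                     class = "ref_library")
  }
  write_matrix_csv(round(lib$design, 6), file.path(out_dir, "reference_library.csv"))
  lines <- log_stage(lines, "library", sprintf("cpgs=%d", nrow(lib$design)))

  ## stage 4: deconvolution + mdNLR ---------------------------------------
  props <- estimate_proportions(beta, lib, normalize = config$mdnlr$normalize)
  score <- compute_mdnlr(props, floor = config$mdnlr$floor)
  group <- dichotomize_mdnlr(score, cutpoint = config$mdnlr$cutpoint,
                             strict = config$mdnlr$strict)
  prop_df <- data.frame(sample_id = rownames(props$proportions),
                        props$proportions,
                        residual_norm = props$residual_norm,
                        row.names = NULL, check.names = FALSE)
  prop_df[-1] <- lapply(prop_df[-1], round, 6)
  write_tsv(prop_df, file.path(out_dir, "cell_proportions.tsv"))
  mdnlr_df <- data.frame(sample_id = score$sample_id,
                         mdnlr = round(score$mdnlr, 6),
                         floored = score$floored, group = as.character(group),
                         stringsAsFactors = FALSE)
  write_tsv(mdnlr_df, file.path(out_dir, "mdnlr.tsv"))
  lines <- log_stage(lines, "deconvolution",
                     sprintf("high=%d low=%d", sum(group == "high"),
                             sum(group == "low")))

  ## stage 5: myeloid surrogate screen ------------------------------------
  surrogate_tab <- NULL
  if (!is.null(pur)) {
    stats_tab <- fit_lineage_model(beta_to_m(pur$beta), pur$lineage,
                                   pur$measured_props)
    top <- select_top_loci(stats_tab, k = min(config$surrogates$top_k,
                                              nrow(stats_tab)))
    m_cohort <- beta_to_m(beta)
    screen <- screen_surrogates(score, m_cohort,
                                loci = intersect(top, rownames(m_cohort)),
                                degrees = config$surrogates$degrees)
    screen$selected <- is.finite(screen$best_adj_r2) &
      screen$best_adj_r2 >= config$surrogates$threshold
    surrogate_tab <- screen[order(-screen$best_adj_r2), ]
    out_tab <- surrogate_tab
    num <- vapply(out_tab, is.numeric, TRUE)
    out_tab[num] <- lapply(out_tab[num], round, 6)
    write_tsv(out_tab, file.path(out_dir, "surrogate_screen.tsv"))
    write_tsv(data.frame(stats_tab, row.names = NULL),
              file.path(out_dir, "lineage_stats.tsv"))
    # per-locus medians (percent beta) by mdNLR group, Mann-Whitney tested
    show <- utils::head(surrogate_tab$cpg_id, 10)
    if (length(show) && nlevels(droplevels(group)) == 2 &&
        all(table(group) >= 2)) {
      grp_tab <- compare_groups_by_locus(beta[show, , drop = FALSE], group)
      grp_num <- vapply(grp_tab, is.numeric, TRUE)
      grp_tab[grp_num] <- lapply(grp_tab[grp_num], round, 6)
      write_tsv(grp_tab, file.path(out_dir, "locus_group_summary.tsv"))
    }
    lines <- log_stage(lines, "surrogates",
                       sprintf("screened=%d selected=%d", nrow(screen),
                               sum(screen$selected)))
  }

  ## stage 6: survival -----------------------------------------------------
  records <- encode_records(covariates, group)
  baseline_cov <- c("age", "male", "gbm", "tert")
  fit_base <- fit_cox(records, baseline_cov)
  fit_full <- fit_cox(records, c(baseline_cov, "mdnlr_high"))
  lr <- likelihood_ratio_test(fit_full, fit_base)
  eval_times <- stats::quantile(records$time[records$event == 1],
                                seq(0.1, 0.9, by = 0.1), names = FALSE)
  perf <- data.frame(
    model = c("baseline", "baseline+mdNLR"),
    c_index = c(concordance_index(fit_base)$c_index,
                concordance_index(fit_full)$c_index),
    brier_integrated = c(brier_score(fit_base, eval_times = eval_times)$integrated,
                         brier_score(fit_full, eval_times = eval_times)$integrated),
    tauroc = c(time_dependent_auroc(fit_base, eval_times = eval_times)$summary,
               time_dependent_auroc(fit_full, eval_times = eval_times)$summary),
    lr_p_vs_baseline = c(NA, lr$p), stringsAsFactors = FALSE)
  perf[-1] <- lapply(perf[-1], round, 6)
  cox_tab <- rbind(cbind(model = "baseline", fit_base$table),
                   cbind(model = "baseline+mdNLR", fit_full$table))
  cox_tab[-(1:2)] <- lapply(cox_tab[-(1:2)], round, 6)
  write_tsv(cox_tab, file.path(out_dir, "cox_models.tsv"))
  write_tsv(perf, file.path(out_dir, "model_performance.tsv"))
  records$mdnlr_group <- group
  km <- kaplan_meier(records, group_by = "mdnlr_group")
  km_curves <- km$curves
  km_curves$surv <- round(km_curves$surv, 6)
  km_curves$time <- round(km_curves$time, 6)
  write_tsv(km_curves, file.path(out_dir, "km_curves.tsv"))
  lines <- log_stage(lines, "survival",
                     sprintf("events=%d lr_p=%.4g", fit_base$n_events, lr$p))

  ## report ---------------------------------------------------------------
  records2 <- cbind(covariates, mdnlr_group = group)
  report <- structure(list(
    cohort_summary = summarize_cohort(records2, config$mdnlr$cutpoint),
    deconvolution = list(n_cpgs_used = props$n_cpgs_used,
                         mean_residual = round(mean(props$residual_norm), 6)),
    mdnlr_by_group = list(
      median_high = round(stats::median(score$mdnlr[group == "high"]), 4),
      median_low = round(stats::median(score$mdnlr[group == "low"]), 4),
      n_high = sum(group == "high"), n_low = sum(group == "low")),
    surrogates = surrogate_tab,
    cox = cox_tab, performance = perf,
    km_median = km$median, logrank_p = km$logrank_p,
    provenance = list(seed = if (has_syn) config$synthetic$seed else NA,
                      package_version = as.character(utils::packageVersion("mdnlr")))
  ), class = "run_report")
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  yaml::write_yaml(report[c("cohort_summary", "deconvolution",
                            "mdnlr_by_group", "km_median", "logrank_p",
                            "provenance")],
                   file.path(out_dir, "report.yaml"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("Cohort: n=%d, %d events, median survival %.1f months\n",
              cs$n, cs$n_events, cs$survival_median))
  cat(sprintf("mdNLR >= %.1f: %d%% of samples\n", cs$mdnlr_cutpoint,
              cs$pct_mdnlr_high))
  cat("\nModel performance:\n")
  print(x$performance, digits = 3)
  invisible(x)
}
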