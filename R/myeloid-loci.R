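#' Per-CpG myeloid-vs-lymphoid lineage model on purified samples
#'
#' For every CpG, fits ordinary least squares of the M value on a myeloid
#' lineage indicator plus the measured cell proportions (one proportion
#' column, the last by cell-type order, is dropped to avoid sum-to-one
#' collinearity). Returns the lineage coefficient (myeloid minus lymphoid),
#' its t statistic, and the rank by |t| (ties broken by CpG id).
#'
#' @param purified_m CpG x sample matrix of M values.
#' @param lineage character vector per sample, values `myeloid`/`lymphoid`.
#' @param measured_props sample x cell-type matrix of measured proportions.
#' @return data.frame of class `lineage_stats`: cpg_id, lineage_coef,
#'   t_stat, rank.
#' @export
fit_lineage_model <- function(purified_m, lineage, measured_props) {
  stopifnot(is.matrix(purified_m))
  lineage <- as.character(lineage)
  if (length(lineage) != ncol(purified_m))
    stop("lineage length must equal ncol(purified_m)")
  if (!all(lineage %in% c("myeloid", "lymphoid")))
    stop("lineage values must be 'myeloid' or 'lymphoid'")
  cnt <- table(factor(lineage, levels = c("myeloid", "lymphoid")))
  if (any(cnt < 3))
    stop("need >= 3 samples per lineage")
  measured_props <- as.matrix(measured_props)
  if (nrow(measured_props) != ncol(purified_m))
    stop("measured_props rows must align with purified_m samples")

  keep <- seq_len(ncol(measured_props) - 1L)  # drop last column (collinearity)
  D <- cbind(intercept = 1, myeloid = as.numeric(lineage == "myeloid"),
             measured_props[, keep, drop = FALSE])
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop("collinear covariates after drop: ", paste(bad, collapse = ", "))
  }
  Y <- t(purified_m)                       # samples x CpGs
  coefs <- qr.coef(qrD, Y)                 # p x CpGs
  resid <- qr.resid(qrD, Y)
  df <- nrow(D) - ncol(D)
  sigma2 <- colSums(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qrD))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  t_stat <- coefs["myeloid", ] / se
  ids <- rownames(purified_m)
  ord <- order(-abs(t_stat), ids)
  rank <- integer(length(ids)); rank[ord] <- seq_along(ids)
  out <- data.frame(cpg_id = ids, lineage_coef = unname(coefs["myeloid", ]),
                    t_stat = unname(t_stat), rank = rank, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("lineage_stats", "data.frame")
  out
}

#' Select the top lineage-discriminating loci
#'
#' Deterministic top-k by |t| descending, ties broken by lexicographically
#' smaller CpG id. The fixed k (default 100) stands in for automatic rank
#' cutoff selection.
#'
#' @param stats a `lineage_stats` data.frame from [fit_lineage_model()].
#' @param k number of loci to keep (default 100).
#' @return character vector of k CpG ids, in rank order.
#' @export
select_top_loci <- function(stats, k = 100) {
  stopifnot(k <= nrow(stats))
  ord <- order(-abs(stats$t_stat), stats$cpg_id)
  stats$cpg_id[ord][seq_len(k)]
}

#' Polynomial surrogate fit of the mdNLR on a single locus
#'
#' Regresses the mdNLR on raw powers (up to cubic) of the locus M value and
#' reports the adjusted R-squared per degree; the best degree is the one with
#' the highest adjusted R-squared.
#'
#' @param mdnlr numeric vector of mdNLR scores (or an `mdnlr_score`
#'   data.frame).
#' @param locus_m numeric vector of the locus M values, same samples.
#' @param degrees subset of 1:3 to evaluate (default all three).
#' @return list of class `surrogate_fit`: `adj_r2` (named by degree),
#'   `best_degree`, `best_adj_r2`, `coefficients` (of the best fit),
#'   `degenerate` (TRUE for a constant locus), `n`.
#' @export
fit_mdnlr_surrogate <- function(mdnlr, locus_m, degrees = 1:3) {
  if (inherits(mdnlr, "data.frame")) mdnlr <- mdnlr$mdnlr
  stopifnot(all(degrees %in% 1:3), length(degrees) >= 1)
  degrees <- sort(unique(degrees))
  n <- length(locus_m)
  if (length(mdnlr) != n) stop("mdnlr and locus_m lengths differ")
  if (any(!is.finite(mdnlr)) || any(!is.finite(locus_m)))
    stop("inputs must be finite")
  if (n < max(degrees) + 2) stop("need at least degree + 2 samples")
  if (stats::sd(locus_m) == 0) {
    return(structure(list(adj_r2 = stats::setNames(rep(NA_real_, length(degrees)),
                                                   degrees),
                          best_degree = NA_integer_, best_adj_r2 = NA_real_,
                          coefficients = NULL, degenerate = TRUE, n = n),
                     class = "surrogate_fit"))
  }
  tss <- sum((mdnlr - mean(mdnlr))^2)
  adj <- stats::setNames(numeric(length(degrees)), degrees)
  coefs <- vector("list", length(degrees))
  for (i in seq_along(degrees)) {
    d <- degrees[i]
    X <- cbind(1, outer(locus_m, seq_len(d), `^`))
    if (d > 1 && kappa(X) > 1e8)
      warning(sprintf("raw polynomial basis ill-conditioned (degree %d)", d))
    fit <- stats::lm.fit(X, mdnlr)
    r2 <- 1 - sum(fit$residuals^2) / tss
    adj[i] <- 1 - (1 - r2) * (n - 1) / (n - d - 1)
    coefs[[i]] <- fit$coefficients
  }
  best <- which.max(adj)
  structure(list(adj_r2 = adj, best_degree = degrees[best],
                 best_adj_r2 = unname(adj[best]),
                 coefficients = coefs[[best]], degenerate = FALSE, n = n),
            class = "surrogate_fit")
}

#' Screen candidate loci as polynomial surrogates of the mdNLR
#'
#' Applies [fit_mdnlr_surrogate()] to each requested locus of an M-value
#' matrix and collects the per-degree adjusted R-squared.
#'
#' @param mdnlr mdNLR scores (vector or `mdnlr_score` data.frame), one per
#'   sample (columns of `m_matrix`).
#' @param m_matrix CpG x sample matrix of M values.
#' @param loci CpG ids to screen (default: all rows).
#' @param degrees polynomial degrees evaluated.
#' @return data.frame: cpg_id, best_degree, best_adj_r2, adj_r2_1..3 (NA for
#'   unevaluated degrees), degenerate.
#' @export
screen_surrogates <- function(mdnlr, m_matrix, loci = rownames(m_matrix),
                              degrees = 1:3) {
  loci <- intersect(loci, rownames(m_matrix))
  res <- lapply(loci, function(cg)
    fit_mdnlr_surrogate(mdnlr, m_matrix[cg, ], degrees))
  grab <- function(f, d) if (d %in% names(f$adj_r2)) f$adj_r2[[as.character(d)]] else NA_real_
  data.frame(cpg_id = loci,
             best_degree = vapply(res, function(f) as.integer(f$best_degree), 1L),
             best_adj_r2 = vapply(res, function(f) f$best_adj_r2, 1),
             adj_r2_1 = vapply(res, grab, 1, d = 1),
             adj_r2_2 = vapply(res, grab, 1, d = 2),
             adj_r2_3 = vapply(res, grab, 1, d = 3),
             degenerate = vapply(res, function(f) f$degenerate, TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select loci that are consistent surrogates across datasets
#'
#' Keeps loci whose best-degree adjusted R-squared meets `threshold` in every
#' supplied dataset; loci absent from any dataset are excluded (and logged as
#' an attribute). Results are ordered by mean adjusted R-squared, descending.
#'
#' @param results list of screening data.frames from [screen_surrogates()],
#'   one per dataset.
#' @param threshold adjusted R-squared cutoff (default 0.80).
#' @return character vector of CpG ids; attribute `excluded` lists loci
#'   missing from at least one dataset.
#' @export
select_consistent_surrogates <- function(results, threshold = 0.80) {
  stopifnot(is.list(results), length(results) >= 1)
  all_ids <- unique(unlist(lapply(results, `[[`, "cpg_id")))
  present <- Reduce(intersect, lapply(results, `[[`, "cpg_id"))
  excluded <- setdiff(all_ids, present)
  if (!length(present)) return(structure(character(0), excluded = excluded))
  r2 <- vapply(results, function(df) {
    stats::setNames(df$best_adj_r2, df$cpg_id)[present]
  }, numeric(length(present)))
  r2 <- matrix(r2, nrow = length(present))
  pass <- apply(r2, 1, function(x) all(is.finite(x) & x >= threshold))
  sel <- present[pass]
  sel <- sel[order(-rowMeans(r2)[pass])]
  structure(sel, excluded = excluded)
}

#' Compare locus methylation between two sample groups (Mann-Whitney)
#'
#' Per CpG, reports the median and IQR of beta values on the percentage scale
#' (beta x 100) in each group and a two-sided Mann-Whitney U test p-value
#' (exact when both groups have at most 20 samples and no ties).
#'
#' @param beta CpG x sample beta matrix.
#' @param groups two-level factor/character vector per sample.
#' @return data.frame: cpg_id, median/q25/q75 per group (percent scale),
#'   U statistic, p_value.
#' @export
compare_groups_by_locus <- function(beta, groups) {
  stopifnot(is.matrix(beta))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  exact <- sum(i1) <= 20 && sum(i2) <= 20
  one <- function(x) {
    a <- 100 * x[i1]; b <- 100 * x[i2]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
    c(stats::median(a), stats::quantile(a, c(0.25, 0.75), names = FALSE),
      stats::median(b), stats::quantile(b, c(0.25, 0.75), names = FALSE),
      unname(wt$statistic), wt$p.value)
  }
  res <- t(apply(beta, 1, one))
  out <- data.frame(cpg_id = rownames(beta), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out) <- c("cpg_id",
                  paste0(g1, c("_median", "_q25", "_q75")),
                  paste0(g2, c("_median", "_q25", "_q75")),
                  "U", "p_value")
  out
}
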