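#' Remove CpGs with a sizable fraction of failed detection p-values
#'
#' Drops every CpG for which the fraction of samples with detection
#' p > `p_threshold` strictly exceeds `sample_fraction` (a probe failing in
#' exactly 25\% of samples is retained under the defaults). Row and column
#' order of the survivors is preserved.
#'
#' @param beta CpG x sample matrix of beta values in \[0,1\] with rownames.
#' @param detection_p matched matrix of detection p-values (same dimnames).
#' @param p_threshold detection p-value above which a measurement counts as
#'   failed (default 1e-5).
#' @param sample_fraction failure fraction a probe must strictly exceed to be
#'   removed (default 0.25).
#' @return list: `beta` and `detection_p` (filtered), `log` (data.frame with
#'   cpg_id, failure_fraction, removed).
#' @export
filter_detection_p <- function(beta, detection_p, p_threshold = 1e-5,
                               sample_fraction = 0.25) {
  if (missing(detection_p) || is.null(detection_p))
    stop("detection_p is required; to skip QC, omit filter_detection_p explicitly")
  stopifnot(is.matrix(beta), is.matrix(detection_p))
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(dimnames(beta), dimnames(detection_p)))
    stop("beta and detection_p must have identical shape and dimnames")
  stopifnot(p_threshold > 0, p_threshold < 1,
            sample_fraction > 0, sample_fraction < 1)
  frac <- rowMeans(detection_p > p_threshold)
  removed <- frac > sample_fraction
  keep <- which(!removed)
  if (anyNA(beta[keep, , drop = FALSE]))
    stop("NA beta values in retained rows; imputation is not supported")
  list(beta = beta[keep, , drop = FALSE],
       detection_p = detection_p[keep, , drop = FALSE],
       log = data.frame(cpg_id = rownames(beta), failure_fraction = frac,
                        removed = removed, row.names = NULL,
                        stringsAsFactors = FALSE))
}

#' Convert beta values to M values
#'
#' Variance-stabilizing logit transform `M = log2(b / (1 - b))` after clipping
#' beta into `[epsilon, 1 - epsilon]` so the result is always finite.
#'
#' @param beta numeric vector or matrix of beta values in \[0,1\].
#' @param epsilon clip bound in (0, 0.5); default 1e-3.
#' @return M values, same shape as input.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Exact inverse of the unclipped logit: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m numeric vector or matrix of finite M values.
#' @return beta values in (0, 1), same shape as input.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("m values must be finite")
  p <- 2^m
  p / (1 + p)
}
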