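#' Select an L-DMR reference library from purified leukocyte samples
#'
#' For each cell type, ranks CpGs by the magnitude of the one-vs-rest
#' two-sample t-statistic on M values and keeps the top `n_per_type`, split
#' evenly between hyper- and hypomethylated markers when both directions are
#' available. The design matrix holds the per-cell-type mean beta of the
#' union of selected CpGs. This is a transparent stand-in for optimized
#' library searches such as IDOL.
#'
#' @param purified_beta CpG x sample beta matrix of sorted-cell samples.
#' @param cell_labels cell type per sample (length = ncol).
#' @param n_per_type CpGs selected per cell type (default 50, i.e. a
#'   300-CpG library over six types).
#' @param epsilon clip bound for the M-value transform.
#' @return list of class `ref_library`: `cpg_ids`, `cell_types`,
#'   `design` (L-DMR x cell-type mean beta matrix), `selected_by_type`.
#' @export
select_reference_library <- function(purified_beta, cell_labels,
                                     n_per_type = 50, epsilon = 1e-3) {
  stopifnot(is.matrix(purified_beta), n_per_type >= 1)
  cell_labels <- as.character(cell_labels)
  if (length(cell_labels) != ncol(purified_beta))
    stop("cell_labels length must equal ncol(purified_beta)")
  types <- unique(cell_labels)
  counts <- table(cell_labels)
  if (any(counts < 2))
    stop("need >= 2 purified samples per cell type; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (n_per_type > nrow(purified_beta))
    stop("n_per_type exceeds the number of available CpGs")

  M <- beta_to_m(purified_beta, epsilon)
  selected <- list()
  for (ty in types) {
    in_ty <- cell_labels == ty
    t_stat <- row_t_stat(M, in_ty)
    n_hyper <- ceiling(n_per_type / 2)
    ord <- order(-abs(t_stat), rownames(M))  # ties broken by id
    pos <- ord[t_stat[ord] > 0]
    neg <- ord[t_stat[ord] < 0]
    take_pos <- utils::head(pos, n_hyper)
    take_neg <- utils::head(neg, n_per_type - length(take_pos))
    take <- c(take_pos, take_neg)
    if (length(take) < n_per_type)  # one direction exhausted: fill from the other
      take <- utils::head(ord, n_per_type)
    selected[[ty]] <- rownames(M)[take]
  }
  cpgs <- sort(unique(unlist(selected)))
  design <- vapply(types, function(ty) {
    rowMeans(purified_beta[cpgs, cell_labels == ty, drop = FALSE])
  }, numeric(length(cpgs)))
  dimnames(design) <- list(cpgs, types)
  structure(list(cpg_ids = cpgs, cell_types = types, design = design,
                 selected_by_type = selected),
            class = "ref_library")
}

# one-vs-rest Welch t statistic per row (group mean difference / pooled SE)
row_t_stat <- function(M, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  m1 <- rowMeans(M[, in_group, drop = FALSE])
  m2 <- rowMeans(M[, !in_group, drop = FALSE])
  v1 <- rowSums((M[, in_group, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((M[, !in_group, drop = FALSE] - m2)^2) / (n2 - 1)
  (m1 - m2) / sqrt(v1 / n1 + v2 / n2 + 1e-300)
}

as_design_matrix <- function(library) {
  if (inherits(library, "ref_library")) library$design
  else if (is.matrix(library)) library
  else stop("library must be a ref_library or a CpG x cell-type matrix")
}

#' Estimate leukocyte proportions by constrained projection
#'
#' For each sample, solves `min ||y - X w||^2` subject to `w >= 0` and
#' `sum(w) <= 1`, where `X` is the reference design matrix restricted to the
#' CpGs shared (by id) between the sample matrix and the library. Optionally
#' rescales each row to the unit simplex.
#'
#' @param beta CpG x sample beta matrix (rownames = CpG ids).
#' @param library a `ref_library` or a CpG x cell-type design matrix.
#' @param normalize if TRUE, rows with positive sum are rescaled to sum to 1.
#' @param min_overlap minimum fraction of library CpGs that must be present
#'   in `beta` (default 0.5).
#' @param tol solver convergence tolerance.
#' @return list of class `cell_props`: `proportions` (sample x cell-type
#'   matrix), `residual_norm` (per sample), `normalized`, `n_cpgs_used`.
#' @export
estimate_proportions <- function(beta, library, normalize = FALSE,
                                 min_overlap = 0.5, tol = 1e-9) {
  X_full <- as_design_matrix(library)
  common <- intersect(rownames(X_full), rownames(beta))
  if (length(common) < min_overlap * nrow(X_full))
    stop(sprintf("only %d of %d library CpGs present in beta (< %.0f%% overlap)",
                 length(common), nrow(X_full), 100 * min_overlap))
  X <- X_full[common, , drop = FALSE]
  Y <- beta[common, , drop = FALSE]
  n <- ncol(Y)
  omega <- matrix(0, n, ncol(X),
                  dimnames = list(colnames(Y), colnames(X)))
  resid_norm <- numeric(n)
  for (i in seq_len(n)) {
    w <- solve_proportions(X, Y[, i], tol = tol)
    resid_norm[i] <- sqrt(sum((Y[, i] - X %*% w)^2))
    omega[i, ] <- w
  }
  if (normalize) {
    rs <- rowSums(omega)
    pos <- rs > 0
    omega[pos, ] <- omega[pos, , drop = FALSE] / rs[pos]
    if (any(!pos))
      warning(sum(!pos), " sample(s) with all-zero fractions left unnormalized")
  }
  structure(list(proportions = omega,
                 residual_norm = stats::setNames(resid_norm, colnames(Y)),
                 normalized = normalize, n_cpgs_used = length(common)),
            class = "cell_props")
}

as_proportion_matrix <- function(props) {
  if (inherits(props, "cell_props")) props$proportions
  else if (is.matrix(props)) props
  else stop("props must be a cell_props object or a sample x cell-type matrix")
}

#' Compute the methylation-derived neutrophil-lymphocyte ratio (mdNLR)
#'
#' `mdNLR = omega(Gran) / (omega(CD4T) + omega(CD8T) + omega(B) + omega(NK))`.
#' Monocytes enter neither numerator nor denominator. A small floor on the
#' lymphoid sum guarantees a finite score; floored samples are flagged.
#'
#' @param props a `cell_props` object or sample x cell-type matrix with
#'   columns CD4T, CD8T, B, NK, Gran.
#' @param floor lower bound applied to the lymphoid sum (default 1e-4).
#' @return data.frame of class `mdnlr_score`: sample_id, mdnlr, floored.
#' @export
compute_mdnlr <- function(props, floor = 1e-4) {
  omega <- as_proportion_matrix(props)
  need <- c(LYMPHOID_TYPES, "Gran")
  if (!all(need %in% colnames(omega)))
    stop("proportions must have columns: ", paste(need, collapse = ", "))
  lymph <- rowSums(omega[, LYMPHOID_TYPES, drop = FALSE])
  floored <- lymph < floor
  score <- omega[, "Gran"] / pmax(lymph, floor)
  out <- data.frame(sample_id = rownames(omega), mdnlr = unname(score),
                    floored = unname(floored), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("mdnlr_score", "data.frame")
  out
}

#' Dichotomize mdNLR scores into high/low groups
#'
#' The default boundary rule assigns scores equal to the cut point to the
#' high group (`mdnlr >= cutpoint`); `strict = TRUE` uses `mdnlr > cutpoint`.
#'
#' @param score an `mdnlr_score` data.frame or numeric vector of scores.
#' @param cutpoint positive threshold (default 4).
#' @param strict if TRUE, the boundary value is assigned to the low group.
#' @return factor with levels `low`, `high` (named by sample when available).
#' @export
dichotomize_mdnlr <- function(score, cutpoint = 4, strict = FALSE) {
  stopifnot(cutpoint > 0)
  x <- if (inherits(score, "data.frame")) {
    stats::setNames(score$mdnlr, score$sample_id)
  } else score
  high <- if (strict) x > cutpoint else x >= cutpoint
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}
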