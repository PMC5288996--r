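#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||y - X w||^2` subject to `w >= 0`. Deterministic active-set
#' iteration with no random initialization; used as the core of the
#' constrained-projection deconvolution.
#'
#' @param X design matrix (rows = observations, columns = components).
#' @param y response vector.
#' @param tol convergence tolerance on the dual feasibility conditions.
#' @return numeric vector of non-negative coefficients.
#' @export
nnls_fit <- function(X, y, tol = 1e-9) {
  X <- as.matrix(X)
  p <- ncol(X)
  w <- numeric(p)
  passive <- logical(p)
  scale <- max(1, max(abs(crossprod(X, y))))
  max_outer <- 10L * p + 50L
  outer <- 0L
  repeat {
    outer <- outer + 1L
    if (outer > max_outer) break
    grad <- drop(crossprod(X, y - X %*% w))
    cand <- which(!passive & grad > tol * scale)
    if (!length(cand)) break
    j <- cand[which.max(grad[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      sol <- qr.coef(qr(X[, passive, drop = FALSE]), y)
      sol[is.na(sol)] <- 0
      s[passive] <- sol
      if (all(s[passive] > tol)) { w <- s; break }
      on <- which(passive & s <= tol & w > s)
      if (!length(on)) { w <- pmax(s, 0); passive <- w > 0; break }
      a <- min(w[on] / (w[on] - s[on]))
      w <- w + a * (s - w)
      w[w < tol] <- 0
      passive <- w > 0
      if (!any(passive)) break
    }
  }
  w
}

# Active-set solver for min ||y - X w||^2 subject to w >= 0, sum(w) = 1.
# Free variables satisfy the KKT system [2X'X 1; 1' 0][w; lambda] = [2X'y; 1];
# a zero variable is optimal iff its reduced gradient does not exceed lambda.
nnls_sum1 <- function(X, y, tol = 1e-9) {
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  scale <- max(1, max(abs(Xty)))
  w <- rep(1 / p, p)
  passive <- rep(TRUE, p)
  solve_eq <- function(idx) {
    k <- length(idx)
    A <- rbind(cbind(2 * XtX[idx, idx, drop = FALSE], 1), c(rep(1, k), 0))
    sol <- qr.solve(A, c(2 * Xty[idx], 1))
    list(w = sol[seq_len(k)], lambda = sol[k + 1])
  }
  for (iter in seq_len(50L * p)) {
    idx <- which(passive)
    sol <- solve_eq(idx)
    s <- numeric(p)
    s[idx] <- sol$w
    if (any(s[idx] < -tol)) {
      bad <- which(passive & s < w & s < tol)
      a <- min(w[bad] / (w[bad] - s[bad]))
      w <- w + a * (s - w)
      hit <- passive & w <= tol & s < tol
      passive[hit] <- FALSE
      w[!passive] <- 0
      next
    }
    w <- s
    lambda <- sol$lambda / 2          # free vars: (X'y - X'X w)_j = lambda
    h <- Xty - drop(XtX %*% w)
    viol <- which(!passive & h > lambda + tol * scale)
    if (!length(viol)) break
    passive[viol[which.max(h[viol])]] <- TRUE
  }
  w
}

# Constrained projection onto the reference library for one sample:
# minimize ||y - X w||^2 subject to w >= 0 and sum(w) <= 1. If the plain
# NNLS solution already satisfies sum(w) <= 1 it is optimal for the
# inequality problem (KKT, inactive constraint); otherwise, by convexity the
# constraint is active at the optimum and the equality-constrained
# active-set solver applies.
solve_proportions <- function(X, y, tol = 1e-9) {
  w <- nnls_fit(X, y, tol)
  if (sum(w) > 1 + 1e-9) w <- nnls_sum1(X, y, tol)
  w
}
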