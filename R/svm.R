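#' Train a binary linear maximum-margin classifier
#'
#' L1-loss soft-margin linear SVM solved in the dual by coordinate descent
#' (liblinear-style), with the bias handled as an augmented constant feature.
#' Updates sweep the training points in a fixed order until the largest
#' projected-gradient violation falls below `tol`, so training is fully
#' deterministic.
#'
#' @param X `[n x p]` training matrix.
#' @param y Labels in `{-1, +1}`.
#' @param C Soft-margin cost (default 1, the fixed unit regularization used
#'   throughout the pipeline).
#' @param tol Convergence tolerance on the projected gradient (1e-4, far
#'   tighter than liblinear's default 0.1).
#' @param max_pass Maximum full sweeps.
#' @return List with weight vector `w` (length p) and intercept `b`.
#' @export
linsvm_fit <- function(X, y, C = 1, tol = 1e-4, max_pass = 2000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || !all(y %in% c(-1, 1))) stop("y must be +/-1 labels, one per row")
  Xa <- cbind(X, 1)
  w <- .linsvm_cd(Xa, as.numeric(y), C, tol, as.integer(max_pass))
  p <- ncol(X)
  list(w = w[seq_len(p)], b = w[p + 1L])
}

# pure-R reference implementation of the same solver (kept for tests)
linsvm_fit_r <- function(X, y, C = 1, tol = 1e-4, max_pass = 2000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || !all(y %in% c(-1, 1))) stop("y must be +/-1 labels, one per row")
  Xa <- cbind(X, 1)
  # dual coordinate descent in kernel form: K[i, j] = y_i y_j <xa_i, xa_j>;
  # the gradient g = K alpha - 1 is maintained incrementally (O(n) per update)
  K <- tcrossprod(Xa) * tcrossprod(y)
  qd <- diag(K)
  alpha <- numeric(n)
  g <- rep(-1, n)
  for (pass in seq_len(max_pass)) {
    max_pg <- 0
    for (i in seq_len(n)) {
      G <- g[i]
      pg <- if (alpha[i] <= 0) min(G, 0) else if (alpha[i] >= C) max(G, 0) else G
      apg <- abs(pg)
      if (apg > max_pg) max_pg <- apg
      if (apg > 1e-14) {
        a_new <- min(max(alpha[i] - G / qd[i], 0), C)
        d <- a_new - alpha[i]
        if (d != 0) {
          g <- g + d * K[, i]
          alpha[i] <- a_new
        }
      }
    }
    if (max_pg < tol) break
  }
  w <- drop(crossprod(Xa, alpha * y))
  p <- ncol(X)
  list(w = w[seq_len(p)], b = w[p + 1L])
}

#' Decision values of a linear classifier
#'
#' @param fit Result of [linsvm_fit()].
#' @param X `[m x p]` test matrix (or a single pattern vector).
#' @return Numeric decision values (positive = class +1).
#' @export
linsvm_decision <- function(fit, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  drop(X %*% fit$w + fit$b)
}

# accuracy credit with deterministic tie-break: a decision value of exactly
# zero counts as half correct
svm_credit <- function(decision, y) {
  ifelse(decision * y > 0, 1, ifelse(decision == 0, 0.5, 0))
}
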