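# Internal gene-wise (weighted) least-squares engine.
#
# E: gene-by-sample matrix; X: sample-by-parameter full-rank design;
# W: optional gene-by-sample positive weights. Returns per-gene coefficients,
# fitted values, residual variances, the flattened (p x p) inverse
# cross-product matrices (for contrast standard errors) and, on request,
# leverages. The orthogonal-design branch (one-way group-means designs, the
# common case in this package) is fully vectorized; correlated designs fall
# back to a per-gene p x p solve.
wls_fit <- function(E, X, W = NULL, hat = FALSE) {
  E <- as.matrix(E)
  X <- as.matrix(X)
  n <- ncol(E); p <- ncol(X); G <- nrow(E)
  if (nrow(X) != n) stop("design rows must match number of samples")
  if (n - p <= 0) stop("saturated design: no residual degrees of freedom")

  if (is.null(W)) {
    qx <- qr(X)
    if (qx$rank < p) stop("design matrix is not of full column rank")
    coef <- t(qr.coef(qx, t(E)))
    fitted <- coef %*% t(X)
    res <- E - fitted
    sigma2 <- rowSums(res^2) / (n - p)
    xtx_inv <- chol2inv(chol(crossprod(X)))
    cov_flat <- matrix(rep(as.vector(xtx_inv), each = G), nrow = G)
    h <- NULL
    if (hat) {
      hv <- rowSums((X %*% xtx_inv) * X)
      h <- matrix(rep(hv, each = G), nrow = G)
    }
    return(list(coef = coef, fitted = fitted, sigma2 = sigma2,
                df_resid = n - p, cov_flat = cov_flat, hat = h))
  }

  W <- as.matrix(W)
  if (!all(dim(W) == dim(E))) stop("weights must match E in shape")
  if (any(!is.finite(W)) || any(W <= 0)) stop("weights must be finite and > 0")

  # P[i, (j-1)*p + k] = X[i,j] * X[i,k]; then (X'W_gX) rows are W %*% P
  P <- matrix(0, n, p * p)
  for (j in seq_len(p)) for (k in seq_len(p))
    P[, (j - 1L) * p + k] <- X[, j] * X[, k]
  C_flat <- W %*% P                       # G x p^2
  B <- (W * E) %*% X                      # G x p   (X' W_g y_g)

  offdiag <- as.vector(upper.tri(matrix(0, p, p)) | lower.tri(matrix(0, p, p)))
  orthogonal <- p == 1L || all(abs(P[, offdiag]) < 1e-300)

  Cinv_flat <- matrix(0, G, p * p)
  if (orthogonal) {
    diag_idx <- (seq_len(p) - 1L) * p + seq_len(p)
    D <- C_flat[, diag_idx, drop = FALSE]
    if (any(D <= 0)) stop("degenerate weighted design (zero diagonal)")
    Cinv_flat[, diag_idx] <- 1 / D
    coef <- B / D
  } else {
    coef <- matrix(0, G, p)
    for (g in seq_len(G)) {
      Ci <- matrix(C_flat[g, ], p, p)
      Cinv <- tryCatch(chol2inv(chol(Ci)),
                       error = function(e) stop("degenerate weighted design"))
      Cinv_flat[g, ] <- as.vector(Cinv)
      coef[g, ] <- Cinv %*% B[g, ]
    }
  }
  fitted <- coef %*% t(X)
  res <- E - fitted
  sigma2 <- rowSums(W * res^2) / (n - p)
  h <- NULL
  if (hat) h <- (Cinv_flat %*% t(P)) * W
  list(coef = coef, fitted = fitted, sigma2 = sigma2, df_resid = n - p,
       cov_flat = Cinv_flat, hat = h)
}

# Variance of a contrast estimate on the unscaled level: sqrt(c' (X'WX)^-1 c)
# computed from the flattened inverses returned by wls_fit.
contrast_stdev_unscaled <- function(cov_flat, contrast) {
  p <- length(contrast)
  q <- as.vector(outer(contrast, contrast))
  v <- as.vector(cov_flat %*% q)
  sqrt(pmax(v, 0))
}
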