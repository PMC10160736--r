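#' Estimate sample (quality) weights
#'
#' Fits the heteroscedastic gene-wise model `var(e_gi) = sigma_g^2 *
#' exp(gamma_i)` by a REML-type fixed-point iteration: given current weights,
#' all genes are refit, and each `gamma` is updated from the ratio of
#' block-aggregated standardized squared residuals to residual leverages,
#' until `max |delta gamma| < tol`. With `block` given, one `gamma` is
#' estimated per group, so all samples in a group share a weight. Weights
#' `1/exp(gamma_hat)` are normalized to geometric mean 1.
#'
#' @param E Gene-by-sample log-CPM matrix.
#' @param X Design matrix of full column rank.
#' @param obs_weights Optional gene-by-sample prior precision weights
#'   (e.g. voom weights) used in the fits.
#' @param block Optional group label per sample; constrains weights to be
#'   equal within each group. `NULL` gives unconstrained per-sample weights.
#' @param tol Convergence tolerance on `max |delta gamma|`.
#' @param maxit Maximum number of iterations.
#' @return An object of class `sample_weight_fit` with `gamma_hat`,
#'   `sample_weight` (= `1/exp(gamma_hat)`, geometric mean 1), `block`,
#'   `constrained`, `iterations` and `converged`.
#' @export
estimate_sample_weights <- function(E, X, obs_weights = NULL, block = NULL,
                                    tol = 1e-6, maxit = 50L) {
  E <- as.matrix(E); X <- as.matrix(X)
  n <- ncol(E); p <- ncol(X)
  if (n < p + 2) stop("need at least 2 residual degrees of freedom overall")
  if (is.null(obs_weights)) obs_weights <- matrix(1, nrow(E), n)
  constrained <- !is.null(block)
  if (constrained) {
    block <- as.character(block)
    if (length(block) != n) stop("block must label every sample")
    sizes <- table(block)
    Z <- factor(block)
  } else {
    Z <- factor(seq_len(n))
  }
  K <- nlevels(Z)

  gamma <- rep(0, K)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    v <- exp(-gamma)[as.integer(Z)]
    U <- obs_weights * rep(v, each = nrow(E))
    fit <- wls_fit(E, X, W = U, hat = TRUE)
    use <- fit$sigma2 > 1e-12
    if (sum(use) < 2) stop("too few genes with positive residual variance")
    std <- (U[use, , drop = FALSE] *
              (E[use, , drop = FALSE] - fit$fitted[use, , drop = FALSE])^2) /
      fit$sigma2[use]
    num <- colSums(std)
    den <- colSums(1 - fit$hat[use, , drop = FALSE])
    num_k <- tapply(num, Z, sum)
    den_k <- tapply(den, Z, sum)
    if (any(den_k <= 0))
      stop("a block contributes no residual degrees of freedom; ",
           "merge it or drop the constraint")
    delta <- log(as.numeric(num_k) / as.numeric(den_k))
    gamma <- gamma + delta
    gamma <- gamma - mean(gamma)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("sample-weight estimation did not converge in ", maxit,
            " iterations")
  g_i <- gamma[as.integer(Z)]
  sw <- exp(-g_i)
  sw <- sw / exp(mean(log(sw)))
  structure(list(gamma_hat = stats::setNames(g_i, colnames(E)),
                 sample_weight = stats::setNames(sw, colnames(E)),
                 block = if (constrained) block else NULL,
                 constrained = constrained,
                 iterations = it, converged = converged),
            class = "sample_weight_fit")
}

#' @export
print.sample_weight_fit <- function(x, ...) {
  cat(sprintf("sample_weight_fit (%s, %s after %d iterations)\n",
              if (x$constrained) "blocked" else "per-sample",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(x$sample_weight, 3))
  invisible(x)
}

#' voomQWB: voom with block-constrained sample quality weights
#'
#' Combines voom precision weights with group-level sample weights:
#' `w*_gi = w_gi / exp(gamma_hat_i)`, where all samples of a group share one
#' `gamma`. The voom trend and the sample weights are refined alternately
#' (`n_iter` passes, default 2, mirroring the standard
#' quality-weighted voom pipeline): voom, estimate weights, re-run voom with
#' the sample weights in the gene-wise fits, re-estimate, combine.
#'
#' @param pb A normalized `pseudobulk` object.
#' @param X Design matrix.
#' @param group Group label per sample used as the weight block. Use
#'   `block = NULL` via [estimate_sample_weights()] for classical per-sample
#'   quality weights.
#' @param span LOWESS span.
#' @param n_iter Number of voom/sample-weight alternations.
#' @return A `pbvoom_fit` with `method = "voomQWB"`, combined `weights`
#'   (`w* = w * sample_weight`) and `sample_weights` recorded.
#' @export
voom_qwb <- function(pb, X, group = pb$samples$group, span = 0.5,
                     n_iter = 2L) {
  stopifnot(inherits(pb, "pseudobulk"), n_iter >= 1)
  group <- as.character(group)
  if (length(group) != ncol(pb$counts)) stop("group must cover all samples")
  v <- voom_weights(pb, X, span = span)
  sw <- estimate_sample_weights(v$E, X, obs_weights = v$weights,
                                block = group)
  if (n_iter >= 2) {
    for (k in seq_len(n_iter - 1L)) {
      v <- voom_weights(pb, X, span = span,
                        sample_weights = sw$sample_weight)
      sw <- estimate_sample_weights(v$E, X, obs_weights = v$weights,
                                    block = group)
    }
  }
  v$weights <- v$weights * rep(sw$sample_weight, each = nrow(v$E))
  v$sample_weights <- sw$sample_weight
  v$method <- "voomQWB"
  v
}
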