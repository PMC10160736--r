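#' Build a design matrix from sample metadata
#'
#' Convenience wrapper around [stats::model.matrix()] using the `samples`
#' table of a `pseudobulk` object. With `~ 0 + group` the columns are named by
#' the group levels, which makes contrasts easy to write.
#'
#' @param pb A `pseudobulk` object.
#' @param formula A one-sided model formula over columns of `pb$samples`,
#'   default `~ 0 + group` (group-means coding).
#' @return A sample-by-parameter design matrix with full column rank.
#' @export
design_matrix <- function(pb, formula = ~ 0 + group) {
  stopifnot(inherits(pb, "pseudobulk"))
  X <- stats::model.matrix(formula, data = pb$samples)
  colnames(X) <- sub("^group", "", colnames(X))
  if (qr(X)$rank < ncol(X)) stop("design matrix is not of full column rank")
  X
}

#' Gene-wise (weighted) linear model fits
#'
#' Fits the linear model `E(y_g) = X beta_g` to every gene by (weighted)
#' least squares.
#'
#' @param E Gene-by-sample matrix of log-CPM values.
#' @param X Sample-by-parameter design matrix of full column rank.
#' @param weights Optional gene-by-sample matrix of positive precision
#'   weights.
#' @return A list with `coef` (gene-by-parameter), `sigma` (residual SD per
#'   gene), `df_resid`, and `fitted` (gene-by-sample, log-CPM scale).
#' @export
fit_gene_lms <- function(E, X, weights = NULL) {
  fit <- wls_fit(E, X, W = weights)
  list(coef = fit$coef, sigma = sqrt(fit$sigma2), df_resid = fit$df_resid,
       fitted = fit$fitted)
}

#' Fit the mean-variance trend
#'
#' LOWESS fit of square-root residual standard deviations against average
#' log2 counts — the voom mean-variance trend. Prediction is by linear
#' interpolation between the smoothed points with constant extrapolation
#' beyond the trained range, floored at 1e-4.
#'
#' @param avg_log_count Per-gene average log2 count.
#' @param sqrt_sd Per-gene square root of the residual standard deviation.
#' @param span LOWESS span (fraction of points in each local window).
#' @param iter Number of robustifying iterations ([stats::lowess()] default).
#' @return An object of class `mv_trend` with the training points, the
#'   smoothed curve, and a `predict()` method.
#' @export
fit_trend <- function(avg_log_count, sqrt_sd, span = 0.5, iter = 3L) {
  ok <- is.finite(avg_log_count) & is.finite(sqrt_sd) & sqrt_sd > 0
  if (sum(ok) < 10)
    stop("fewer than 10 usable genes for the mean-variance trend; ",
         "use the overall trend instead")
  x <- avg_log_count[ok]; y <- sqrt_sd[ok]
  l <- stats::lowess(x, y, f = span, iter = iter)
  structure(list(train_x = x, train_y = y, x = l$x, y = l$y,
                 span = span, iter = iter),
            class = "mv_trend")
}

#' Predict from a mean-variance trend
#'
#' @param object An `mv_trend` object.
#' @param newdata Numeric vector or matrix of average log2 counts.
#' @param ... Unused.
#' @return Predicted square-root residual SDs (>= 1e-4), same shape as
#'   `newdata`.
#' @export
predict.mv_trend <- function(object, newdata, ...) {
  f <- stats::approxfun(object$x, object$y, rule = 2,
                        ties = list("ordered", mean))
  out <- pmax(f(as.numeric(newdata)), 1e-4)
  if (is.matrix(newdata)) out <- matrix(out, nrow(newdata), ncol(newdata),
                                        dimnames = dimnames(newdata))
  out
}

#' @export
print.mv_trend <- function(x, ...) {
  cat(sprintf("mv_trend: %d training genes, span %.2f, range [%.2f, %.2f]\n",
              length(x$train_x), x$span, min(x$x), max(x$x)))
  invisible(x)
}

# Average log2 count per gene on the voom scale: mean log-CPM shifted back to
# the count scale by the (log) geometric mean effective library size.
avg_log_count <- function(E, elib) {
  rowMeans(E) + mean(log2(elib + 1)) - log2(1e6)
}

# Per-observation fitted log2 counts from fitted log-CPM.
fitted_log_count <- function(fitted, elib) {
  t(t(fitted) + log2(elib + 1) - log2(1e6))
}

#' voom: mean-variance precision weights for pseudo-bulk counts
#'
#' Transforms counts to log-CPM, fits gene-wise linear models, fits the
#' LOWESS mean-variance trend of sqrt residual SD against average log2 count,
#' and converts the trend prediction at each fitted log2 count into an
#' observation precision weight `w = lo(lambda_hat)^-4`.
#'
#' @param pb A normalized `pseudobulk` object.
#' @param X Design matrix (see [design_matrix()]).
#' @param span LOWESS span.
#' @param sample_weights Optional positive per-sample weights applied in the
#'   gene-wise fits (used by [voom_qwb()]).
#' @param prior_count Offset used in the log-CPM transform.
#' @return A `pbvoom_fit` object: `E` (log-CPM), `weights` (precision
#'   weights), `design`, `trend` (the fitted `mv_trend`), `amean` (average
#'   log2 counts), `samples`, and `method = "voom"`.
#' @export
voom_weights <- function(pb, X, span = 0.5, sample_weights = NULL,
                         prior_count = 0.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  lc <- log_cpm(pb, prior_count = prior_count)
  E <- lc$values
  elib <- lc$effective_lib_size
  W <- NULL
  if (!is.null(sample_weights)) {
    if (length(sample_weights) != ncol(E) || any(sample_weights <= 0))
      stop("sample_weights must be positive, one per sample")
    W <- matrix(sample_weights, nrow(E), ncol(E), byrow = TRUE)
  }
  fit <- wls_fit(E, X, W = W)
  sx <- avg_log_count(E, elib)
  sy <- sqrt(sqrt(fit$sigma2))
  trend <- fit_trend(sx, sy, span = span)
  lambda_hat <- fitted_log_count(fit$fitted, elib)
  w <- predict(trend, lambda_hat)^(-4)
  dimnames(w) <- dimnames(E)
  structure(list(E = E, weights = w, design = X, trend = trend,
                 amean = sx, effective_lib_size = elib,
                 samples = pb$samples, method = "voom",
                 sample_weights = NULL, group_trends = NULL,
                 group_bcv = NULL, dynamic = NULL),
            class = "pbvoom_fit")
}

#' @export
print.pbvoom_fit <- function(x, ...) {
  cat(sprintf("pbvoom_fit (%s): %d genes x %d samples\n",
              x$method, nrow(x$E), ncol(x$E)))
  if (!is.null(x$sample_weights)) {
    cat("sample weights:\n")
    print(round(x$sample_weights, 3))
  }
  if (!is.null(x$group_bcv)) {
    cat("group BCV:\n")
    print(round(x$group_bcv, 3))
  }
  invisible(x)
}

#' Serialize a fitted voom object to TSV + JSON
#'
#' Writes `<prefix>_E.tsv` (log-CPM), `<prefix>_weights.tsv` and
#' `<prefix>.json` (method, sample table, sample weights, group BCVs).
#'
#' @param fit A `pbvoom_fit` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_voom_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "pbvoom_fit"))
  paths <- c(paste0(prefix, "_E.tsv"), paste0(prefix, "_weights.tsv"),
             paste0(prefix, ".json"))
  for (i in 1:2) {
    m <- if (i == 1) fit$E else fit$weights
    utils::write.table(data.frame(gene = rownames(fit$E), m,
                                  check.names = FALSE),
                       paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(method = fit$method,
               samples = fit$samples,
               sample_weights = fit$sample_weights,
               group_bcv = fit$group_bcv,
               dynamic = fit$dynamic)
  jsonlite::write_json(meta, paths[3], digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(paths)
}
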