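#' Weighted linear-model fit for a contrast
#'
#' Per gene, weighted least-squares fit of log-CPM on the design using the
#' precision weights of a fitted voom object, plus the contrast estimate and
#' its unscaled standard deviation.
#'
#' @param wle A `pbvoom_fit` object (from [voom_weights()], [voom_qwb()] or
#'   [voom_by_group()]).
#' @param contrast Numeric contrast vector, one entry per design column, or a
#'   string like `"g2-g1"` naming design columns.
#' @return A list with `logFC`, `stdev_unscaled`, `s2`, `df_resid`,
#'   `amean`, `genes`, and `valid` (FALSE for an all-zero contrast).
#' @export
lm_contrast_fit <- function(wle, contrast) {
  stopifnot(inherits(wle, "pbvoom_fit"))
  X <- wle$design
  contrast <- parse_contrast(contrast, colnames(X))
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns")
  fit <- wls_fit(wle$E, X, W = wle$weights)
  valid <- any(contrast != 0)
  list(logFC = as.vector(fit$coef %*% contrast),
       stdev_unscaled = contrast_stdev_unscaled(fit$cov_flat, contrast),
       s2 = fit$sigma2, df_resid = fit$df_resid,
       amean = rowMeans(wle$E), genes = rownames(wle$E), valid = valid)
}

# "g2-g1" (or a single column name) -> numeric contrast over design columns.
parse_contrast <- function(contrast, cols) {
  if (is.numeric(contrast)) return(contrast)
  s <- gsub(" ", "", contrast)
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% 1:2 || !all(parts %in% cols))
    stop("contrast '", contrast, "' does not name design columns (",
         paste(cols, collapse = ", "), ")")
  v <- stats::setNames(numeric(length(cols)), cols)
  v[parts[1]] <- 1
  if (length(parts) == 2) v[parts[2]] <- -1
  unname(v)
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  x
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Moment-matching on `log(s^2)`: fits the scaled-F prior
#' `s^2 ~ s0^2 * F(df, d0)` by matching the mean and variance of `log s^2`
#' (Newton inversion of the trigamma function), then forms posterior
#' variances `s2_post = (d0*s0^2 + df*s2) / (d0 + df)`. When the `log s^2`
#' spread is no larger than expected under equal true variances, `d0` is
#' infinite and `s2_post` is constant.
#'
#' @param s2 Per-gene residual variances (finite, >= 0; zeros are floored at
#'   1e-10 for the log moment fit).
#' @param df_resid Residual degrees of freedom.
#' @return A list with `d0` (prior df, possibly `Inf`), `s0_sq` (prior
#'   variance) and `s2_post`.
#' @export
squeeze_var <- function(s2, df_resid) {
  if (any(!is.finite(s2)) || any(s2 < 0)) stop("s2 must be finite and >= 0")
  if (length(s2) < 2) stop("need at least 2 variances")
  if (df_resid == 0) return(list(d0 = 0, s0_sq = NA_real_, s2_post = s2))
  z <- log(pmax(s2, 1e-10))
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  evar <- stats::var(e) - trigamma(df_resid / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  } else {
    # spread of log s^2 no larger than chi-square sampling noise: the prior
    # absorbs everything and the common variance is the plain average
    d0 <- Inf
    s0_sq <- mean(s2)
    s2_post <- rep(s0_sq, length(s2))
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' Moderated t-tests and ranked results table
#'
#' Computes moderated t-statistics `t = logFC / (stdev_unscaled *
#' sqrt(s2_post))` on `df_resid + d0` degrees of freedom, two-sided p-values,
#' and Benjamini-Hochberg adjusted p-values.
#'
#' @param fit Output of [lm_contrast_fit()].
#' @param squeeze Output of [squeeze_var()] on `fit$s2` (computed if `NULL`).
#' @return A tibble of class `de_table` with columns `gene`, `logFC`,
#'   `AveExpr`, `t`, `P.Value`, `adj.P.Val`, sorted by p-value with a stable
#'   tie-break on gene ID.
#' @export
moderated_t_table <- function(fit, squeeze = NULL) {
  if (!fit$valid) stop("invalid (all-zero) contrast")
  if (is.null(squeeze)) squeeze <- squeeze_var(fit$s2, fit$df_resid)
  df_total <- fit$df_resid + squeeze$d0
  se <- fit$stdev_unscaled * sqrt(squeeze$s2_post)
  t <- unname(fit$logFC / se)
  p <- 2 * stats::pt(-abs(t), df = df_total)
  adj <- stats::p.adjust(p, method = "BH")
  tab <- tibble::tibble(gene = fit$genes, logFC = unname(fit$logFC),
                        AveExpr = unname(fit$amean), t = t, P.Value = p,
                        adj.P.Val = adj)
  tab <- tab[order(tab$P.Value, tab$gene), ]
  attr(tab, "d0") <- squeeze$d0
  attr(tab, "s0_sq") <- squeeze$s0_sq
  attr(tab, "df_resid") <- fit$df_resid
  class(tab) <- c("de_table", class(tab))
  tab
}

#' Full differential-expression pipeline for one contrast
#'
#' Weighted fit, variance squeezing, and the moderated-t results table in one
#' call.
#'
#' @inheritParams lm_contrast_fit
#' @return A `de_table` tibble (see [moderated_t_table()]).
#' @export
de_test <- function(wle, contrast) {
  moderated_t_table(lm_contrast_fit(wle, contrast))
}

#' Call differentially expressed genes
#'
#' @param table A `de_table` (or any data frame with `gene` and `adj.P.Val`).
#' @param cutoff Adjusted p-value cutoff in (0, 1).
#' @return Character vector of gene IDs with `adj.P.Val <= cutoff`.
#' @export
decide_de <- function(table, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff < 1)
  if (nrow(table) == 0) return(character(0))
  table$gene[table$adj.P.Val <= cutoff]
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname moderated_t_table
#' @param x A `de_table`.
#' @param ... Unused.
#' @export
tidy.de_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_table")
  out
}

#' @rdname moderated_t_table
#' @export
glance.de_table <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 d0 = attr(x, "d0"),
                 s0_sq = attr(x, "s0_sq"),
                 df_resid = attr(x, "df_resid"),
                 n_de_05 = sum(x$adj.P.Val <= 0.05))
}

#' Write a DE results table as TSV
#'
#' @param table A `de_table`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
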