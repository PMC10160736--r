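# Mean Cox-Reid adjusted profile log-likelihood over genes for an
# intercept-only negative binomial model with log effective-library-size
# offsets, at dispersion phi. Vectorized over genes: the intercept MLE is
# found by Fisher scoring (weights mu/(1+phi*mu)).
cr_apl_mean <- function(counts, elib, phi) {
  y <- counts
  n <- ncol(y)
  loff <- log(elib)
  beta <- log(pmax(rowMeans(y), 1e-8) / mean(elib))
  for (i in 1:25) {
    mu <- exp(outer(beta, loff, "+"))
    wt <- mu / (1 + phi * mu)
    score <- rowSums((y - mu) / (1 + phi * mu))
    info <- rowSums(wt)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(outer(beta, loff, "+"))
  r <- 1 / phi
  ll <- rowSums(lgamma(y + r) - lgamma(y + 1) +
                  y * log(phi * mu / (1 + phi * mu)) -
                  r * log1p(phi * mu)) - n * lgamma(r)
  cr <- 0.5 * log(rowSums(mu / (1 + phi * mu)))
  mean(ll - cr)
}

#' Estimate the common NB dispersion (BCV) for a set of samples
#'
#' Maximizes the per-gene average of the Cox-Reid adjusted profile
#' log-likelihood of an intercept-only negative binomial model with
#' log effective-library-size offsets, by golden-section search on
#' `log10(phi)`. The biological coefficient of variation is `sqrt(phi)`.
#'
#' @param pb A `pseudobulk` object.
#' @param samples Optional sample subset (indices, names, or logical), e.g.
#'   one group's samples. Default: all samples.
#' @param group Optional label stored with the result.
#' @param bounds Search bounds on `log10(phi)`.
#' @param tol Golden-section tolerance on `log10(phi)`.
#' @return An object of class `common_dispersion` with `phi`, `bcv =
#'   sqrt(phi)`, `group` and `n_genes_used`.
#' @export
estimate_common_dispersion <- function(pb, samples = NULL, group = NULL,
                                       bounds = c(-4, 0.7), tol = 1e-4) {
  stopifnot(inherits(pb, "pseudobulk"))
  idx <- if (is.null(samples)) seq_len(ncol(pb$counts)) else samples
  y <- pb$counts[, idx, drop = FALSE]
  elib <- effective_lib_size(pb)[idx]
  if (ncol(y) < 2) stop("need at least 2 samples to estimate dispersion")
  keep <- rowSums(y) > 0
  y <- y[keep, , drop = FALSE]
  if (nrow(y) == 0) stop("no non-zero genes")

  f <- function(t) cr_apl_mean(y, elib, 10^t)
  gr <- (sqrt(5) - 1) / 2
  a <- bounds[1]; b <- bounds[2]
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  phi <- 10^((a + b) / 2)
  structure(list(phi = phi, bcv = sqrt(phi), group = group,
                 n_genes_used = nrow(y)),
            class = "common_dispersion")
}

#' @export
print.common_dispersion <- function(x, ...) {
  cat(sprintf("common dispersion%s: phi = %.4f (BCV = %.3f), %d genes\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$phi, x$bcv, x$n_genes_used))
  invisible(x)
}

#' Group-wise common BCVs
#'
#' @param pb A `pseudobulk` object.
#' @param group Group label per sample (default from the sample table).
#' @param ... Passed to [estimate_common_dispersion()].
#' @return Named numeric vector of BCVs, one per group (groups with fewer
#'   than 2 samples yield `NA`).
#' @export
group_bcv <- function(pb, group = pb$samples$group, ...) {
  group <- as.character(group)
  out <- vapply(unique(group), function(g) {
    idx <- which(group == g)
    if (length(idx) < 2) return(NA_real_)
    estimate_common_dispersion(pb, samples = idx, group = g, ...)$bcv
  }, numeric(1))
  out
}
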