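#' Combine group-specific weight submatrices
#'
#' Places each sample's column of group-specific precision weights into a
#' single gene-by-sample matrix `w#`.
#'
#' @param per_group Named list mapping group label to a gene-by-sample weight
#'   submatrix (columns named by sample).
#' @param group Group label per sample, in output sample order.
#' @param sample_ids Sample IDs in output order.
#' @return Gene-by-sample weight matrix.
#' @export
combine_group_weights <- function(per_group, group,
                                  sample_ids = names(group)) {
  force(sample_ids)
  group <- as.character(group)
  if (is.null(sample_ids)) stop("sample IDs required")
  covered <- unlist(lapply(per_group, colnames), use.names = FALSE)
  if (anyDuplicated(covered))
    stop("overlapping sample coverage across groups")
  if (!setequal(covered, sample_ids))
    stop("group submatrices must cover all samples exactly")
  G <- nrow(per_group[[1]])
  out <- matrix(NA_real_, G, length(sample_ids),
                dimnames = list(rownames(per_group[[1]]), sample_ids))
  for (g in names(per_group)) {
    sub <- per_group[[g]]
    out[, colnames(sub)] <- sub
  }
  out
}

# Subset a design matrix to one group's rows, dropping all-zero columns and
# falling back to intercept-only when the remainder is rank-deficient or
# leaves no residual degrees of freedom.
subset_design <- function(X, idx) {
  Xc <- X[idx, , drop = FALSE]
  keep <- colSums(abs(Xc)) > 0
  Xc <- Xc[, keep, drop = FALSE]
  rank <- if (ncol(Xc)) qr(Xc)$rank else 0L
  if (ncol(Xc) == 0 || rank < ncol(Xc) || length(idx) - rank < 1)
    Xc <- matrix(1, length(idx), 1, dimnames = list(NULL, "(Intercept)"))
  Xc
}

#' voomByGroup: group-specific mean-variance trends and weights
#'
#' The main group-heteroscedasticity method: for each group, the log-CPM
#' matrix and the design are subset to that group's samples, a group-specific
#' LOWESS mean-variance trend is fitted, and precision weights
#' `w_gic = lo_c(lambda_hat_gic)^-4` are computed from it. The group-specific
#' weights are then assembled across groups into `w#_gi`, which replaces the
#' single-trend voom weights in the downstream weighted linear-model
#' pipeline. Log-CPM values, library sizes and TMM factors are computed once
#' on the full data so weights are comparable across groups.
#'
#' Groups flagged `dynamic` use the overall voom trend (and weights) instead
#' of their own — recommended for groups with 2 or fewer samples, and the
#' default for such groups.
#'
#' @param pb A normalized `pseudobulk` object.
#' @param X Design matrix on the full data.
#' @param group Group label per sample.
#' @param dynamic Logical vector, one per group (in `unique(group)` order) or
#'   named by group: use the overall trend for that group. Default:
#'   `TRUE` for groups with <= 2 samples.
#' @param span LOWESS span.
#' @param compute_bcv Estimate each group's common BCV (annotation for
#'   plots); see [estimate_common_dispersion()].
#' @return A `pbvoom_fit` with `method = "voomByGroup"`, combined weights,
#'   `group_trends` (per-group `mv_trend`s plus the overall trend),
#'   `dynamic` flags and `group_bcv`.
#' @export
voom_by_group <- function(pb, X, group = pb$samples$group, dynamic = NULL,
                          span = 0.5, compute_bcv = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  group <- as.character(group)
  if (length(group) != ncol(pb$counts)) stop("group must cover all samples")
  groups <- unique(group)
  sizes <- table(factor(group, levels = groups))

  if (is.null(dynamic)) {
    dynamic <- sizes <= 2
  } else if (!is.null(names(dynamic))) {
    dynamic <- dynamic[groups]
  } else {
    dynamic <- stats::setNames(rep_len(dynamic, length(groups)), groups)
  }
  dynamic <- stats::setNames(as.logical(dynamic), groups)

  small <- groups[!dynamic & sizes[groups] < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "),
         "; set dynamic = TRUE for these groups to use the overall trend")

  overall <- voom_weights(pb, X, span = span)
  E <- overall$E
  elib <- overall$effective_lib_size

  per_group <- list()
  trends <- list()
  for (g in groups) {
    idx <- which(group == g)
    if (dynamic[[g]]) {
      per_group[[g]] <- overall$weights[, idx, drop = FALSE]
      trends[[g]] <- overall$trend
      next
    }
    Ec <- E[, idx, drop = FALSE]
    Xc <- subset_design(X, idx)
    fit <- wls_fit(Ec, Xc)
    sx <- avg_log_count(Ec, elib[idx])
    sy <- sqrt(sqrt(fit$sigma2))
    tr <- fit_trend(sx, sy, span = span)
    lam <- fitted_log_count(fit$fitted, elib[idx])
    w <- predict(tr, lam)^(-4)
    dimnames(w) <- dimnames(Ec)
    per_group[[g]] <- w
    trends[[g]] <- tr
  }
  wsharp <- combine_group_weights(per_group, group,
                                  sample_ids = colnames(E))
  bcv <- NULL
  if (compute_bcv) bcv <- group_bcv(pb, group)

  out <- overall
  out$weights <- wsharp
  out$method <- "voomByGroup"
  out$group_trends <- trends
  out$overall_trend <- overall$trend
  out$dynamic <- dynamic
  out$group_bcv <- bcv
  out$group <- group
  out
}
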