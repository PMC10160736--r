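#' Construct a single-cell count container
#'
#' Bundles a gene-by-cell UMI count matrix with the cell-to-sample and
#' sample-to-group mappings needed for pseudo-bulk aggregation.
#'
#' @param counts Gene-by-cell matrix of non-negative integer counts. Row names
#'   are gene IDs, column names cell barcodes (generated if absent).
#' @param cell_sample Character or factor vector, one entry per cell, giving
#'   the sample each cell belongs to.
#' @param sample_group Named character vector or two-column data frame
#'   (`sample_id`, `group`) mapping each sample to its experimental group.
#' @return An object of class `cell_counts`.
#' @export
cell_counts <- function(counts, cell_sample, sample_group) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (length(cell_sample) != ncol(counts))
    stop("cell_sample must have one entry per cell (column of counts)")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  cell_sample <- as.character(cell_sample)
  if (is.data.frame(sample_group)) {
    sg <- stats::setNames(as.character(sample_group[[2]]),
                          as.character(sample_group[[1]]))
  } else {
    sg <- stats::setNames(as.character(sample_group), names(sample_group))
  }
  missing_map <- setdiff(unique(cell_sample), names(sg))
  if (length(missing_map))
    stop("samples without a group mapping: ", paste(missing_map, collapse = ", "))
  structure(list(counts = counts, cell_sample = cell_sample,
                 sample_group = sg),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d genes x %d cells, %d samples, %d groups\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_sample)),
              length(unique(x$sample_group))))
  invisible(x)
}

#' Construct a pseudo-bulk count container
#'
#' Usually produced by [aggregate_cells()]; this constructor is exported for
#' pre-aggregated gene-by-sample tables read from file.
#'
#' @param counts Gene-by-sample matrix of non-negative integer counts.
#' @param sample_group Group label per sample (recycled names from columns).
#' @param cells_per_sample Integer number of cells aggregated per sample;
#'   defaults to `NA` for externally aggregated data.
#' @param norm_factor TMM normalization factors (default 1; see
#'   [tmm_norm_factors()]).
#' @return An object of class `pseudobulk` with elements `counts`, `lib_size`,
#'   `norm_factor`, `samples` (a tibble with `sample_id`, `group`, `n_cells`),
#'   and `meta` (a list of processing notes).
#' @export
pseudobulk <- function(counts, sample_group, cells_per_sample = NA_integer_,
                       norm_factor = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
  sample_group <- as.character(sample_group)
  if (length(sample_group) != ncol(counts))
    stop("sample_group must have one entry per sample")
  cells <- rep_len(as.integer(cells_per_sample), ncol(counts))
  structure(list(
    counts = counts,
    lib_size = colSums(counts),
    norm_factor = stats::setNames(rep_len(norm_factor, ncol(counts)),
                                  colnames(counts)),
    samples = tibble::tibble(sample_id = colnames(counts),
                             group = sample_group,
                             n_cells = cells),
    meta = list()
  ), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$samples$group)),
                            as.integer(table(x$samples$group))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.pseudobulk <- function(x) dim(x$counts)

#' Effective (TMM-scaled) library sizes
#' @param pb A `pseudobulk` object.
#' @return Numeric vector `lib_size * norm_factor`.
#' @export
effective_lib_size <- function(pb) pb$lib_size * pb$norm_factor

#' Aggregate single-cell counts to pseudo-bulk samples
#'
#' Sums UMI counts over all cells belonging to each sample, producing one
#' pseudo-bulk expression column per sample. Aggregation conserves the total
#' read count.
#'
#' @param cc A [cell_counts()] object.
#' @return A [pseudobulk()] object with `n_cells` recorded per sample and
#'   normalization factors initialized to 1.
#' @export
aggregate_cells <- function(cc) {
  stopifnot(inherits(cc, "cell_counts"))
  samples <- names(cc$sample_group)
  n_cells <- table(factor(cc$cell_sample, levels = samples))
  if (any(n_cells == 0))
    stop("sample(s) with zero cells: ",
         paste(samples[n_cells == 0], collapse = ", "))
  # t(rowsum(t(x), f)) sums columns by sample in one pass
  agg <- t(rowsum(t(cc$counts), group = factor(cc$cell_sample, levels = samples)))
  storage.mode(agg) <- "double"
  pseudobulk(agg[, samples, drop = FALSE],
             sample_group = unname(cc$sample_group[samples]),
             cells_per_sample = as.integer(n_cells[samples]))
}

#' Filter lowly expressed genes
#'
#' Removes genes whose total count across all pseudo-bulk samples falls below
#' `min_total` (default 30 reads), then recomputes library sizes. Gene order
#' is preserved. Normalization factors are reset to 1 and should be
#' recomputed with [tmm_norm_factors()].
#'
#' @param pb A `pseudobulk` object.
#' @param min_total Minimum total read count across samples for a gene to be
#'   retained.
#' @return A filtered `pseudobulk` object.
#' @export
filter_genes <- function(pb, min_total = 30) {
  stopifnot(inherits(pb, "pseudobulk"), min_total >= 0)
  keep <- rowSums(pb$counts) >= min_total
  if (!any(keep)) stop("all genes removed by filter_genes(min_total = ",
                       min_total, ")")
  out <- pseudobulk(pb$counts[keep, , drop = FALSE],
                    sample_group = pb$samples$group,
                    cells_per_sample = pb$samples$n_cells)
  out$meta <- c(pb$meta, list(filter_genes = list(min_total = min_total,
                                                  removed = sum(!keep))))
  out
}

#' Filter low-quality pseudo-bulk samples
#'
#' Removes samples with fewer than `min_cells` aggregated cells or library
#' size below `min_lib`. If a group loses all of its samples a warning is
#' recorded in the result's `meta` (the group may still be analyzable in a
#' reduced design).
#'
#' @param pb A `pseudobulk` object with known `n_cells`.
#' @param min_cells Minimum number of cells per retained sample.
#' @param min_lib Minimum library size per retained sample.
#' @return A filtered `pseudobulk` object.
#' @export
filter_samples <- function(pb, min_cells = 50, min_lib = 0) {
  stopifnot(inherits(pb, "pseudobulk"), min_cells >= 0, min_lib >= 0)
  n_cells <- pb$samples$n_cells
  keep <- (is.na(n_cells) | n_cells >= min_cells) & pb$lib_size >= min_lib
  if (!any(keep)) stop("all samples removed by filter_samples()")
  out <- pseudobulk(pb$counts[, keep, drop = FALSE],
                    sample_group = pb$samples$group[keep],
                    cells_per_sample = n_cells[keep])
  lost <- setdiff(unique(pb$samples$group), out$samples$group)
  out$meta <- c(pb$meta, list(filter_samples = list(
    min_cells = min_cells, min_lib = min_lib, removed = sum(!keep),
    groups_emptied = lost)))
  if (length(lost))
    warning("group(s) left with zero samples: ", paste(lost, collapse = ", "))
  out
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scale factors (log-ratio trim 0.30,
#' absolute-intensity trim 0.05, precision weighting, reference sample chosen
#' by upper-quartile CPM closest to the mean upper quartile), rescaled to a
#' geometric mean of 1.
#'
#' @param pb A `pseudobulk` object with at least 2 samples, all with positive
#'   library size.
#' @return The `pseudobulk` object with `norm_factor` filled in.
#' @export
tmm_norm_factors <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (ncol(pb$counts) < 2) stop("TMM needs at least 2 samples")
  if (any(pb$lib_size <= 0)) stop("sample(s) with zero library size")
  nf <- edgeR::calcNormFactors(pb$counts, lib.size = pb$lib_size,
                               method = "TMM")
  pb$norm_factor <- stats::setNames(nf, colnames(pb$counts))
  pb
}

#' Log2 counts-per-million
#'
#' voom-convention log-CPM: `log2((count + prior_count) /
#' (lib_size * norm_factor + 1) * 1e6)`. The prior count keeps zeros finite;
#' the `+ 1` in the denominator matches the precision-weight interpolation
#' scale used throughout the package.
#'
#' @param pb A `pseudobulk` object (normalization factors applied if present).
#' @param prior_count Offset added to each count before the log.
#' @return A list of class `log_cpm` with elements `values` (gene-by-sample
#'   matrix) and `effective_lib_size`.
#' @export
log_cpm <- function(pb, prior_count = 0.5) {
  stopifnot(inherits(pb, "pseudobulk"))
  elib <- effective_lib_size(pb)
  if (any(elib <= 0)) stop("non-positive effective library size")
  vals <- t(log2(t(pb$counts + prior_count) / (elib + 1) * 1e6))
  structure(list(values = vals, effective_lib_size = elib),
            class = "log_cpm")
}
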