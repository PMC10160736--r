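#' Read single-cell counts from a MatrixMarket triple
#'
#' Reads the standard MTX triple (matrix, gene list, cell barcodes) plus cell
#' and sample metadata tables.
#'
#' @param mtx Path to the MatrixMarket file (genes in rows, cells in columns).
#' @param genes Path to a one-column text file of gene IDs.
#' @param barcodes Path to a one-column text file of cell barcodes.
#' @param cell_meta Path to a TSV with columns `cell_id`, `sample_id`.
#' @param sample_meta Path to a TSV with columns `sample_id`, `group`.
#' @return A [cell_counts()] object.
#' @export
read_cell_counts_mtx <- function(mtx, genes, barcodes, cell_meta, sample_meta) {
  for (p in c(mtx, genes, barcodes, cell_meta, sample_meta))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes)
  colnames(m) <- readLines(barcodes)
  cm <- utils::read.delim(cell_meta, stringsAsFactors = FALSE)
  sm <- utils::read.delim(sample_meta, stringsAsFactors = FALSE)
  idx <- match(colnames(m), cm$cell_id)
  if (anyNA(idx)) stop("cell barcodes missing from cell metadata")
  cell_counts(m, cell_sample = cm$sample_id[idx],
              sample_group = sm[, c("sample_id", "group")])
}

#' Read single-cell counts from a dense gene-by-cell TSV
#'
#' @param counts_tsv Path to a TSV with gene IDs in the first column and one
#'   column per cell.
#' @inheritParams read_cell_counts_mtx
#' @return A [cell_counts()] object.
#' @export
read_cell_counts_tsv <- function(counts_tsv, cell_meta, sample_meta) {
  for (p in c(counts_tsv, cell_meta, sample_meta))
    if (!file.exists(p)) stop("file not found: ", p)
  df <- utils::read.delim(counts_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cm <- utils::read.delim(cell_meta, stringsAsFactors = FALSE)
  sm <- utils::read.delim(sample_meta, stringsAsFactors = FALSE)
  idx <- match(colnames(m), cm$cell_id)
  if (anyNA(idx)) stop("cell IDs missing from cell metadata")
  cell_counts(m, cell_sample = cm$sample_id[idx],
              sample_group = sm[, c("sample_id", "group")])
}

#' Read a pre-aggregated pseudo-bulk count table
#'
#' @param counts_tsv TSV with gene IDs in the first column, samples in the
#'   remaining columns.
#' @param sample_meta TSV with columns `sample_id`, `group` and optionally
#'   `n_cells`.
#' @return A [pseudobulk()] object (normalization factors set to 1).
#' @export
read_pseudobulk <- function(counts_tsv, sample_meta) {
  for (p in c(counts_tsv, sample_meta))
    if (!file.exists(p)) stop("file not found: ", p)
  df <- utils::read.delim(counts_tsv, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sm <- utils::read.delim(sample_meta, stringsAsFactors = FALSE)
  idx <- match(colnames(m), sm$sample_id)
  if (anyNA(idx)) stop("samples missing from sample metadata: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  n_cells <- if ("n_cells" %in% names(sm)) sm$n_cells[idx] else NA_integer_
  pseudobulk(m, sample_group = sm$group[idx], cells_per_sample = n_cells)
}

#' Write pseudo-bulk counts as TSV plus a JSON sidecar
#'
#' The TSV has genes in rows (first column `gene`) and one column per sample;
#' the sidecar records library sizes, normalization factors, groups and cells
#' per sample.
#'
#' @param pb A `pseudobulk` object.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_pseudobulk <- function(pb, prefix) {
  stopifnot(inherits(pb, "pseudobulk"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- data.frame(gene = rownames(pb$counts), pb$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(sample_id = pb$samples$sample_id,
               group = pb$samples$group,
               n_cells = pb$samples$n_cells,
               lib_size = unname(pb$lib_size),
               norm_factor = unname(pb$norm_factor))
  jsonlite::write_json(side, json, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}

#' Write single-cell counts as a MatrixMarket triple plus metadata
#'
#' @param cc A `cell_counts` object.
#' @param dir Output directory (created if needed); files `matrix.mtx`,
#'   `genes.txt`, `barcodes.txt`, `cell_meta.tsv`, `sample_meta.tsv`.
#' @return Invisibly, the directory.
#' @export
write_cell_counts <- function(cc, dir) {
  stopifnot(inherits(cc, "cell_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(cc$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cc$counts), file.path(dir, "genes.txt"))
  writeLines(colnames(cc$counts), file.path(dir, "barcodes.txt"))
  utils::write.table(
    data.frame(cell_id = colnames(cc$counts), sample_id = cc$cell_sample),
    file.path(dir, "cell_meta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cc$sample_group),
               group = unname(cc$sample_group)),
    file.path(dir, "sample_meta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
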