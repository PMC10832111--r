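#' Write / read a cell table as MTX + TSV
#'
#' The common exchange layout for sparse single-cell counts:
#' `matrix.mtx` (genes x cells), `genes.tsv` (gene metadata),
#' `barcodes.tsv` (cell metadata including the QC fields).
#'
#' @param cells A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_mtx <- function(cells, dir) {
  stopifnot(methods::is(cells, "SingleCellExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(SummarizedExperiment::assay(cells, "counts"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(as.data.frame(SummarizedExperiment::rowData(cells)),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(cells))
  cd <- cbind(barcode = colnames(cells), cd)
  write.table(cd, file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_mtx
#' @return For `read_cell_mtx`, the reconstructed `SingleCellExperiment`.
#' @export
read_cell_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"))
  cells <- read.delim(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes$gene_id, cells$barcode)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cells[, -1, drop = FALSE],
                                   row.names = cells$barcode),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id))
}

#' Write / read a bulk survival cohort as CSV
#'
#' `expression.csv` holds the samples-by-genes matrix (first column
#' `sample`); `survival.csv` holds `sample`, `os_time`, `os_event`.
#'
#' @param cohort A [cohort_table()].
#' @param dir Output directory.
#' @return `dir`, invisibly; `read_cohort_csv` returns a [cohort_table()].
#' @param standardize Passed to [cohort_table()] on read; the default
#'   re-standardizes, which is a no-op on an already standardized cohort.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cbind(data.frame(sample = rownames(cohort$expr)),
                  as.data.frame(cohort$expr)),
            file.path(dir, "expression.csv"), row.names = FALSE)
  write.csv(data.frame(sample = rownames(cohort$expr),
                       os_time = cohort$os_time, os_event = cohort$os_event),
            file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir, standardize = TRUE) {
  ex <- read.csv(file.path(dir, "expression.csv"), check.names = FALSE)
  sv <- read.csv(file.path(dir, "survival.csv"))
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex$sample
  sv <- sv[match(ex$sample, sv$sample), ]
  cohort_table(m, sv$os_time, sv$os_event, standardize = standardize)
}

#' Write / read a spatial grid as CSV
#'
#' `coords.csv`: `spot_id`, `x`, `y`, `lattice`; `abundance.csv`:
#' cell-type-by-spot matrix (first column `cell_type`).
#'
#' @param grid A [spatial_grid()].
#' @param dir Output directory.
#' @return `dir`, invisibly; `read_spatial_csv` returns a
#'   [spatial_grid()].
#' @export
write_spatial_csv <- function(grid, dir) {
  stopifnot(inherits(grid, "spatial_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cbind(grid$coords, lattice = grid$lattice),
            file.path(dir, "coords.csv"), row.names = FALSE)
  write.csv(cbind(data.frame(cell_type = rownames(grid$abundance)),
                  as.data.frame(grid$abundance)),
            file.path(dir, "abundance.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spatial_csv
#' @export
read_spatial_csv <- function(dir) {
  co <- read.csv(file.path(dir, "coords.csv"))
  ab <- read.csv(file.path(dir, "abundance.csv"), check.names = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$cell_type
  spatial_grid(co[, c("spot_id", "x", "y")], m, lattice = co$lattice[1])
}

#' Write a marker table as TSV
#'
#' @param markers Output of [rank_markers()] / [refine_markers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
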