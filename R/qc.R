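#' Quality-control thresholds for cell filtering
#'
#' Boundary semantics follow the criteria as stated: UMI and mitochondrial
#' thresholds are strict (`total_umi > min_umi`, `pct_mito < max_pct_mito`)
#' while the detected-gene range is inclusive
#' (`min_genes <= n_genes_detected <= max_genes`).
#'
#' @param min_umi Minimum UMI total (exclusive). Default 2000.
#' @param min_genes,max_genes Inclusive range of detected genes.
#'   Defaults 500 and 7000.
#' @param max_pct_mito Maximum mitochondrial percentage (exclusive).
#'   Default 10.
#' @param require_singlet Keep only predicted singlets. Default `TRUE`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_umi = 2000, min_genes = 500, max_genes = 7000,
                      max_pct_mito = 10, require_singlet = TRUE) {
  stopifnot(min_genes < max_genes, min_umi > 0, max_pct_mito > 0)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_genes = max_genes, max_pct_mito = max_pct_mito,
                 require_singlet = isTRUE(require_singlet)),
            class = "qc_config")
}

#' Filter cells on quality-control criteria
#'
#' Retains exactly the cells with `total_umi > min_umi`,
#' `min_genes <= n_genes_detected <= max_genes`, `pct_mito < max_pct_mito`
#' and, when `require_singlet`, a singlet prediction. The number of cells
#' removed by each criterion (counted independently, so a cell can appear
#' in several tallies) is recorded in `metadata(.)$qc_log`.
#'
#' @param cells A `SingleCellExperiment` whose `colData` carries the QC
#'   fields `total_umi`, `n_genes_detected`, `pct_mito`, `is_singlet`.
#' @param qc A [qc_config()].
#' @return The filtered `SingleCellExperiment`. Idempotent: filtering twice
#'   equals filtering once.
#' @examples
#' # full-scale genes so healthy cells clear the default thresholds
#' sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 50,
#'                                  qc_fail_fraction = 0.1))
#' kept <- filter_cells(sim$cells)
#' setequal(setdiff(colnames(sim$cells), colnames(kept)),
#'          sim$truth$qc_fail_cells)
#' @export
filter_cells <- function(cells, qc = qc_config()) {
  stopifnot(methods::is(cells, "SingleCellExperiment"), inherits(qc, "qc_config"))
  cd <- SummarizedExperiment::colData(cells)
  needed <- c("total_umi", "n_genes_detected", "pct_mito", "is_singlet")
  missing <- setdiff(needed, colnames(cd))
  if (length(missing))
    stop("colData is missing QC field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pass_umi <- cd$total_umi > qc$min_umi
  pass_genes <- cd$n_genes_detected >= qc$min_genes &
    cd$n_genes_detected <= qc$max_genes
  pass_mito <- cd$pct_mito < qc$max_pct_mito
  pass_singlet <- if (qc$require_singlet) cd$is_singlet else rep(TRUE, ncol(cells))
  keep <- pass_umi & pass_genes & pass_mito & pass_singlet
  out <- cells[, keep]
  S4Vectors::metadata(out)$qc_log <- list(
    n_input = ncol(cells), n_kept = sum(keep),
    removed_umi = sum(!pass_umi), removed_genes = sum(!pass_genes),
    removed_mito = sum(!pass_mito), removed_doublet = sum(!pass_singlet),
    qc = qc)
  out
}

#' Total-count normalize and log-transform
#'
#' Adds a `logcounts` assay with
#' `log(1 + target_sum * counts[g, c] / total_counts[c])`, the standard
#' library-size normalization. The `counts` assay is left untouched.
#'
#' @param cells A `SingleCellExperiment` with a `counts` assay.
#' @param target_sum Library size every cell is scaled to. Default 10000,
#'   the usual convention.
#' @return `cells` with a `logcounts` assay added.
#' @export
normalize_log <- function(cells, target_sum = 1e4) {
  stopifnot(methods::is(cells, "SingleCellExperiment"))
  target_sum <- .assert_positive(target_sum, "target_sum")
  cts <- SummarizedExperiment::assay(cells, "counts")
  tot <- Matrix::colSums(cts)
  if (any(tot == 0))
    stop("cannot normalize: cell(s) with zero total counts: ",
         paste(head(colnames(cells)[tot == 0], 5), collapse = ", "),
         call. = FALSE)
  scaled <- cts %*% Matrix::Diagonal(x = target_sum / tot)
  dimnames(scaled) <- dimnames(cts)
  SingleCellExperiment::logcounts(cells) <- log1p(scaled)
  cells
}
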