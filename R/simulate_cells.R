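## Number of genes in the shared cycling program and its fold change.
## The program is deliberately strong: cycling transcriptomes converge, which
## is exactly why parent identities must be recovered by label transfer.
.CYCLE_N_GENES <- 30L
.CYCLE_FOLD <- 8

## Fraction of genes flagged mitochondrial (disjoint from markers and the
## cycling program so planted signals never collide with QC metadata).
.MITO_FRACTION <- 0.05

#' Simulate a clustered single-cell count matrix with recorded ground truth
#'
#' Draws negative-binomial counts for `n_clusters` subclusters with disjoint
#' planted marker sets (markers have mean `nb_mean * marker_fold_change`
#' inside their own subcluster, baseline elsewhere), appends a cycling
#' population whose cells are sampled from parent subclusters with a shared
#' 30-gene cycling program superposed, assigns patients round-robin, and
#' optionally plants quality-control failures, each violating exactly one
#' criterion (UMI total thinned below 2000; detected genes collapsed below
#' 500; mitochondrial percentage raised above 10; or doublet flag).
#'
#' Per-gene baseline means are log-normal around `nb_mean` (mean-preserving,
#' sdlog 0.5), a standard model of gene-level expression heterogeneity.
#' All QC metadata except the doublet flag are computed from the final count
#' matrix, so planted violations are consistent with the counts themselves.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{cells}{A [SingleCellExperiment::SingleCellExperiment] with a
#'       sparse `counts` assay; `colData` columns `patient_id`,
#'       `cluster_label`, `major_type`, `total_umi`, `n_genes_detected`,
#'       `pct_mito`, `is_singlet`; `rowData` columns `gene_id`, `is_mito`.}
#'     \item{truth}{Ground-truth record: `planted_markers` (cluster -> gene
#'       ids), `cycle_genes`, `parent_of_cycling_cell` (named by cell),
#'       `qc_fail_cells`, `qc_fail_modes`, and `cluster_profiles`, the
#'       gene-by-cluster matrix of true negative-binomial means (reusable as
#'       mixture components by [simulate_cohort()]).}
#'   }
#' @examples
#' sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 40,
#'                                  n_genes = 200, cycling_fraction = 0))
#' table(SummarizedExperiment::colData(sim$cells)$cluster_label)
#' @seealso [filter_cells()], [rank_markers()], [transfer_labels()]
#' @export
simulate_cells <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  K <- config$n_clusters
  n_mark <- config$n_markers_per_cluster
  n_mito <- max(1L, floor(.MITO_FRACTION * G))
  if (K * n_mark + .CYCLE_N_GENES + n_mito > G)
    stop("configuration error: n_genes too small to hold disjoint marker, ",
         "cycling and mitochondrial gene sets", call. = FALSE)

  gene_ids <- sprintf("gene%04d", seq_len(G))
  clusters <- sprintf("C%02d", seq_len(K))
  marker_idx <- split(seq_len(K * n_mark), rep(seq_len(K), each = n_mark))
  cycle_idx <- K * n_mark + seq_len(.CYCLE_N_GENES)
  mito_idx <- G - n_mito + seq_len(n_mito)

  ## mean-preserving log-normal per-gene baselines
  sdlog <- 0.5
  base_mu <- config$nb_mean * exp(rnorm(G, 0, sdlog) - sdlog^2 / 2)
  profiles <- matrix(base_mu, nrow = G, ncol = K,
                     dimnames = list(gene_ids, clusters))
  for (k in seq_len(K))
    profiles[marker_idx[[k]], k] <- base_mu[marker_idx[[k]]] * config$marker_fold_change

  size <- 1 / config$nb_dispersion
  n_per <- config$n_cells_per_cluster
  draw_block <- function(mu, n) {
    matrix(rnbinom(length(mu) * n, mu = mu, size = size), nrow = length(mu))
  }
  blocks <- lapply(seq_len(K), function(k) draw_block(profiles[, k], n_per))
  cluster_label <- rep(clusters, each = n_per)

  n_cycling <- round(config$cycling_fraction * K * n_per)
  parent <- character(0)
  if (n_cycling > 0) {
    parent <- sample(clusters, n_cycling, replace = TRUE)
    cyc <- vapply(parent, function(k) {
      mu <- profiles[, k]
      mu[cycle_idx] <- mu[cycle_idx] * .CYCLE_FOLD
      rnbinom(G, mu = mu, size = size)
    }, numeric(G))
    blocks <- c(blocks, list(cyc))
    cluster_label <- c(cluster_label, rep("Cycling", n_cycling))
  }
  counts <- do.call(cbind, blocks)
  n_cells <- ncol(counts)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)
  names(parent) <- if (n_cycling > 0) cell_ids[cluster_label == "Cycling"] else character(0)

  is_singlet <- rep(TRUE, n_cells)
  n_fail <- round(config$qc_fail_fraction * n_cells)
  fail_cells <- character(0)
  fail_modes <- character(0)
  if (n_fail > 0) {
    fail_pos <- sort(sample.int(n_cells, n_fail))
    fail_cells <- cell_ids[fail_pos]
    fail_modes <- rep_len(c("umi", "genes", "mito", "singlet"), n_fail)
    for (i in seq_len(n_fail)) {
      j <- fail_pos[i]
      col <- counts[, j]
      switch(fail_modes[i],
        umi = {
          target <- sample(1200:1800, 1L)
          counts[, j] <- rbinom(G, size = col, prob = min(1, target / sum(col)))
        },
        genes = {
          keep <- head(setdiff(order(col, decreasing = TRUE), mito_idx), 400L)
          col[setdiff(seq_len(G), keep)] <- 0L
          if (sum(col) <= 2100) col[keep] <- col[keep] * ceiling(2200 / max(sum(col), 1))
          counts[, j] <- col
        },
        mito = {
          tot <- sum(col)
          extra <- ceiling(max(0, 0.13 * tot - sum(col[mito_idx])) / 0.87)
          col[mito_idx[1L]] <- col[mito_idx[1L]] + extra
          counts[, j] <- col
        },
        singlet = {
          is_singlet[j] <- FALSE
        })
    }
  }

  total_umi <- colSums(counts)
  cd <- S4Vectors::DataFrame(
    patient_id = sprintf("P%02d", (seq_len(n_cells) - 1L) %% config$n_patients + 1L),
    cluster_label = cluster_label,
    major_type = ifelse(cluster_label %in% clusters[seq_len(ceiling(K / 2))] |
                          cluster_label == "Cycling", "Epithelial", "Fibroblast"),
    total_umi = total_umi,
    n_genes_detected = colSums(counts > 0),
    pct_mito = 100 * colSums(counts[mito_idx, , drop = FALSE]) / total_umi,
    is_singlet = is_singlet,
    row.names = cell_ids)
  rd <- S4Vectors::DataFrame(
    gene_id = gene_ids,
    is_mito = seq_len(G) %in% mito_idx,
    row.names = gene_ids)

  cells <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = cd, rowData = rd)

  truth <- structure(list(
    planted_markers = setNames(lapply(marker_idx, function(ix) gene_ids[ix]), clusters),
    cycle_genes = gene_ids[cycle_idx],
    parent_of_cycling_cell = parent,
    qc_fail_cells = fail_cells,
    qc_fail_modes = setNames(fail_modes, fail_cells),
    cluster_profiles = profiles,
    config = config), class = "ground_truth")

  list(cells = cells, truth = truth)
}
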