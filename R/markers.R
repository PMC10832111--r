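#' Rank cluster marker genes by specificity gap score
#'
#' For every gene the per-cluster mean log-normalized expression is computed
#' and max-normalized by the top-expressing cluster (top value set to 1).
#' The gap score, `1 -` the second-highest normalized value, measures how
#' specifically the gene marks its top cluster. A gene is a marker
#' *candidate* for its top cluster when the top-cluster mean exceeds
#' `min_top_mean` and the fraction of top-cluster cells expressing it
#' exceeds `min_fraction`; candidates are ranked by gap, tested by a
#' two-sided Wilcoxon rank-sum test (top cluster vs all other cells,
#' normal approximation without continuity correction) and
#' Benjamini-Hochberg adjusted across the candidate list.
#'
#' Genes whose per-cluster means are all zero are dropped. Ties for the top
#' cluster are broken by the higher expressing fraction, then by cluster
#' name, so the ranking is deterministic.
#'
#' @param cells A normalized `SingleCellExperiment` (see [normalize_log()]).
#' @param grouping Cluster labels: either a `colData` column name or a
#'   vector with one label per cell. Default `"cluster_label"`. At least
#'   two clusters are required.
#' @param min_top_mean Minimum mean log-normalized expression in the top
#'   cluster (exclusive). Default 0.4.
#' @param min_fraction Minimum expressing fraction in the top cluster
#'   (exclusive). Default 0.10.
#' @param alpha Adjusted-p threshold below which a candidate is flagged a
#'   final marker. Default 0.05.
#' @return A `data.frame` with one row per retained gene, columns
#'   `gene_id`, `cluster`, `top_mean`, `second_norm`, `gap`,
#'   `expr_fraction`, `candidate`, `pvalue`, `p_adj`, `final`, `refined`
#'   (`NA` until [refine_markers()]); rows ordered by cluster, candidacy,
#'   then gap descending.
#' @examples
#' sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 60,
#'                                  n_genes = 300, cycling_fraction = 0))
#' mk <- rank_markers(normalize_log(sim$cells))
#' head(mk[mk$candidate, c("gene_id", "cluster", "gap")])
#' @export
rank_markers <- function(cells, grouping = "cluster_label",
                         min_top_mean = 0.4, min_fraction = 0.10,
                         alpha = 0.05) {
  stopifnot(methods::is(cells, "SingleCellExperiment"))
  if (!"logcounts" %in% SummarizedExperiment::assayNames(cells))
    stop("no 'logcounts' assay; run normalize_log() first", call. = FALSE)
  groups <- .resolve_grouping(cells, grouping)
  lvls <- sort(unique(groups))
  if (length(lvls) < 2L)
    stop("marker ranking needs at least two clusters", call. = FALSE)

  ln <- SingleCellExperiment::logcounts(cells)
  ind <- Matrix::sparseMatrix(i = seq_along(groups),
                              j = match(groups, lvls), x = 1,
                              dims = c(length(groups), length(lvls)))
  n_k <- Matrix::colSums(ind)
  means <- as.matrix(ln %*% ind %*% Matrix::Diagonal(x = 1 / n_k))
  fracs <- as.matrix((ln > 0) %*% ind %*% Matrix::Diagonal(x = 1 / n_k))
  colnames(means) <- colnames(fracs) <- lvls

  keep <- Matrix::rowSums(means) > 0
  means <- means[keep, , drop = FALSE]
  fracs <- fracs[keep, , drop = FALSE]
  gene_ids <- rownames(cells)[keep]

  top_k <- integer(nrow(means))
  for (g in seq_len(nrow(means))) {
    cand <- which(means[g, ] == max(means[g, ]))
    if (length(cand) > 1L)
      cand <- cand[order(-fracs[g, cand], lvls[cand])]
    top_k[g] <- cand[1L]
  }
  top_mean <- means[cbind(seq_along(top_k), top_k)]
  second <- vapply(seq_along(top_k), function(g)
    max(means[g, -top_k[g]]), numeric(1))
  second_norm <- second / top_mean
  gap <- 1 - second_norm
  expr_fraction <- fracs[cbind(seq_along(top_k), top_k)]
  candidate <- top_mean > min_top_mean & expr_fraction > min_fraction

  res <- data.frame(
    gene_id = gene_ids, cluster = lvls[top_k], top_mean = top_mean,
    second_norm = second_norm, gap = gap, expr_fraction = expr_fraction,
    candidate = candidate, pvalue = NA_real_, p_adj = NA_real_,
    final = FALSE, refined = NA, row.names = NULL)

  if (any(candidate)) {
    sub <- as.matrix(ln[gene_ids[candidate], , drop = FALSE])
    in_top <- outer(res$cluster[candidate], groups, "==")
    pv <- vapply(seq_len(nrow(sub)), function(i)
      wilcox.test(sub[i, in_top[i, ]], sub[i, !in_top[i, ]],
                  exact = FALSE, correct = FALSE)$p.value, numeric(1))
    res$pvalue[candidate] <- pv
    res$p_adj[candidate] <- p.adjust(pv, method = "BH")
    res$final <- !is.na(res$p_adj) & res$p_adj < alpha
  }
  res[order(res$cluster, -res$candidate, -res$gap, res$gene_id), ]
}

#' @noRd
.resolve_grouping <- function(cells, grouping) {
  if (is.character(grouping) && length(grouping) == 1L) {
    cd <- SummarizedExperiment::colData(cells)
    if (!grouping %in% colnames(cd))
      stop("grouping column '", grouping, "' not found in colData", call. = FALSE)
    as.character(cd[[grouping]])
  } else {
    stopifnot(length(grouping) == ncol(cells))
    as.character(grouping)
  }
}

#' Top candidate markers per cluster
#'
#' Convenience accessor: the `n` highest-gap candidates of each cluster.
#'
#' @param markers Output of [rank_markers()].
#' @param n Markers to keep per cluster.
#' @return Subset of `markers`, gap-ordered within cluster.
#' @export
top_markers <- function(markers, n = 20L) {
  cand <- markers[markers$candidate, ]
  cand <- cand[order(cand$cluster, -cand$gap, cand$gene_id), ]
  do.call(rbind, lapply(split(cand, cand$cluster), head, n = n))
}

#' Refine markers against leakage into other major cell types
#'
#' Bulk tissue mixes all major cell types, so a subcluster marker is only
#' usable for bulk scoring if it is not broadly expressed outside its own
#' compartment. A marker's `refined` flag is set when, for every *other*
#' major type, the mean log-normalized expression is below
#' `leakage_ratio * top_mean`. This makes the curation step an explicit,
#' reproducible rule with the tolerated leakage exposed as a parameter.
#'
#' @param markers Output of [rank_markers()].
#' @param cells The normalized `SingleCellExperiment` the markers came from.
#' @param major_grouping Major-type labels: `colData` column name or vector
#'   per cell. Default `"major_type"`.
#' @param leakage_ratio Tolerated expression in another major type,
#'   relative to the marker's top-cluster mean. Default 0.5; a very large
#'   value disables refinement (all markers kept).
#' @return `markers` with the `refined` column filled in.
#' @export
refine_markers <- function(markers, cells, major_grouping = "major_type",
                           leakage_ratio = 0.5) {
  stopifnot(methods::is(cells, "SingleCellExperiment"), leakage_ratio >= 0)
  majors <- .resolve_grouping(cells, major_grouping)
  clusters <- .resolve_grouping(cells, "cluster_label")
  ## a subcluster belongs to the major type of (the majority of) its cells
  cl2major <- vapply(split(majors, clusters), function(m)
    names(sort(table(m), decreasing = TRUE))[1L], character(1))

  ln <- SingleCellExperiment::logcounts(cells)
  lvls <- sort(unique(majors))
  ind <- Matrix::sparseMatrix(i = seq_along(majors), j = match(majors, lvls),
                              x = 1, dims = c(length(majors), length(lvls)))
  major_means <- as.matrix(ln %*% ind %*% Matrix::Diagonal(x = 1 / Matrix::colSums(ind)))
  colnames(major_means) <- lvls

  home <- cl2major[markers$cluster]
  ok <- vapply(seq_len(nrow(markers)), function(i) {
    others <- setdiff(lvls, home[i])
    if (!length(others)) return(TRUE)
    all(major_means[markers$gene_id[i], others] <
          leakage_ratio * markers$top_mean[i])
  }, logical(1))
  markers$refined <- ok
  markers
}

#' Average-expression gene-set signature score
#'
#' The score of an observation (cell or bulk sample) is the arithmetic mean
#' of its expression values over the genes of the set. Set genes absent
#' from the matrix are dropped with a warning; if none are present this is
#' an error.
#'
#' @param x A `SingleCellExperiment` (uses `logcounts`; per-cell scores), a
#'   [cohort_table()] (uses standardized expression; per-sample scores), or
#'   a genes-by-observations numeric matrix.
#' @param gene_set Character vector of gene identifiers.
#' @return Named numeric vector of scores, one per observation.
#' @examples
#' m <- matrix(c(2, 4), nrow = 2, dimnames = list(c("a", "b"), "cell1"))
#' score_gene_set(m, c("a", "b"))  # 3
#' @export
score_gene_set <- function(x, gene_set) UseMethod("score_gene_set")

#' @export
score_gene_set.default <- function(x, gene_set) {
  stopifnot(is.matrix(x) || methods::is(x, "Matrix"))
  present <- intersect(gene_set, rownames(x))
  if (!length(present))
    stop("none of the ", length(gene_set), " set genes are present", call. = FALSE)
  if (length(present) < length(unique(gene_set)))
    warning(length(unique(gene_set)) - length(present),
            " set gene(s) absent from the matrix; dropped", call. = FALSE)
  Matrix::colMeans(x[present, , drop = FALSE])
}

#' @export
score_gene_set.SingleCellExperiment <- function(x, gene_set) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
    stop("no 'logcounts' assay; run normalize_log() first", call. = FALSE)
  score_gene_set(SingleCellExperiment::logcounts(x), gene_set)
}
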