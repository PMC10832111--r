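#' Transfer parent identities onto cycling cells
#'
#' Proliferating cells converge transcriptionally on a shared cell-cycle
#' program, which masks their subcluster of origin. To recover it, a
#' multinomial ridge classifier ([glmnet::glmnet()], alpha = 0, fixed
#' penalty) is trained on the log-normalized profiles of non-cycling
#' reference cells — with the cell-cycle genes excluded from the features —
#' and applied to the cycling cells. Accuracy on a held-out 20% of the
#' reference cells is reported alongside the predictions.
#'
#' The ridge penalty is fixed at `lambda = 1 / n_train` (the unit-cost
#' equivalent) so the fit is deterministic and hyperparameter-free.
#'
#' @param cells A normalized `SingleCellExperiment` with `cluster_label`
#'   in `colData`.
#' @param cycling_cluster Label of the cycling cluster (e.g. `"Cycling"`).
#' @param exclude_genes Cell-cycle genes removed from the features: the
#'   generator's cycle-gene list for synthetic data, or a user-supplied
#'   list for real data.
#' @param holdout_fraction Fraction of reference cells held out for the
#'   reported accuracy. Default 0.2.
#' @param seed Seed controlling the holdout split. Default 1.
#' @return List with `labels` (named character vector, one parent per
#'   cycling cell), `holdout_accuracy`, and `reference_levels`. Reference
#'   clusters with fewer than 10 cells trigger a warning; fewer than two
#'   reference clusters is an error.
#' @export
transfer_labels <- function(cells, cycling_cluster, exclude_genes = character(0),
                            holdout_fraction = 0.2, seed = 1L) {
  stopifnot(methods::is(cells, "SingleCellExperiment"))
  if (!"logcounts" %in% SummarizedExperiment::assayNames(cells))
    stop("no 'logcounts' assay; run normalize_log() first", call. = FALSE)
  groups <- .resolve_grouping(cells, "cluster_label")
  if (!cycling_cluster %in% groups)
    stop("cycling cluster '", cycling_cluster, "' not present", call. = FALSE)
  is_cyc <- groups == cycling_cluster
  ref_labels <- groups[!is_cyc]
  lvls <- sort(unique(ref_labels))
  if (length(lvls) < 2L)
    stop("need at least two non-cycling reference clusters", call. = FALSE)
  small <- names(which(table(ref_labels) < 10))
  if (length(small))
    warning("reference cluster(s) with < 10 cells: ",
            paste(small, collapse = ", "), call. = FALSE)

  feats <- setdiff(rownames(cells), exclude_genes)
  ln <- SingleCellExperiment::logcounts(cells)[feats, , drop = FALSE]
  X_ref <- Matrix::t(ln[, !is_cyc, drop = FALSE])
  X_cyc <- Matrix::t(ln[, is_cyc, drop = FALSE])

  set.seed(seed)
  n_ref <- nrow(X_ref)
  holdout <- sample.int(n_ref, max(1L, round(holdout_fraction * n_ref)))
  train <- setdiff(seq_len(n_ref), holdout)
  lambda <- 1 / length(train)
  fit <- glmnet::glmnet(X_ref[train, , drop = FALSE],
                        factor(ref_labels[train], levels = lvls),
                        family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  pred_class <- function(X) {
    p <- predict(fit, X, type = "class")
    as.character(p[, 1L])
  }
  acc <- mean(pred_class(X_ref[holdout, , drop = FALSE]) == ref_labels[holdout])
  labels <- if (any(is_cyc)) pred_class(X_cyc) else character(0)
  names(labels) <- colnames(cells)[is_cyc]
  list(labels = labels, holdout_accuracy = acc, reference_levels = lvls)
}

#' Cycling-population enrichment of subclusters
#'
#' Compares each subcluster's share of the cycling compartment with its
#' share of the non-cycling compartment: `enrichment = frac_cycling /
#' frac_noncycling`, tested per subcluster by a two-sided two-proportion
#' z-test with pooled variance (no continuity correction). A subcluster is
#' called `enriched` when enrichment > 1 and p < `alpha`, `depleted` when
#' enrichment < 1 and p < `alpha`, otherwise `ns`. No multiplicity
#' correction is applied by default; set `correct = "BH"` (or any
#' [stats::p.adjust()] method) to adjust across subclusters.
#'
#' @param parent_labels Parent subcluster of each cycling cell (e.g. from
#'   [transfer_labels()]).
#' @param noncycling_labels Subcluster labels of the non-cycling cells.
#' @param alpha Significance level for the calls. Default 0.05.
#' @param correct Multiple-testing correction method, `"none"` by default.
#' @return `data.frame` with columns `cluster`, `n_cycling`,
#'   `n_noncycling`, `frac_cycling`, `frac_noncycling`, `enrichment`
#'   (`Inf`, flagged in `undefined`, for a cluster absent from the
#'   non-cycling compartment), `z`, `pvalue`, `p_adj`, `call`.
#' @examples
#' cycling_enrichment(rep(c("A", "B"), c(30, 70)),
#'                    rep(c("A", "B"), c(100, 900)))
#' @export
cycling_enrichment <- function(parent_labels, noncycling_labels,
                               alpha = 0.05, correct = "none") {
  stopifnot(length(parent_labels) > 0, length(noncycling_labels) > 0)
  alpha <- .assert_fraction(alpha, "alpha")
  clusters <- sort(unique(c(parent_labels, noncycling_labels)))
  n1 <- length(parent_labels)
  n2 <- length(noncycling_labels)
  x1 <- vapply(clusters, function(k) sum(parent_labels == k), numeric(1))
  x2 <- vapply(clusters, function(k) sum(noncycling_labels == k), numeric(1))
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z[p1 == p2] <- 0  # includes the degenerate pooled in {0,1} case
  pv <- 2 * pnorm(-abs(z))
  padj <- p.adjust(pv, method = correct)
  enr <- p1 / p2
  res <- data.frame(
    cluster = clusters, n_cycling = x1, n_noncycling = x2,
    frac_cycling = p1, frac_noncycling = p2,
    enrichment = enr, undefined = p2 == 0, z = z, pvalue = pv, p_adj = padj,
    call = ifelse(padj < alpha & enr > 1, "enriched",
                  ifelse(padj < alpha & enr < 1, "depleted", "ns")),
    row.names = NULL)
  res
}
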