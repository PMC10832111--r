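#' Patient-level subcluster composition matrix
#'
#' For each patient and compartment (e.g. cancer cells vs CAFs), the
#' proportion of the compartment's cells in each subcluster. Proportions
#' sum to 1 within a compartment for every patient with cells in it;
#' patients with no cells in a compartment get a zero row and are flagged.
#'
#' @param cells A `SingleCellExperiment` with `patient_id` and
#'   `cluster_label` in `colData`.
#' @param compartment_map Named character vector mapping subcluster labels
#'   to compartments; subclusters absent from the map are dropped.
#' @return A `composition_matrix`: patients-by-subclusters proportion
#'   matrix with attributes `compartment` (per column) and `empty`
#'   (logical patients-by-compartments flag matrix).
#' @examples
#' sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 40,
#'                                  n_genes = 200, cycling_fraction = 0))
#' comp <- composition_matrix(sim$cells, c(C01 = "cancer", C02 = "CAF"))
#' rowSums(comp)
#' @export
composition_matrix <- function(cells, compartment_map) {
  stopifnot(methods::is(cells, "SingleCellExperiment"),
            !is.null(names(compartment_map)))
  cd <- SummarizedExperiment::colData(cells)
  stopifnot(all(c("patient_id", "cluster_label") %in% colnames(cd)))
  keep <- cd$cluster_label %in% names(compartment_map)
  patient <- as.character(cd$patient_id)[keep]
  cluster <- as.character(cd$cluster_label)[keep]
  patients <- sort(unique(as.character(cd$patient_id)))
  subclusters <- sort(names(compartment_map))
  compartments <- compartment_map[subclusters]

  counts <- table(factor(patient, levels = patients),
                  factor(cluster, levels = subclusters))
  counts <- matrix(as.numeric(counts), nrow = length(patients),
                   dimnames = list(patients, subclusters))
  prop <- counts
  empty <- matrix(FALSE, length(patients), length(unique(compartments)),
                  dimnames = list(patients, unique(compartments)))
  for (cp in unique(compartments)) {
    cols <- subclusters[compartments == cp]
    tot <- rowSums(counts[, cols, drop = FALSE])
    empty[, cp] <- tot == 0
    prop[, cols] <- counts[, cols, drop = FALSE] / ifelse(tot > 0, tot, 1)
  }
  structure(prop, compartment = compartments, empty = empty,
            class = c("composition_matrix", class(prop)))
}

#' Hierarchical patient stratification on composition
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances, the
#' standard choice for composition heatmaps) of the concatenated
#' compartment proportions, cut at `k` groups. Group labels are renumbered
#' `hClust0, hClust1, ...` by decreasing group size (ties by first patient
#' name), so the labelling does not depend on patient order.
#'
#' @param comp A [composition_matrix()] (or plain numeric matrix,
#'   patients in rows).
#' @param k Number of patient groups. Default 3.
#' @param method Linkage passed to [stats::hclust()]. Default `"ward.D2"`.
#' @return Named character vector of group labels, one per patient.
#' @export
cluster_patients <- function(comp, k = 3L, method = "ward.D2") {
  k <- .assert_count(k, "k")
  m <- unclass(comp)
  attr(m, "compartment") <- attr(m, "empty") <- NULL
  if (k > nrow(m))
    stop("k exceeds the number of patients", call. = FALSE)
  hc <- hclust(dist(m, method = "euclidean"), method = method)
  grp <- cutree(hc, k = k)
  ## order-independent relabelling: by size, then lexicographically first member
  info <- data.frame(
    old = unique(grp),
    size = as.vector(table(grp)[as.character(unique(grp))]),
    first = vapply(unique(grp), function(g) min(rownames(m)[grp == g]),
                   character(1)))
  info <- info[order(-info$size, info$first), ]
  relabel <- setNames(paste0("hClust", seq_len(k) - 1L), info$old)
  setNames(relabel[as.character(grp)], rownames(m))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the positive entries of a composition
#' vector (natural log by default). Zero for a single-subcluster
#' composition; maximal, `log(k)`, for the uniform composition over `k`
#' subclusters.
#'
#' @param proportions Non-negative proportions summing to 1
#'   (tolerance 1e-6).
#' @param base Logarithm base. Default `exp(1)`.
#' @return The diversity `H >= 0`.
#' @examples
#' shannon_index(c(1, 0, 0))       # 0
#' shannon_index(rep(1 / 4, 4))    # log(4)
#' @export
shannon_index <- function(proportions, base = exp(1)) {
  if (any(proportions < 0))
    stop("proportions must be non-negative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1", call. = FALSE)
  p <- proportions[proportions > 0]
  -sum(p * log(p, base = base))
}

#' Per-patient Shannon diversity of a compartment
#'
#' Applies [shannon_index()] to each patient's composition within one
#' compartment of a [composition_matrix()].
#'
#' @param comp A [composition_matrix()].
#' @param compartment Compartment name to restrict to; `NULL` uses all
#'   columns (only sensible for a single-compartment matrix).
#' @return `data.frame` with columns `patient`, `compartment`, `H`
#'   (`NA` for patients with no cells in the compartment).
#' @export
compartment_diversity <- function(comp, compartment = NULL) {
  stopifnot(inherits(comp, "composition_matrix"))
  cp_of <- attr(comp, "compartment")
  empty <- attr(comp, "empty")
  if (is.null(compartment)) compartment <- unique(cp_of)
  out <- lapply(compartment, function(cp) {
    cols <- names(cp_of)[cp_of == cp]
    H <- vapply(rownames(comp), function(pt) {
      if (empty[pt, cp]) return(NA_real_)
      shannon_index(unclass(comp)[pt, cols])
    }, numeric(1))
    data.frame(patient = rownames(comp), compartment = cp, H = H,
               row.names = NULL)
  })
  do.call(rbind, out)
}
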