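#' High spots of a cell type
#'
#' Spots whose deconvolved abundance for `cell_type` strictly exceeds
#' `threshold` (the usual rule for 5%-quantile abundance estimates is
#' `> 3`; a spot at exactly the threshold is excluded).
#'
#' @param grid A [spatial_grid()].
#' @param cell_type Row name of the abundance matrix.
#' @param threshold Strict abundance threshold. Default 3.
#' @return Character vector of spot ids (possibly empty).
#' @export
find_high_spots <- function(grid, cell_type, threshold = 3) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (!cell_type %in% rownames(grid$abundance))
    stop("unknown cell type: ", cell_type, call. = FALSE)
  colnames(grid$abundance)[grid$abundance[cell_type, ] > threshold]
}

#' Distance-shell neighborhood of a spot
#'
#' The neighborhood is defined by distance shells: all spots (excluding the
#' focal one) whose center-to-center distance equals one of the `n_shells`
#' smallest distinct distances realized from that spot. On a lattice this
#' is deterministic where a k-nearest-spots rule would be tie-degenerate;
#' an interior square-lattice spot with `n_shells = 3` has 12 neighbors
#' (4 at distance 1, 4 at sqrt(2), 4 at 2) and an interior hex spot with
#' `n_shells = 1` has 6.
#'
#' Distances are grouped into shells with a relative tolerance of 1e-8 to
#' absorb floating-point noise in hex coordinates.
#'
#' @param grid A [spatial_grid()].
#' @param spot A spot id.
#' @param n_shells Number of shells. Default 3.
#' @return Character vector of neighbor spot ids.
#' @export
neighbor_shells <- function(grid, spot, n_shells = 3L) {
  stopifnot(inherits(grid, "spatial_grid"))
  n_shells <- .assert_count(n_shells, "n_shells")
  i <- match(spot, grid$coords$spot_id)
  if (is.na(i)) stop("unknown spot: ", spot, call. = FALSE)
  d <- sqrt((grid$coords$x - grid$coords$x[i])^2 +
              (grid$coords$y - grid$coords$y[i])^2)
  pos <- d > 0
  if (!any(pos)) {
    warning("spot ", spot, " is isolated; empty neighborhood", call. = FALSE)
    return(character(0))
  }
  ## distinct realized distances, grouped with a relative tolerance
  dd <- sort(d[pos])
  shell_edges <- dd[c(TRUE, diff(dd) > 1e-8 * dd[-length(dd)])]
  cut_d <- shell_edges[min(n_shells, length(shell_edges))]
  grid$coords$spot_id[pos & d <= cut_d * (1 + 1e-8)]
}

#' Neighborhood enrichment profile of a focal cell type
#'
#' For each high spot of the focal type, the abundances of all cell types
#' are summed over the spot's shell neighborhood (observed) and compared
#' with the expected sum — the number of neighbors times the average
#' abundance of that type over *all* spots. The per-spot
#' observed-to-expected ratios are then averaged over the focal type's
#' high spots (`aggregate = "mean_ratio"`, the default) or pooled as a
#' ratio of sums (`aggregate = "ratio_of_sums"`).
#'
#' A spatially constant field has ratio exactly 1 at every spot; values
#' above 1 mean the type is enriched in the focal type's neighborhood.
#'
#' @param grid A [spatial_grid()].
#' @param focal_type Cell type whose high spots define the neighborhoods.
#' @param threshold Passed to [find_high_spots()]. Default 3.
#' @param n_shells Passed to [neighbor_shells()]. Default 3.
#' @param aggregate `"mean_ratio"` or `"ratio_of_sums"`.
#' @return An `enrichment_profile`: `focal_type`, `per_type_ratio` (named
#'   vector over all cell types; `NA` for a type with zero global mean),
#'   `n_high_spots`.
#' @export
neighborhood_enrichment <- function(grid, focal_type, threshold = 3,
                                    n_shells = 3L,
                                    aggregate = c("mean_ratio", "ratio_of_sums")) {
  aggregate <- match.arg(aggregate)
  high <- find_high_spots(grid, focal_type, threshold)
  if (!length(high))
    stop("focal type '", focal_type, "' has no high spots", call. = FALSE)
  global_mean <- rowMeans(grid$abundance)
  obs <- matrix(0, nrow = nrow(grid$abundance), ncol = length(high),
                dimnames = list(rownames(grid$abundance), high))
  n_nb <- numeric(length(high))
  for (j in seq_along(high)) {
    nb <- neighbor_shells(grid, high[j], n_shells)
    n_nb[j] <- length(nb)
    if (length(nb))
      obs[, j] <- rowSums(grid$abundance[, nb, drop = FALSE])
  }
  expected <- outer(global_mean, n_nb)
  ratio <- if (aggregate == "mean_ratio") {
    rowMeans(obs / expected)
  } else {
    rowSums(obs) / rowSums(expected)
  }
  ratio[global_mean == 0] <- NA_real_
  structure(list(focal_type = focal_type,
                 per_type_ratio = ratio,
                 n_high_spots = length(high)),
            class = "enrichment_profile")
}

#' Enrichment profiles for every cell type of a sample
#'
#' Runs [neighborhood_enrichment()] for each cell type that has at least
#' one high spot; types without high spots are skipped.
#'
#' @inheritParams neighborhood_enrichment
#' @return Named list of `enrichment_profile`s.
#' @export
enrichment_profiles <- function(grid, threshold = 3, n_shells = 3L,
                                aggregate = c("mean_ratio", "ratio_of_sums")) {
  aggregate <- match.arg(aggregate)
  types <- rownames(grid$abundance)
  out <- list()
  for (ty in types) {
    if (length(find_high_spots(grid, ty, threshold)) == 0) next
    out[[ty]] <- neighborhood_enrichment(grid, ty, threshold, n_shells, aggregate)
  }
  out
}

#' Mutual neighborhood-enrichment graph
#'
#' Aggregates directional enrichment over samples and keeps only mutual
#' relationships: the directional score A -> B is the unweighted mean,
#' over the samples in which A has high spots, of A's per-type ratio for
#' B; an undirected edge A--B exists iff both directional scores exceed 1,
#' with weight the mean of the two. Nodes carry a `size` attribute (mean
#' abundance of the type over all spots of all samples) when `grids` are
#' supplied; types that never have high spots are kept as isolated nodes
#' and listed in the graph attribute `no_high_spots`.
#'
#' @param profiles A list with one element per sample, each a named list of
#'   `enrichment_profile`s (as returned by [enrichment_profiles()]); a
#'   single sample's profile list is accepted too.
#' @param grids Optional list of the corresponding [spatial_grid()]s, used
#'   only for the node `size` attribute.
#' @return An [igraph::graph][igraph] — simple, undirected, no self-edges —
#'   with edge attribute `weight` and graph attribute `directional`, the
#'   full directional score matrix.
#' @export
build_mutual_graph <- function(profiles, grids = NULL) {
  if (length(profiles) && inherits(profiles[[1]], "enrichment_profile"))
    profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  types <- sort(unique(unlist(lapply(profiles, function(s)
    unique(c(names(s), unlist(lapply(s, function(p) names(p$per_type_ratio)))))))))
  score <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(types, types))
  for (a in types) {
    rat <- lapply(profiles, function(s) if (a %in% names(s))
      s[[a]]$per_type_ratio[types] else NULL)
    rat <- do.call(rbind, rat[!vapply(rat, is.null, logical(1))])
    if (!is.null(rat)) score[a, ] <- colMeans(rat)
  }
  no_high <- types[apply(is.na(score), 1, all)]

  edges <- character(0)
  weights <- numeric(0)
  combs <- if (length(types) >= 2) utils::combn(types, 2) else matrix(character(0), 2, 0)
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    ab <- score[a, b]; ba <- score[b, a]
    if (!is.na(ab) && !is.na(ba) && ab > 1 && ba > 1) {
      edges <- c(edges, a, b)
      weights <- c(weights, (ab + ba) / 2)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(types), name = types)
  if (length(edges))
    g <- igraph::add_edges(g, edges, weight = weights)
  if (!is.null(grids)) {
    ab_all <- do.call(cbind, lapply(grids, function(gr)
      gr$abundance[types, , drop = FALSE]))
    igraph::V(g)$size <- rowMeans(ab_all)
  }
  g <- igraph::set_graph_attr(g, "directional", score)
  igraph::set_graph_attr(g, "no_high_spots", no_high)
}

#' Average neighborhood abundance of a target type around a focal type
#'
#' Mean over the focal type's high spots of the target type's average
#' abundance in the shell neighborhood — an absolute-abundance companion
#' to the relative [neighborhood_enrichment()] ratios.
#'
#' @inheritParams neighborhood_enrichment
#' @param target_type Cell type whose abundance is averaged.
#' @return A single number, or `NA` (with a warning) if the focal type has
#'   no high spots.
#' @export
neighborhood_abundance <- function(grid, focal_type, target_type,
                                   threshold = 3, n_shells = 3L) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (!target_type %in% rownames(grid$abundance))
    stop("unknown cell type: ", target_type, call. = FALSE)
  high <- find_high_spots(grid, focal_type, threshold)
  if (!length(high)) {
    warning("focal type '", focal_type, "' has no high spots", call. = FALSE)
    return(NA_real_)
  }
  per_spot <- vapply(high, function(s) {
    nb <- neighbor_shells(grid, s, n_shells)
    if (!length(nb)) return(NA_real_)
    mean(grid$abundance[target_type, nb])
  }, numeric(1))
  mean(per_spot, na.rm = TRUE)
}
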