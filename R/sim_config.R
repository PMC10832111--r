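#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: clustered
#' negative-binomial single-cell counts with planted cluster markers and a
#' cycling population ([simulate_cells()]), bulk survival cohorts mixed from
#' cluster expression profiles with a hidden prognostic cut-off
#' ([simulate_cohort()]), and spot lattices with planted co-localized and
#' segregated cell-type abundance fields ([simulate_spatial()]).
#'
#' Defaults describe a down-scaled but realistic pancreatic-tumor atlas:
#' four subclusters of 250 cells each over 2000 genes, 20 planted markers
#' per subcluster at 8-fold over-expression, a negative-binomial baseline
#' with mean 3 and dispersion 0.5 (per-gene baselines drawn log-normal),
#' 10% cycling cells, a 200-sample bulk cohort with hazard ratio 3 above a
#' hidden median cut-off and 30% censoring, and a 12x12 spot lattice.
#'
#' @param n_clusters Number of (non-cycling) cell subclusters.
#' @param n_cells_per_cluster Cells simulated per subcluster.
#' @param n_genes Total genes.
#' @param n_markers_per_cluster Planted marker genes per subcluster; marker
#'   sets of different subclusters are disjoint.
#' @param marker_fold_change Mean fold change of a planted marker inside its
#'   own subcluster (1 = null markers, used as a negative control).
#' @param nb_mean Baseline negative-binomial mean; per-gene baselines are
#'   drawn log-normal around it.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param n_patients Patients; cells are assigned round-robin.
#' @param cycling_fraction Fraction of additional cycling cells, each drawn
#'   from a parent subcluster with a shared cycling program superposed.
#' @param qc_fail_fraction Fraction of cells given exactly one planted
#'   QC violation each (low UMI, too few genes, high mitochondrial
#'   percentage, or doublet call).
#' @param n_samples Bulk cohort size.
#' @param hazard_ratio Hazard multiplier for samples whose signature score
#'   exceeds the hidden cut-off (1 = null cohort).
#' @param true_cutoff_quantile Quantile of the signature score at which the
#'   hidden cut-off is planted.
#' @param censor_rate Probability a sample's survival time is independently
#'   right-censored.
#' @param grid_side Side length of the spot lattice (>= 8 for spatial
#'   simulation).
#' @param lattice `"square"` or `"hex"` (offset rows at sqrt(3)/2 spacing,
#'   the Visium geometry).
#' @param seed Integer seed; fixing it reproduces the outputs exactly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_clusters = 3, n_cells_per_cluster = 50, n_genes = 300)
#' cfg$n_clusters
#' @export
sim_config <- function(n_clusters = 4L,
                       n_cells_per_cluster = 250L,
                       n_genes = 2000L,
                       n_markers_per_cluster = 20L,
                       marker_fold_change = 8,
                       nb_mean = 3,
                       nb_dispersion = 0.5,
                       n_patients = 8L,
                       cycling_fraction = 0.1,
                       qc_fail_fraction = 0,
                       n_samples = 200L,
                       hazard_ratio = 3,
                       true_cutoff_quantile = 0.5,
                       censor_rate = 0.3,
                       grid_side = 12L,
                       lattice = c("square", "hex"),
                       seed = 1L) {
  cfg <- list(
    n_clusters = .assert_count(n_clusters, "n_clusters"),
    n_cells_per_cluster = .assert_count(n_cells_per_cluster, "n_cells_per_cluster"),
    n_genes = .assert_count(n_genes, "n_genes"),
    n_markers_per_cluster = .assert_count(n_markers_per_cluster, "n_markers_per_cluster"),
    marker_fold_change = .assert_positive(marker_fold_change, "marker_fold_change"),
    nb_mean = .assert_positive(nb_mean, "nb_mean"),
    nb_dispersion = .assert_positive(nb_dispersion, "nb_dispersion"),
    n_patients = .assert_count(n_patients, "n_patients"),
    cycling_fraction = .assert_fraction(cycling_fraction, "cycling_fraction"),
    qc_fail_fraction = .assert_fraction(qc_fail_fraction, "qc_fail_fraction"),
    n_samples = .assert_count(n_samples, "n_samples"),
    hazard_ratio = .assert_positive(hazard_ratio, "hazard_ratio"),
    true_cutoff_quantile = .assert_fraction(true_cutoff_quantile, "true_cutoff_quantile"),
    censor_rate = .assert_fraction(censor_rate, "censor_rate"),
    grid_side = .assert_count(grid_side, "grid_side"),
    lattice = match.arg(lattice),
    seed = .assert_count(seed, "seed", min = 0L)
  )
  if (cfg$true_cutoff_quantile <= 0 || cfg$true_cutoff_quantile >= 1)
    stop("'true_cutoff_quantile' must lie strictly inside (0, 1)", call. = FALSE)
  if (cfg$n_markers_per_cluster * cfg$n_clusters > cfg$n_genes)
    stop("configuration error: n_markers_per_cluster * n_clusters exceeds n_genes",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d clusters x %d cells, %d genes (%d markers/cluster, fold %.3g)",
              x$n_clusters, x$n_cells_per_cluster, x$n_genes,
              x$n_markers_per_cluster, x$marker_fold_change),
      sprintf("cohort n=%d HR=%.3g cutoff-q=%.2f | grid %dx%d (%s) | seed %d",
              x$n_samples, x$hazard_ratio, x$true_cutoff_quantile,
              x$grid_side, x$grid_side, x$lattice, x$seed),
      sep = "\n  ")
  invisible(x)
}
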