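#' Simulate a bulk survival cohort from cluster expression profiles
#'
#' Each sample's expression is a Dirichlet-weighted mixture of the given
#' cluster profiles plus Gaussian noise, then standardized per gene (via
#' [cohort_table()]) — emulating bulk tumor transcriptomes as mixtures of
#' cell-population programs. The Dirichlet concentration is below 1 by
#' default, so compositions are skewed toward a dominant population the
#' way patient compositions cluster around archetypes; the gene-level
#' noise is substantial, so same-set marker genes correlate moderately
#' (about 0.2 pairwise) and the signature score has a spread of roughly
#' half a standardized unit, as refined-set scores do in real cohorts.
#' Survival follows a two-group exponential
#' proportional-hazards model: samples whose signature score (mean
#' standardized expression of `signature`) exceeds the hidden cut-off —
#' the `true_cutoff_quantile` quantile of the scores — have their hazard
#' multiplied by `hazard_ratio`. Baseline hazard corresponds to a 24-month
#' median survival. Censoring is independent: each sample is censored with
#' probability `censor_rate` at a uniform fraction of its event time.
#'
#' The planted threshold makes the optimal cut-off a well-defined recovery
#' target for [scan_cutoff()].
#'
#' @param config A [sim_config()] (uses `n_samples`, `hazard_ratio`,
#'   `true_cutoff_quantile`, `censor_rate`, `seed`).
#' @param cluster_profiles Genes-by-clusters matrix of mixture components,
#'   e.g. `truth$cluster_profiles` from [simulate_cells()].
#' @param signature Non-empty gene set (subset of the profile genes) whose
#'   mean standardized expression defines the prognostic score.
#' @param noise_sd Gaussian noise added to the mixture before
#'   standardization. Default 10 on the profile-mean scale.
#' @param concentration Symmetric Dirichlet concentration of the mixing
#'   weights. Values below 1 give dominant-population-skewed compositions;
#'   default 0.5.
#' @return List with `cohort` (a [cohort_table()]) and `truth` holding
#'   `true_cutoff` (score-scale), `high_risk_samples`, `scores`, `weights`.
#' @examples
#' sim <- simulate_cells(sim_config(n_clusters = 3, n_cells_per_cluster = 30,
#'                                  n_genes = 300))
#' co <- simulate_cohort(sim_config(n_samples = 60, seed = 2),
#'                       sim$truth$cluster_profiles,
#'                       sim$truth$planted_markers[["C01"]])
#' co$truth$true_cutoff
#' @export
simulate_cohort <- function(config, cluster_profiles, signature,
                            noise_sd = 10, concentration = 0.5) {
  stopifnot(inherits(config, "sim_config"), is.matrix(cluster_profiles))
  if (length(signature) == 0)
    stop("configuration error: empty signature gene set", call. = FALSE)
  if (!all(signature %in% rownames(cluster_profiles)))
    stop("signature genes missing from cluster_profiles: ",
         paste(head(setdiff(signature, rownames(cluster_profiles)), 5),
               collapse = ", "), call. = FALSE)
  set.seed(config$seed)
  n <- config$n_samples
  K <- ncol(cluster_profiles)

  ## Dirichlet mixing weights via normalized gammas
  w <- matrix(rgamma(n * K, shape = concentration), nrow = n)
  w <- w / rowSums(w)
  expr <- w %*% t(cluster_profiles) +
    matrix(rnorm(n * nrow(cluster_profiles), sd = noise_sd), nrow = n)
  colnames(expr) <- rownames(cluster_profiles)
  rownames(expr) <- sprintf("S%04d", seq_len(n))

  ## survival drawn against the score before censoring
  tmp <- cohort_table(expr, os_time = rep(1, n), os_event = rep(1L, n))
  scores <- score_gene_set(tmp, signature)
  true_cutoff <- unname(quantile(scores, config$true_cutoff_quantile, type = 7))
  high <- scores > true_cutoff

  lambda0 <- log(2) / 24  # 24-month baseline median survival
  t_event <- rexp(n, rate = lambda0 * ifelse(high, config$hazard_ratio, 1))
  censored <- runif(n) < config$censor_rate
  os_time <- ifelse(censored, runif(n) * t_event, t_event)
  os_time <- pmax(os_time, 1e-6)
  os_event <- as.integer(!censored)

  cohort <- cohort_table(expr, os_time, os_event)
  truth <- structure(list(
    true_cutoff = true_cutoff,
    high_risk_samples = rownames(expr)[high],
    scores = scores,
    weights = w,
    config = config), class = "ground_truth")
  list(cohort = cohort, truth = truth)
}
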