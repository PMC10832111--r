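test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_clusters = 10, n_markers_per_cluster = 50,
                          n_genes = 100), "exceeds n_genes")
  expect_error(sim_config(true_cutoff_quantile = 0), "strictly inside")
  expect_error(sim_config(cycling_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(nb_mean = -1), "positive")
  expect_error(simulate_spatial(sim_config(grid_side = 7)), "at least 8")
})

test_that("fixed seed reproduces cells exactly; different seeds differ", {
  cfg <- sim_config(n_clusters = 2, n_cells_per_cluster = 30, n_genes = 200,
                    qc_fail_fraction = 0.1, seed = 11)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(SummarizedExperiment::assay(a$cells), SummarizedExperiment::assay(b$cells))
  expect_identical(a$truth$qc_fail_cells, b$truth$qc_fail_cells)
  cfg2 <- sim_config(n_clusters = 2, n_cells_per_cluster = 30, n_genes = 200,
                     qc_fail_fraction = 0.1, seed = 12)
  c <- simulate_cells(cfg2)
  expect_false(identical(SummarizedExperiment::assay(a$cells),
                         SummarizedExperiment::assay(c$cells)))
})

test_that("generated counts are non-negative integers with consistent metadata", {
  sim <- simulate_cells(sim_config(n_clusters = 3, n_cells_per_cluster = 40,
                                   n_genes = 300, cycling_fraction = 0.1, seed = 4))
  m <- as.matrix(SummarizedExperiment::assay(sim$cells))
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  cd <- SummarizedExperiment::colData(sim$cells)
  expect_equal(unname(cd$total_umi), unname(colSums(m)))
  expect_equal(unname(cd$n_genes_detected), unname(colSums(m > 0)))
  expect_true(all(cd$pct_mito >= 0 & cd$pct_mito <= 100))
})

test_that("no QC failures are planted when qc_fail_fraction is zero", {
  sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 20,
                                   n_genes = 200, qc_fail_fraction = 0, seed = 1))
  expect_length(sim$truth$qc_fail_cells, 0)
})

test_that("every planted QC failure violates exactly one criterion", {
  sim <- simulate_cells(sim_config(n_cells_per_cluster = 100,
                                   qc_fail_fraction = 0.2, seed = 8))
  cd <- SummarizedExperiment::colData(sim$cells)
  viol <- cbind(umi = cd$total_umi <= 2000,
                genes = cd$n_genes_detected < 500 | cd$n_genes_detected > 7000,
                mito = cd$pct_mito >= 10,
                singlet = !cd$is_singlet)
  n_viol <- rowSums(viol)
  expect_true(all(n_viol[sim$truth$qc_fail_cells] == 1))
  expect_true(all(n_viol[setdiff(colnames(sim$cells), sim$truth$qc_fail_cells)] == 0))
  ## and the planted mode is the violated criterion
  for (cell in sim$truth$qc_fail_cells)
    expect_equal(unname(colnames(viol)[viol[cell, ]]),
                 unname(sim$truth$qc_fail_modes[cell]))
})

test_that("patients are assigned round-robin and cycling cells have one parent", {
  cfg <- sim_config(n_clusters = 2, n_cells_per_cluster = 25, n_genes = 200,
                    n_patients = 4, cycling_fraction = 0.2, seed = 3)
  sim <- simulate_cells(cfg)
  cd <- SummarizedExperiment::colData(sim$cells)
  expect_equal(as.character(cd$patient_id[1:8]),
               rep(sprintf("P%02d", 1:4), 2))
  cyc <- colnames(sim$cells)[cd$cluster_label == "Cycling"]
  expect_length(cyc, round(0.2 * 50))
  expect_setequal(names(sim$truth$parent_of_cycling_cell), cyc)
  expect_true(all(sim$truth$parent_of_cycling_cell %in% c("C01", "C02")))
})

test_that("null marker fold change leaves planted markers unseparated", {
  sim <- simulate_cells(sim_config(n_clusters = 3, n_cells_per_cluster = 60,
                                   n_genes = 300, marker_fold_change = 1,
                                   cycling_fraction = 0, seed = 5))
  mk <- rank_markers(normalize_log(sim$cells), min_top_mean = 0)
  planted <- unlist(sim$truth$planted_markers)
  gaps_planted <- mk$gap[mk$gene_id %in% planted]
  gaps_other <- mk$gap[!mk$gene_id %in% planted]
  ## same distribution: planted mean within 3 SE of background mean
  se <- sd(gaps_other) * sqrt(1 / length(gaps_planted) + 1 / length(gaps_other))
  expect_lt(abs(mean(gaps_planted) - mean(gaps_other)), 3 * se)
})

test_that("cohort generator honours censoring and null hazard settings", {
  sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 20,
                                   n_genes = 200, seed = 1))
  prof <- sim$truth$cluster_profiles
  sig <- sim$truth$planted_markers[["C01"]]
  expect_error(simulate_cohort(sim_config(), prof, character(0)), "empty signature")

  co <- simulate_cohort(sim_config(n_samples = 80, censor_rate = 0, seed = 2),
                        prof, sig)
  expect_true(all(co$cohort$os_event == 1))
  expect_setequal(co$truth$high_risk_samples,
                  names(co$truth$scores)[co$truth$scores > co$truth$true_cutoff])

  ## expression is standardized per gene
  expect_lt(max(abs(colMeans(co$cohort$expr))), 1e-8)
  expect_lt(max(abs(apply(co$cohort$expr, 2, sd) - 1)), 1e-8)
})

test_that("null-hazard cohorts rarely reach significance at the scanned optimum", {
  sim <- simulate_cells(sim_config(n_clusters = 2, n_cells_per_cluster = 20,
                                   n_genes = 200, seed = 1))
  prof <- sim$truth$cluster_profiles
  sig <- sim$truth$planted_markers[["C01"]]
  ## with HR = 1 the planted label carries no survival information: at a
  ## FIXED pre-chosen cut-off (the true one) the log-rank test is a valid
  ## null test, so its rejection rate stays near alpha
  rej <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(sim_config(n_samples = 60, hazard_ratio = 1,
                                     seed = 3000 + r), prof, sig)
    hi <- co$truth$scores > co$truth$true_cutoff
    p <- logrank_test(co$cohort$os_time[hi], co$cohort$os_event[hi],
                      co$cohort$os_time[!hi], co$cohort$os_event[!hi])$pvalue
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / n_rep, 0.10)  # within 2x nominal
})

test_that("spatial generator plants the advertised structure", {
  sp <- simulate_spatial(sim_config(grid_side = 10, seed = 6))
  ab <- sp$grid$abundance
  expect_true(all(ab >= 0) && all(is.finite(ab)))
  expect_true(all(ab["Uniform", ] == 5))
  dm <- sp$truth$domain_map
  expect_setequal(find_high_spots(sp$grid, "CoA"), names(dm)[dm == "coloc"])
  expect_setequal(find_high_spots(sp$grid, "CoB"), names(dm)[dm == "coloc"])
  expect_setequal(find_high_spots(sp$grid, "SegA"), names(dm)[dm == "segA"])
  ## co-localized and segregated pair lists are disjoint
  expect_length(intersect(unlist(sp$truth$colocalized_pairs),
                          unlist(sp$truth$segregated_pairs)), 0)
  ## reproducibility
  sp2 <- simulate_spatial(sim_config(grid_side = 10, seed = 6))
  expect_identical(sp$grid$abundance, sp2$grid$abundance)
})
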