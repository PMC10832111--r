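# tmekit

Tools for dissecting tumor-microenvironment structure from single-cell
and spatial transcriptomics, built around the computational workflow of a
pancreatic ductal adenocarcinoma (PDAC) atlas: which genes specifically
mark each cancer-cell or fibroblast subcluster, which subcluster
signatures carry prognostic information in bulk cohorts, where cycling
cells came from, how patients group by cellular composition, and which
cell types co-occur in each other's spatial neighborhoods.

It is aimed at computational biologists who have cluster-labelled
single-cell data, bulk expression cohorts with survival, and/or
deconvolved spatial spot abundances, and want the bespoke statistics of
that workflow as tested, reusable functions rather than notebook code.

## What it computes

**Gap-score marker ranking.** For each gene, per-cluster mean
log-normalized expression is max-normalized by the top cluster; the gap
score `1 − μ₍₂₎/μ₍₁₎` (second-highest over highest) ranks specificity.
Candidates require top-cluster mean > 0.4 and expressing fraction > 10%,
and are confirmed by one-vs-rest Wilcoxon rank-sum tests with BH
adjustment (`rank_markers()`). `refine_markers()` drops markers leaking
into other major cell types, making them safe for bulk scoring.

**Minimum-p survival cut-off scanning.** Samples are scored by the mean
standardized expression of a refined marker set (`subcluster_score()`).
`scan_cutoff()` tests every candidate cut-off from Q1 to Q3 in steps of
0.04 with a log-rank test, reporting the minimum-p optimum;
`cross_validate_cutoff()` applies a trained cut-off to an independent
cohort, the honest check against minimum-p optimism.

**Cycling-cell deconvolution.** `transfer_labels()` assigns each cycling
cell a parent subcluster with a ridge multinomial classifier trained on
non-cycling cells (cell-cycle genes excluded); `cycling_enrichment()`
tests which subclusters over-contribute to the cycling pool with pooled
two-proportion z-tests.

**Composition stratification.** Patient-by-subcluster proportion
matrices per compartment (`composition_matrix()`), Ward hierarchical
patient groups (`cluster_patients()`), and Shannon diversity
(`shannon_index()`).

**Spatial neighborhood enrichment.** From spot-lattice abundance
estimates: high spots (abundance > 3), three-shell neighborhoods,
observed-to-expected neighbor abundance profiles
(`neighborhood_enrichment()`), and the mutual-enrichment graph whose
edges require ratios above 1 in both directions (`build_mutual_graph()`).

**Synthetic data with ground truth.** `simulate_cells()`,
`simulate_cohort()` and `simulate_spatial()` generate all three input
modalities with planted markers, QC failures, cycling parents, a hidden
prognostic cut-off, and co-localized/segregated spatial domains — every
downstream stage has a parameter-recovery test with no external data.

## Worked example

```r
library(tmekit)

## single-cell side: QC, markers, refinement
sim <- simulate_cells(sim_config(seed = 1))
cells <- normalize_log(filter_cells(sim$cells))
markers <- refine_markers(rank_markers(cells), cells)
ep_set <- subset(top_markers(markers, 20), cluster == "C01" & refined)$gene_id
length(ep_set)
#> [1] 19

## bulk side: train a cut-off, validate on an independent cohort
train <- simulate_cohort(sim_config(n_samples = 200, seed = 2),
                         sim$truth$cluster_profiles, ep_set)
test <- simulate_cohort(sim_config(n_samples = 200, seed = 3),
                        sim$truth$cluster_profiles, ep_set)
cv <- cross_validate_cutoff(train$cohort, test$cohort, ep_set)
cv$scan
#> cutoff_scan: 18 candidates on [-0.394, 0.326] step 0.04 (0 skipped)
#>   optimal cut-off -0.0342, log-rank p 2.02e-08
train$truth$true_cutoff  # the planted cut-off
#> [1] -0.1039
cv$p_test
#> [1] 1.3e-14
```

The scan recovers a cut-off near the planted one (the minimum-p point
estimate is intrinsically variable — here it lands two grid steps away),
and the transferred split is strongly prognostic in the independent
cohort, which is the validation that matters.

```r
## spatial side: mutual-enrichment graph
sp <- simulate_spatial(sim_config(seed = 4))
g <- build_mutual_graph(list(enrichment_profiles(sp$grid)),
                        grids = list(sp$grid))
igraph::as_edgelist(g)
#>      [,1]  [,2]
#> [1,] "CoA" "CoB"
```

The planted co-localized pair is the only mutual edge; the segregated
pair is not connected.

## Documentation

The methods vignette (`vignettes/tmekit-methods.Rmd`) describes the
models, parameter defaults and their rationale, the generator's design,
numerical edge cases, and known limitations — including why scanned
minimum-p values must not be reported without cross-cohort validation.
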