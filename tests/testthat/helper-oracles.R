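# Independent scalar-loop oracles used to cross-check the vectorized
# implementations. Deliberately naive: plain loops, no shared code with R/.

# Build a small SingleCellExperiment from a dense count matrix and labels.
make_toy_sce <- function(counts, clusters, majors = NULL, patients = NULL) {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(n))
  cd <- S4Vectors::DataFrame(
    patient_id = patients %||% rep("P01", n),
    cluster_label = clusters,
    major_type = majors %||% rep("Epithelial", n),
    total_umi = colSums(counts),
    n_genes_detected = colSums(counts > 0),
    pct_mito = rep(0, n),
    is_singlet = rep(TRUE, n),
    row.names = colnames(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = cd,
    rowData = S4Vectors::DataFrame(gene_id = rownames(counts),
                                   is_mito = rep(FALSE, nrow(counts)),
                                   row.names = rownames(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar-loop log-normalization.
oracle_normalize <- function(counts, target_sum) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts)))
      out[i, j] <- log(1 + target_sum * counts[i, j] / tot)
  }
  out
}

# Scalar-loop Wilcoxon rank-sum p-value, normal approximation with tie
# correction, no continuity correction.
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu) / sqrt(sig2)
  2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
}

# Scalar-loop re-derivation of the full marker table on a toy data set:
# per-cluster means, max-normalization, gap, candidacy, rank-sum p, BH.
oracle_rank_markers <- function(lognorm, clusters, min_top_mean = 0.4,
                                min_fraction = 0.10, alpha = 0.05) {
  lvls <- sort(unique(clusters))
  rows <- list()
  for (g in rownames(lognorm)) {
    mg <- fg <- setNames(numeric(length(lvls)), lvls)
    for (k in lvls) {
      v <- lognorm[g, clusters == k]
      mg[k] <- mean(v)
      fg[k] <- mean(v > 0)
    }
    if (all(mg == 0)) next
    top <- names(mg)[mg == max(mg)]
    if (length(top) > 1) top <- top[order(-fg[top], top)][1]
    norm <- mg / mg[top]
    second <- max(norm[setdiff(lvls, top)])
    rows[[g]] <- data.frame(
      gene_id = g, cluster = top, top_mean = unname(mg[top]),
      second_norm = unname(second), gap = 1 - unname(second),
      expr_fraction = unname(fg[top]),
      candidate = unname(mg[top] > min_top_mean & fg[top] > min_fraction))
  }
  out <- do.call(rbind, rows)
  out$pvalue <- NA_real_
  for (i in which(out$candidate)) {
    g <- out$gene_id[i]
    sel <- clusters == out$cluster[i]
    out$pvalue[i] <- oracle_wilcox_p(lognorm[g, sel], lognorm[g, !sel])
  }
  out$p_adj <- NA_real_
  out$p_adj[out$candidate] <- p.adjust(out$pvalue[out$candidate], "BH")
  out$final <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- out$gene_id
  out
}

# Hand life-table log-rank statistic (O/E/V over distinct event times).
oracle_logrank_stat <- function(timesA, eventsA, timesB, eventsB) {
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  inA <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
  OE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & inA); n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & inA)
    OE <- OE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Permutation p-value of the hand log-rank statistic.
oracle_logrank_perm_p <- function(timesA, eventsA, timesB, eventsB,
                                  n_perm = 2000, seed = 1) {
  set.seed(seed)
  obs <- oracle_logrank_stat(timesA, eventsA, timesB, eventsB)
  time <- c(timesA, timesB); event <- c(eventsA, eventsB)
  nA <- length(timesA); n <- length(time)
  hits <- 0
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, nA)
    s <- oracle_logrank_stat(time[idx], event[idx], time[-idx], event[-idx])
    if (s >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Hand product-limit estimator.
oracle_km <- function(times, events) {
  s <- 1
  out <- data.frame(time = 0, surv = 1)
  for (t in sort(unique(times[events == 1]))) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Brute-force shell neighborhood from raw coordinates.
oracle_neighbors <- function(coords, spot, n_shells) {
  i <- which(coords$spot_id == spot)
  d <- sqrt((coords$x - coords$x[i])^2 + (coords$y - coords$y[i])^2)
  dd <- sort(unique(round(d[d > 1e-12], 9)))
  coords$spot_id[d > 1e-12 & round(d, 9) <= dd[min(n_shells, length(dd))]]
}

# Brute-force enrichment profile of one focal type.
oracle_enrichment <- function(grid, focal, threshold = 3, n_shells = 3) {
  ab <- grid$abundance
  gm <- apply(ab, 1, mean)
  high <- colnames(ab)[ab[focal, ] > threshold]
  acc <- matrix(0, nrow(ab), length(high), dimnames = list(rownames(ab), high))
  for (s in high) {
    nb <- oracle_neighbors(grid$coords, s, n_shells)
    for (ty in rownames(ab))
      acc[ty, s] <- sum(ab[ty, nb]) / (length(nb) * gm[ty])
  }
  apply(acc, 1, mean)
}

# Dirichlet-ish archetype compositions with planted groups.
make_archetype_comp <- function(n_patients = 30, seed = 1) {
  set.seed(seed)
  lab <- sample(1:3, n_patients, replace = TRUE)
  m <- t(sapply(lab, function(l) {
    x <- rgamma(3, shape = 0.1 + 5 * (1:3 == l))
    x / sum(x)
  }))
  rownames(m) <- sprintf("P%02d", seq_len(n_patients))
  colnames(m) <- c("EpA", "EpB", "EpC")
  list(comp = m, labels = lab)
}
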