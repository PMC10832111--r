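# Shared in-code fixtures.

# SCE whose logcounts are set directly to chosen values, so per-cluster
# means are exact rational numbers.
sce_with_lognorm <- function(lognorm, clusters, majors = NULL) {
  sce <- make_toy_sce(matrix(1L, nrow(lognorm), ncol(lognorm),
                             dimnames = dimnames(lognorm)),
                      clusters = clusters, majors = majors)
  SingleCellExperiment::logcounts(sce) <- Matrix::Matrix(lognorm, sparse = TRUE)
  sce
}

# 5x5 square lattice: focal type F high (10) only at the center, 1
# elsewhere; target type T with abundance x^2 — every observed/expected
# entry is hand-computable.
square_grid_5x5 <- function() {
  xy <- expand.grid(x = 0:4, y = 0:4)
  coords <- data.frame(spot_id = sprintf("s%02d", seq_len(25)),
                       x = xy$x, y = xy$y)
  focal <- ifelse(xy$x == 2 & xy$y == 2, 10, 1)
  target <- xy$x^2
  ab <- rbind(F = focal, T = target)
  colnames(ab) <- coords$spot_id
  spatial_grid(coords, ab, "square")
}
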