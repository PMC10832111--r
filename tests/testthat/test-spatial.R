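test_that("high spots use a strict threshold", {
  g <- square_grid_5x5()
  expect_length(find_high_spots(g, "T", threshold = 16), 0)  # max is exactly 16
  expect_setequal(find_high_spots(g, "T", threshold = 15.9),
                  g$coords$spot_id[g$coords$x == 4])
  expect_error(find_high_spots(g, "nope"), "unknown cell type")
})

test_that("shell neighborhoods match brute-force enumeration", {
  g <- square_grid_5x5()
  center <- g$coords$spot_id[g$coords$x == 2 & g$coords$y == 2]
  nb3 <- neighbor_shells(g, center, 3)
  expect_length(nb3, 12)  # 4 at d=1, 4 at sqrt 2, 4 at d=2
  expect_setequal(nb3, oracle_neighbors(g$coords, center, 3))
  corner <- g$coords$spot_id[g$coords$x == 0 & g$coords$y == 0]
  expect_setequal(neighbor_shells(g, corner, 3),
                  oracle_neighbors(g$coords, corner, 3))
  ## hex first ring has 6 spots
  hx <- simulate_spatial(sim_config(grid_side = 10, lattice = "hex", seed = 2))$grid
  interior <- hx$coords$spot_id[abs(hx$coords$x - 4.5) < 1e-9 &
                                  abs(hx$coords$y - 5 * sqrt(3) / 2) < 1e-9]
  expect_length(neighbor_shells(hx, interior, 1), 6)
  for (s in sample(hx$coords$spot_id, 8))
    expect_setequal(neighbor_shells(hx, s, 3), oracle_neighbors(hx$coords, s, 3))
})

test_that("shell membership is symmetric for interior lattice spots", {
  g <- simulate_spatial(sim_config(grid_side = 9, seed = 3))$grid
  interior <- g$coords$spot_id[g$coords$x >= 2 & g$coords$x <= 6 &
                                 g$coords$y >= 2 & g$coords$y <= 6]
  for (a in sample(interior, 5)) {
    for (b in neighbor_shells(g, a, 3)) {
      if (b %in% interior)
        expect_true(a %in% neighbor_shells(g, b, 3))
    }
  }
})

test_that("a spatially constant field has ratio exactly one at every high spot", {
  sp <- simulate_spatial(sim_config(grid_side = 10, seed = 4))
  pr <- neighborhood_enrichment(sp$grid, "Uniform")
  expect_equal(unname(pr$per_type_ratio["Uniform"]), 1, tolerance = 1e-12)
  expect_equal(pr$n_high_spots, 100)
})

test_that("the 5x5 worked micro-example reproduces the hand-computed table", {
  g <- square_grid_5x5()
  pr <- neighborhood_enrichment(g, "F", threshold = 3, n_shells = 3)
  expect_equal(pr$n_high_spots, 1)
  ## hand table: observed T over the 12 neighbors = 62; global mean = 6;
  ## expected = 12 * 6 = 72
  expect_equal(unname(pr$per_type_ratio["T"]), 62 / 72, tolerance = 1e-12)
  ## observed F = 12 * 1; global mean = (10 + 24) / 25
  expect_equal(unname(pr$per_type_ratio["F"]), 12 / (12 * 34 / 25),
               tolerance = 1e-12)
  expect_equal(neighborhood_abundance(g, "F", "T"), 62 / 12, tolerance = 1e-12)
})

test_that("enrichment matches the brute-force oracle on a generated lattice", {
  sp <- simulate_spatial(sim_config(grid_side = 10, seed = 7))
  for (ty in c("CoA", "SegA", "Uniform")) {
    got <- neighborhood_enrichment(sp$grid, ty)$per_type_ratio
    want <- oracle_enrichment(sp$grid, ty)
    expect_equal(got, want, tolerance = 1e-10)
  }
  ## planted relationships: co-localization above 1, segregation below 1
  expect_gt(neighborhood_enrichment(sp$grid, "CoA")$per_type_ratio["CoB"], 1)
  expect_lt(neighborhood_enrichment(sp$grid, "SegA")$per_type_ratio["SegB"], 1)
})

test_that("enrichment ratios are invariant to rescaling a type's abundance", {
  sp <- simulate_spatial(sim_config(grid_side = 9, seed = 8))
  base <- neighborhood_enrichment(sp$grid, "CoA")$per_type_ratio
  g2 <- sp$grid
  g2$abundance["CoB", ] <- 7.3 * g2$abundance["CoB", ]
  scaled <- neighborhood_enrichment(g2, "CoA")$per_type_ratio
  expect_equal(unname(scaled["CoB"]), unname(base["CoB"]), tolerance = 1e-12)
})

test_that("unstructured fields average to ratio one within Monte-Carlo error", {
  set.seed(15)
  ratios <- replicate(50, {
    xy <- expand.grid(x = 0:7, y = 0:7)
    coords <- data.frame(spot_id = sprintf("s%02d", seq_len(64)),
                         x = xy$x, y = xy$y)
    ab <- rbind(A = runif(64, 2.5, 5), B = runif(64, 0, 2))
    colnames(ab) <- coords$spot_id
    neighborhood_enrichment(spatial_grid(coords, ab, "square"),
                            "A")$per_type_ratio["B"]
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("mutual graph requires enrichment in both directions", {
  mk_prof <- function(focal, ratios) structure(
    list(focal_type = focal, per_type_ratio = ratios, n_high_spots = 4),
    class = "enrichment_profile")
  profs <- list(
    A = mk_prof("A", c(A = 2, B = 1.4, C = 0.5)),
    B = mk_prof("B", c(A = 0.9, B = 2, C = 1.2)),
    C = mk_prof("C", c(A = 0.2, B = 1.1, C = 2)))
  g <- build_mutual_graph(list(profs))
  el <- igraph::as_edgelist(g)
  ## A->B = 1.4 but B->A = 0.9: no A-B edge; B-C mutual (1.2, 1.1)
  expect_equal(nrow(el), 1)
  expect_setequal(el[1, ], c("B", "C"))
  expect_equal(igraph::E(g)$weight, (1.2 + 1.1) / 2, tolerance = 1e-12)
  ## sample order does not matter
  profs2 <- list(
    A = mk_prof("A", c(A = 2, B = 3.0, C = 0.5)),
    B = mk_prof("B", c(A = 1.5, B = 2, C = 1.2)),
    C = mk_prof("C", c(A = 0.2, B = 1.1, C = 2)))
  g12 <- build_mutual_graph(list(profs, profs2))
  g21 <- build_mutual_graph(list(profs2, profs))
  e12 <- igraph::as_edgelist(g12); e21 <- igraph::as_edgelist(g21)
  expect_setequal(apply(e12, 1, paste, collapse = "-"),
                  apply(e21, 1, paste, collapse = "-"))
})

test_that("planted co-localized pairs produce the only expected mutual edge", {
  sp <- simulate_spatial(sim_config(grid_side = 12, seed = 9))
  profs <- enrichment_profiles(sp$grid)
  g <- build_mutual_graph(list(profs), grids = list(sp$grid))
  el <- igraph::as_edgelist(g)
  pairs <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true("CoA-CoB" %in% pairs)
  expect_false("SegA-SegB" %in% pairs)
  ## node sizes are the global mean abundances
  expect_equal(igraph::V(g)$size[match("Uniform", igraph::V(g)$name)], 5,
               tolerance = 1e-12)
})

test_that("neighborhood abundance has its closed forms on simple fields", {
  sp <- simulate_spatial(sim_config(grid_side = 9, seed = 10))
  expect_equal(neighborhood_abundance(sp$grid, "CoA", "Uniform"), 5,
               tolerance = 1e-12)
  g2 <- sp$grid
  g2$abundance["Bg1", ] <- 0
  expect_equal(neighborhood_abundance(g2, "CoA", "Bg1"), 0, tolerance = 1e-12)
  expect_warning(res <- neighborhood_abundance(g2, "Bg2", "Bg1"), "no high spots")
  expect_true(is.na(res))
})
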