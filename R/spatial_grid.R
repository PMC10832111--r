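#' Spatial spot grid with deconvolved abundances
#'
#' Container for a spot lattice and a cell-type-by-spot abundance matrix,
#' as produced by spatial deconvolution (typically the 5%-quantile
#' posterior abundance estimates per spot). Coordinates are geometric:
#' for a hex lattice, odd rows are offset by half a column and row spacing
#' is sqrt(3)/2 of the column spacing, so Euclidean distances between
#' stored coordinates are true center-to-center distances.
#'
#' @param coords `data.frame` with columns `spot_id`, `x`, `y`
#'   (unique coordinates).
#' @param abundance Cell-type-by-spot numeric matrix, finite and >= 0;
#'   columns named by `spot_id`.
#' @param lattice `"square"` or `"hex"` (metadata only; distances are taken
#'   from the coordinates).
#' @return A `spatial_grid` list.
#' @export
spatial_grid <- function(coords, abundance, lattice = c("square", "hex")) {
  lattice <- match.arg(lattice)
  stopifnot(is.data.frame(coords),
            all(c("spot_id", "x", "y") %in% names(coords)),
            is.matrix(abundance))
  if (anyDuplicated(coords[, c("x", "y")]))
    stop("spot coordinates must be unique", call. = FALSE)
  if (anyDuplicated(coords$spot_id))
    stop("spot ids must be unique", call. = FALSE)
  if (is.null(colnames(abundance)) ||
      !setequal(colnames(abundance), coords$spot_id))
    stop("abundance columns must match coords$spot_id", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundances must be finite and non-negative", call. = FALSE)
  abundance <- abundance[, as.character(coords$spot_id), drop = FALSE]
  structure(list(coords = coords, abundance = abundance, lattice = lattice),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("spatial_grid: %d spots (%s lattice), %d cell types\n",
              nrow(x$coords), x$lattice, nrow(x$abundance)))
  invisible(x)
}

#' Simulate a spot lattice with planted spatial structure
#'
#' Places spots on a `grid_side` x `grid_side` square or hex lattice and
#' plants abundance fields with known spatial relationships:
#' \describe{
#'   \item{Uniform}{constant abundance 5 everywhere (above the usual
#'     high-spot threshold of 3), so every enrichment ratio involving it
#'     is exactly 1.}
#'   \item{CoA / CoB}{a co-localized pair, both high (uniform 4.5-8) in the
#'     same planted circular domain and low (uniform 0-1) elsewhere.}
#'   \item{SegA / SegB}{a segregated pair, each high in its own domain;
#'     the two domains are disjoint and separated by more than three
#'     neighbor shells.}
#'   \item{Bg1-Bg3}{unstructured background, uniform 0-2.}
#' }
#'
#' @param config A [sim_config()] (uses `grid_side >= 8`, `lattice`,
#'   `seed`).
#' @return List with `grid` (a [spatial_grid()]) and `truth` holding
#'   `colocalized_pairs`, `segregated_pairs`, `domain_map` (spot -> one of
#'   `"coloc"`, `"segA"`, `"segB"`, `"none"`), and `high_threshold`.
#' @examples
#' sp <- simulate_spatial(sim_config(grid_side = 10))
#' table(sp$truth$domain_map)
#' @export
simulate_spatial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$grid_side
  if (s < 8) stop("grid_side must be at least 8", call. = FALSE)
  set.seed(config$seed)

  row <- rep(seq_len(s) - 1L, each = s)
  col <- rep(seq_len(s) - 1L, times = s)
  if (config$lattice == "hex") {
    x <- col + 0.5 * (row %% 2)
    y <- row * sqrt(3) / 2
  } else {
    x <- as.numeric(col)
    y <- as.numeric(row)
  }
  n <- s * s
  coords <- data.frame(spot_id = sprintf("spot%04d", seq_len(n)), x = x, y = y)

  in_disk <- function(cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2
  r <- 0.14 * s
  dom_coloc <- in_disk(0.25 * max(x), 0.25 * max(y), r)
  dom_segA <- in_disk(0.18 * max(x), 0.82 * max(y), r)
  dom_segB <- in_disk(0.82 * max(x), 0.82 * max(y), r)

  highf <- function(m) ifelse(m, runif(n, 4.5, 8), runif(n, 0, 1))
  ab <- rbind(
    Uniform = rep(5, n),
    CoA = highf(dom_coloc),
    CoB = highf(dom_coloc),
    SegA = highf(dom_segA),
    SegB = highf(dom_segB),
    Bg1 = runif(n, 0, 2),
    Bg2 = runif(n, 0, 2),
    Bg3 = runif(n, 0, 2))
  colnames(ab) <- coords$spot_id

  domain_map <- rep("none", n)
  domain_map[dom_coloc] <- "coloc"
  domain_map[dom_segA] <- "segA"
  domain_map[dom_segB] <- "segB"
  names(domain_map) <- coords$spot_id

  truth <- structure(list(
    colocalized_pairs = list(c("CoA", "CoB")),
    segregated_pairs = list(c("SegA", "SegB")),
    domain_map = domain_map,
    high_threshold = 3,
    config = config), class = "ground_truth")

  list(grid = spatial_grid(coords, ab, config$lattice), truth = truth)
}
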