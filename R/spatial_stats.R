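# Region-level descriptive spatial statistics: density grids, annotated
# region composition, immune-desert calling, cross-type nearest-neighbor
# gaps, Pearson correlation, and the caliper tumor-volume utility.

.REGION_LABELS <- c("lymphoid_aggregate", "satellite", "edge_NOS2pos",
                    "edge_NOS2neg", "large_tumor_nest", "tumor_core",
                    "immune_desert", "stroma")

#' Region annotation polygon
#'
#' @param label One of the fixed region vocabulary:
#'   lymphoid_aggregate, satellite, edge_NOS2pos, edge_NOS2neg,
#'   large_tumor_nest, tumor_core, immune_desert, stroma.
#' @param x,y Polygon vertex coordinates in um (closed implicitly). The
#'   polygon must be simple (non-self-intersecting).
#' @return Object of class `region_annotation` carrying the label, the
#'   vertices and the polygon area (mm^2).
#' @export
region_annotation <- function(label, x, y) {
  label <- match.arg(label, .REGION_LABELS)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  # drop a repeated closing vertex
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)   # shoelace, signed
  if (abs(area2) < .Machine$double.eps)
    stop("degenerate (zero-area) polygon")
  if (area2 < 0) { x <- rev(x); y <- rev(y) }  # enforce anticlockwise
  win <- spatstat.geom::owin(poly = list(x = x, y = y))
  structure(list(label = label, x = x, y = y, window = win,
                 area_mm2 = abs(area2) / 2 * 1e-6),
            class = "region_annotation")
}

# boundary-inclusive point-in-polygon: interior via inside.owin, plus
# points within a tiny tolerance of the boundary (documented convention)
.points_in_region <- function(x, y, region) {
  inside <- spatstat.geom::inside.owin(x, y, region$window)
  if (!all(inside)) {
    tol <- 1e-9 * max(diff(region$window$xrange), diff(region$window$yrange))
    inside[!inside] <- .dist_to_polygon(x[!inside], y[!inside], region) <= tol
  }
  inside
}

# distance from points to polygon boundary (segment-wise)
.dist_to_polygon <- function(px, py, region) {
  vx <- c(region$x, region$x[1]); vy <- c(region$y, region$y[1])
  d <- rep(Inf, length(px))
  for (s in seq_len(length(vx) - 1L)) {
    ax <- vx[s]; ay <- vy[s]; bx <- vx[s + 1L]; by <- vy[s + 1L]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2, 0), 1)
    d <- pmin(d, sqrt((px - (ax + t * (bx - ax)))^2 +
                      (py - (ay + t * (by - ay)))^2))
  }
  d
}

#' Density grid of selected cells
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param selector Logical vector (one per cell) choosing the cells to
#'   count, or `NULL` for all cells.
#' @param bin_size_um Square bin side length in um.
#' @param bounds Field bounding box `c(xmin, xmax, ymin, ymax)`; default
#'   the coordinate range over all cells.
#' @return Object of class `density_grid`: `density` matrix (cells/mm^2,
#'   rows = x bins), `x_edges`, `y_edges`, `bin_area_mm2`, `n_selected`.
#'   Conservation: `sum(density) * bin_area_mm2 == n_selected` exactly.
#' @export
density_grid <- function(cells, selector = NULL, bin_size_um,
                         bounds = NULL) {
  stopifnot(bin_size_um > 0, all(c("x_um", "y_um") %in% names(cells)))
  if (is.null(selector)) selector <- rep(TRUE, nrow(cells))
  stopifnot(length(selector) == nrow(cells))
  if (is.null(bounds)) bounds <- c(range(cells$x_um), range(cells$y_um))
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / bin_size_um))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / bin_size_um))
  x_edges <- bounds[1] + bin_size_um * (0:nx)
  y_edges <- bounds[3] + bin_size_um * (0:ny)
  x <- cells$x_um[selector]; y <- cells$y_um[selector]
  if (!length(x)) warning("empty selection: all-zero density grid")
  bx <- .bin_index(x, x_edges)
  by <- .bin_index(y, y_edges)
  counts <- tabulate((by - 1L) * nx + bx, nbins = nx * ny)
  bin_area <- bin_size_um^2 * 1e-6
  structure(list(density = matrix(counts, nx, ny) / bin_area,
                 x_edges = x_edges, y_edges = y_edges,
                 bin_area_mm2 = bin_area, n_selected = length(x)),
            class = "density_grid")
}

#' Per-region percentage of selected cells
#'
#' Cells are assigned to annotated regions by boundary-inclusive
#' point-in-polygon; a cell inside several overlapping regions is assigned
#' to the first label in the documented priority order
#' (lymphoid_aggregate > satellite > edges > large_tumor_nest >
#' tumor_core > immune_desert > stroma), with a warning.
#' Percentages use region-local denominators.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param annotations List of [region_annotation()] objects.
#' @param selector Logical vector marking the cells of interest (e.g.
#'   CD8+), one per cell.
#' @return Data frame with `label`, `n_cells`, `n_selected`, `percent`
#'   (`NA` for regions containing no cells).
#' @export
region_percentages <- function(cells, annotations, selector) {
  stopifnot(length(selector) == nrow(cells),
            all(vapply(annotations, inherits, logical(1),
                       "region_annotation")))
  labels <- vapply(annotations, `[[`, character(1), "label")
  ord <- order(match(labels, .REGION_LABELS))
  membership <- rep(NA_integer_, nrow(cells))
  overlap <- FALSE
  for (ai in ord) {
    inside <- .points_in_region(cells$x_um, cells$y_um, annotations[[ai]])
    overlap <- overlap || any(inside & !is.na(membership))
    membership[inside & is.na(membership)] <- ai
  }
  if (overlap)
    warning("overlapping regions: cells assigned by label priority order")
  out <- do.call(rbind, lapply(seq_along(annotations), function(ai) {
    idx <- which(membership == ai)
    n <- length(idx)
    data.frame(label = labels[ai], n_cells = n,
               n_selected = sum(selector[idx]),
               percent = if (n > 0) 100 * sum(selector[idx]) / n else
                 NA_real_)
  }))
  out
}

#' Immune-desert call for a region
#'
#' A region is an immune desert when its CD8+ cell density is strictly
#' below the threshold (default 100 cells/mm^2).
#'
#' @param cells Cell table with `x_um`, `y_um` and either a logical
#'   `cd8_pos` column or an integer `phenotype` column (codes 4-7 = CD8+).
#' @param region A [region_annotation()], or a numeric region area in mm^2
#'   (in which case all cells are taken to lie in the region).
#' @param threshold Density threshold in cells/mm^2.
#' @return `TRUE` if the region's CD8+ density is below the threshold.
#' @export
immune_desert_call <- function(cells, region, threshold = 100) {
  stopifnot(threshold > 0)
  cd8 <- if ("cd8_pos" %in% names(cells)) as.logical(cells$cd8_pos)
         else if ("phenotype" %in% names(cells)) cells$phenotype >= 4L
         else stop("cells need a 'cd8_pos' or 'phenotype' column")
  if (inherits(region, "region_annotation")) {
    inside <- .points_in_region(cells$x_um, cells$y_um, region)
    area <- region$area_mm2
    n_cd8 <- sum(cd8 & inside)
  } else {
    area <- as.numeric(region)
    n_cd8 <- sum(cd8)
  }
  if (!is.finite(area) || area <= 0) stop("region area must be positive")
  (n_cd8 / area) < threshold
}

#' Cross-type nearest-neighbor gap distances
#'
#' For every cell of set A, the distance to its nearest cell of set B;
#' summaries are over A. Not symmetric in its arguments.
#'
#' @param a,b Cell tables (or 2-column matrices) of coordinates in um.
#' @return List with `mean`, `median` and the full `distances` vector (um).
#' @export
crosstype_nn_gap <- function(a, b) {
  xy <- function(z) {
    if (is.data.frame(z)) as.matrix(z[, c("x_um", "y_um")]) else as.matrix(z)
  }
  A <- xy(a); B <- xy(b)
  if (!nrow(A) || !nrow(B)) stop("both cell sets must be nonempty")
  d <- FNN::get.knnx(B, A, k = 1)$nn.dist[, 1]
  list(mean = mean(d), median = stats::median(d), distances = d)
}

#' Pearson correlation with R-squared and p-value
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return List with `r`, `r_squared` and the two-sided `p` from the t
#'   distribution on n - 2 df.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value)
}

#' Caliper tumor volume
#'
#' `volume = short^2 * long / 2` in mm^3, from two orthogonal caliper
#' diameters in mm.
#'
#' @param short_diameter_mm,long_diameter_mm Caliper measurements with
#'   `0 < short <= long`.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(4, 8)   # 64
#' tumor_volume(5, 10)  # 125
#' @export
tumor_volume <- function(short_diameter_mm, long_diameter_mm) {
  stopifnot(all(short_diameter_mm > 0))
  if (any(short_diameter_mm > long_diameter_mm))
    stop("short diameter exceeds long diameter; measurements swapped?")
  short_diameter_mm^2 * long_diameter_mm / 2
}
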