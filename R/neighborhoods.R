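# Per-cell phenotype density census over annular distance bins.
#
# Each cell's neighborhood is summarised as the density (cells/mm^2) of each
# of the 8 phenotypes within concentric annuli around it; with the default
# bins [0,25,50,100,150,200] um this is a 40-value descriptor per cell.
# Counts are divided by the exact annulus area pi*(hi^2 - lo^2) in mm^2;
# intervals are half-open [lo, hi) and the focal cell is excluded.

#' Annular distance bins
#'
#' @param edges Strictly increasing non-negative bin edges in um; the default
#'   `c(0, 25, 50, 100, 150, 200)` defines 5 annuli out to 200 um.
#' @return Object of class `distance_bins` with elements `edges`, `n_bins`,
#'   `areas_mm2` (exact annulus areas) and `r_max`.
#' @export
distance_bins <- function(edges = c(0, 25, 50, 100, 150, 200)) {
  stopifnot(is.numeric(edges), length(edges) >= 2L, all(is.finite(edges)),
            edges[1] >= 0, all(diff(edges) > 0))
  nb <- length(edges) - 1L
  areas <- pi * diff(edges^2) * 1e-6   # um^2 -> mm^2
  structure(list(edges = as.numeric(edges), n_bins = nb,
                 areas_mm2 = areas, r_max = edges[length(edges)]),
            class = "distance_bins")
}

#' @export
print.distance_bins <- function(x, ...) {
  cat("Distance bins (um):", paste(x$edges, collapse = ", "),
      sprintf(" (%d annuli, r_max %g um)\n", x$n_bins, x$r_max))
  invisible(x)
}

.profile_colnames <- function(bins) {
  as.vector(t(outer(0:7, seq_len(bins$n_bins),
                    function(p, b) sprintf("d%d_b%d", p, b))))
}

.check_census_input <- function(cells) {
  need <- c("x_um", "y_um", "phenotype")
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop("cell table lacks columns: ", paste(missing, collapse = ", "))
  bad <- !is.finite(cells$x_um) | !is.finite(cells$y_um)
  if (any(bad)) {
    ids <- if ("cell_id" %in% names(cells)) cells$cell_id[bad] else which(bad)
    stop("missing/non-finite coordinates for cell(s): ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  if ("sample_id" %in% names(cells) &&
      length(unique(cells$sample_id)) > 1L)
    stop("census operates on a single sample; split by sample_id first")
  stopifnot(all(cells$phenotype %in% 0:7))
  invisible(cells)
}

# accumulate pair lists (i, phenotype of j, bin) into an n x 8*nb matrix
.accumulate_profiles <- function(i, ph_j, bin, n, bins) {
  nb <- bins$n_bins
  col <- ph_j * nb + bin                      # 1-based column, phenotype-major
  counts <- tabulate((col - 1L) * n + i, nbins = n * 8L * nb)
  M <- matrix(counts, nrow = n, ncol = 8L * nb)
  sweep(M, 2L, rep(bins$areas_mm2, 8L), "/")
}

#' Neighborhood profile of a single cell
#'
#' @param cells Phenotyped single-sample cell table (columns `x_um`, `y_um`,
#'   `phenotype`, and `cell_id` if `focal_id` is a character id).
#' @param focal_id Cell id (matched against `cell_id`) or row index.
#' @param bins A [distance_bins()].
#' @return Named numeric vector of length `8 * n_bins` (phenotype-major:
#'   all bins of phenotype 0, then phenotype 1, ...), densities in
#'   cells/mm^2.
#' @export
census_cell <- function(cells, focal_id, bins = distance_bins()) {
  .check_census_input(cells)
  stopifnot(inherits(bins, "distance_bins"))
  if (is.character(focal_id)) {
    idx <- match(focal_id, cells$cell_id)
    if (is.na(idx)) stop("focal cell '", focal_id, "' not found")
  } else {
    idx <- as.integer(focal_id)
    if (idx < 1L || idx > nrow(cells)) stop("focal index out of range")
  }
  d <- sqrt((cells$x_um - cells$x_um[idx])^2 +
            (cells$y_um - cells$y_um[idx])^2)
  keep <- seq_len(nrow(cells)) != idx & d < bins$r_max
  bin <- findInterval(d[keep], bins$edges)     # [lo, hi) half-open
  prof <- .accumulate_profiles(rep(1L, sum(keep)),
                               as.integer(cells$phenotype[keep]), bin,
                               1L, bins)[1L, ]
  stats::setNames(prof, .profile_colnames(bins))
}

#' Neighborhood profiles of all cells in a sample
#'
#' Uses a spatial fixed-radius pair search ([spatstat.geom::closepairs()]);
#' row order matches the input cell order. Cells whose outermost disk
#' crosses the tissue bounds can be kept, flagged or excluded.
#'
#' @param cells Phenotyped single-sample cell table.
#' @param bins A [distance_bins()].
#' @param edge_policy `"flag"` (default; attach logical `edge_flag`
#'   attribute), `"keep"` (no flag) or `"exclude"` (drop edge cells).
#' @param bounds Tissue bounding box `c(xmin, xmax, ymin, ymax)` in um;
#'   default the coordinate range of the sample.
#' @return `n x (8 * n_bins)` matrix of densities (cells/mm^2), rownames =
#'   cell ids (if present), with attribute `edge_flag` unless
#'   `edge_policy = "keep"`.
#' @export
census_all <- function(cells, bins = distance_bins(),
                       edge_policy = c("flag", "keep", "exclude"),
                       bounds = NULL) {
  edge_policy <- match.arg(edge_policy)
  .check_census_input(cells)
  stopifnot(inherits(bins, "distance_bins"))
  n <- nrow(cells)
  cn <- .profile_colnames(bins)
  rn <- if ("cell_id" %in% names(cells)) cells$cell_id else NULL
  if (n == 0L)
    return(matrix(numeric(0), 0L, length(cn), dimnames = list(NULL, cn)))
  if (is.null(bounds))
    bounds <- c(range(cells$x_um), range(cells$y_um))
  stopifnot(length(bounds) == 4L)
  if (n == 1L) {
    M <- matrix(0, 1L, length(cn), dimnames = list(rn, cn))
  } else {
    win <- spatstat.geom::owin(xrange = bounds[1:2], yrange = bounds[3:4])
    X <- spatstat.geom::ppp(cells$x_um, cells$y_um, window = win,
                            checkdup = FALSE)
    cp <- spatstat.geom::closepairs(X, rmax = bins$r_max, what = "ijd",
                                    twice = TRUE, distinct = TRUE)
    # closepairs returns d <= rmax; drop d == rmax to keep bins half-open
    keep <- cp$d < bins$r_max
    bin <- findInterval(cp$d[keep], bins$edges)
    bin[bin < 1L] <- 1L                        # guard: d >= edges[1] always
    M <- .accumulate_profiles(cp$i[keep],
                              as.integer(cells$phenotype[cp$j[keep]]),
                              bin, n, bins)
    dimnames(M) <- list(rn, cn)
  }
  edge <- cells$x_um - bounds[1] < bins$r_max |
          bounds[2] - cells$x_um < bins$r_max |
          cells$y_um - bounds[3] < bins$r_max |
          bounds[4] - cells$y_um < bins$r_max
  if (edge_policy == "exclude") {
    M <- M[!edge, , drop = FALSE]
  } else if (edge_policy == "flag") {
    attr(M, "edge_flag") <- edge
  }
  M
}

#' Brute-force all-pairs census (reference implementation)
#'
#' Exhaustive O(n^2) computation with the same contract as
#' `census_all(..., edge_policy = "keep")`; intended for validation on
#' small samples.
#'
#' @param cells Phenotyped single-sample cell table.
#' @param bins A [distance_bins()].
#' @return `n x (8 * n_bins)` density matrix.
#' @export
census_oracle <- function(cells, bins = distance_bins()) {
  .check_census_input(cells)
  n <- nrow(cells)
  cn <- .profile_colnames(bins)
  rn <- if ("cell_id" %in% names(cells)) cells$cell_id else NULL
  M <- matrix(0, n, length(cn), dimnames = list(rn, cn))
  if (n < 2L) return(M)
  ph <- as.integer(cells$phenotype)
  nb <- bins$n_bins
  for (i in seq_len(n)) {
    d <- sqrt((cells$x_um - cells$x_um[i])^2 +
              (cells$y_um - cells$y_um[i])^2)
    keep <- which(seq_len(n) != i & d < bins$r_max)
    if (!length(keep)) next
    b <- pmax(findInterval(d[keep], bins$edges), 1L)
    col <- ph[keep] * nb + b
    M[i, ] <- tabulate(col, nbins = 8L * nb) / rep(bins$areas_mm2, 8L)
  }
  M
}
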