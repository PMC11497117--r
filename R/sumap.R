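# Embedding of neighborhood profiles, group-contrast 2D histograms with
# log-ratio thresholding, and niche discovery by Davies-Bouldin-adaptive
# k-means.

#' Embed neighborhood profiles in 2D with UMAP
#'
#' @param profiles Numeric matrix (cells x profile entries), no NaN.
#' @param n_neighbors UMAP neighbor count (default 30).
#' @param min_dist UMAP minimum spacing (default 0.1).
#' @param metric Distance metric (default Euclidean).
#' @param seed Integer seed; fixed seed and parameters give identical
#'   coordinates.
#' @param scale_profiles If `TRUE`, z-score profile columns before
#'   embedding (default `FALSE`: profiles are used unscaled).
#' @param bin_areas Optional vector of annulus areas (mm^2), one per
#'   distance bin (recycled across the 8 phenotype blocks). When given,
#'   density columns are multiplied by their annulus area so the embedding
#'   operates on expected neighbor *counts*. This equalises Poisson shot
#'   noise across annuli: the innermost annulus is ~100x smaller than the
#'   outermost, so raw densities there move in steps of hundreds of
#'   cells/mm^2 per neighbor and would otherwise dominate the Euclidean
#'   metric.
#' @return `n x 2` coordinate matrix with the hyperparameters and seed
#'   attached as attribute `params`.
#' @export
embed_profiles <- function(profiles, n_neighbors = 30, min_dist = 0.1,
                           metric = "euclidean", seed = 42L,
                           scale_profiles = FALSE, bin_areas = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 10L)
    stop("need at least 10 profiles to embed")
  if (anyNA(profiles) || any(!is.finite(profiles)))
    stop("profiles contain non-finite values")
  if (nrow(profiles) <= n_neighbors)
    stop("fewer profiles (", nrow(profiles), ") than n_neighbors (",
         n_neighbors, "); reduce n_neighbors")
  if (!is.null(bin_areas)) {
    if (ncol(profiles) %% length(bin_areas) != 0L)
      stop("length of 'bin_areas' must divide the profile width")
    profiles <- sweep(profiles, 2L,
                      rep(bin_areas, ncol(profiles) / length(bin_areas)),
                      "*")
  }
  X <- if (scale_profiles) {
    sdv <- matrixStats::colSds(profiles)
    scale(profiles, center = TRUE, scale = ifelse(sdv > 0, sdv, 1))
  } else profiles
  coords <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = metric, n_threads = 1, n_sgd_threads = 0,
                       seed = as.integer(seed), verbose = FALSE)
  dimnames(coords) <- list(rownames(profiles), c("umap1", "umap2"))
  attr(coords, "params") <- list(n_neighbors = n_neighbors,
                                 min_dist = min_dist, metric = metric,
                                 seed = as.integer(seed),
                                 scale_profiles = scale_profiles,
                                 count_scaled = !is.null(bin_areas))
  coords
}

.bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Group-normalized 2D histograms of an embedding
#'
#' Both groups share one grid spanning the joint extent; per-group bin
#' frequencies are counts divided by the group total, so each group's
#' frequencies sum to 1.
#'
#' @param coords `n x 2` embedding coordinates.
#' @param groups Vector/factor with exactly two levels, one value per row.
#' @param n_bins Bins per axis (default 100).
#' @return Object of class `group_histogram`: `x_edges`, `y_edges`,
#'   `freq` (named list of two frequency matrices), `counts` (group
#'   totals), `bin_x`/`bin_y` (per-cell bin indices).
#' @export
group_histograms <- function(coords, groups, n_bins = 100) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(groups),
            n_bins >= 2L)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels")
  if (any(table(groups) == 0L))
    stop("each group must contain at least one cell")
  x_edges <- seq(min(coords[, 1]), max(coords[, 1]), length.out = n_bins + 1L)
  y_edges <- seq(min(coords[, 2]), max(coords[, 2]), length.out = n_bins + 1L)
  bx <- .bin_index(coords[, 1], x_edges)
  by <- .bin_index(coords[, 2], y_edges)
  freq <- lapply(levels(groups), function(g) {
    sel <- groups == g
    counts <- tabulate((by[sel] - 1L) * n_bins + bx[sel],
                       nbins = n_bins * n_bins)
    matrix(counts, n_bins, n_bins) / sum(sel)   # rows = x bins
  })
  names(freq) <- levels(groups)
  structure(list(x_edges = x_edges, y_edges = y_edges, freq = freq,
                 counts = as.vector(table(groups)),
                 levels = levels(groups), bin_x = bx, bin_y = by),
            class = "group_histogram")
}

#' Log-ratio field between two group histograms
#'
#' Computes `log10((f_num + eps) / (f_den + eps))` bin-wise on the shared
#' grid. The field negates exactly under group swap.
#'
#' @param hist A [group_histograms()] result.
#' @param numerator,denominator Group level names; default the first
#'   (conventionally deceased) and second (alive) levels.
#' @param eps Pseudofrequency guarding empty bins; default
#'   `1 / max(group counts)`.
#' @param tau Prevalence threshold on the log10 scale (default 0.01).
#' @return Object of class `log_ratio_field` with elements `field` (matrix),
#'   `x_edges`, `y_edges`, `eps`, `tau`, `numerator`, `denominator`.
#' @export
log_ratio_field <- function(hist, numerator = NULL, denominator = NULL,
                            eps = NULL, tau = 0.01) {
  stopifnot(inherits(hist, "group_histogram"), tau > 0)
  if (is.null(numerator)) numerator <- hist$levels[1]
  if (is.null(denominator)) denominator <- hist$levels[2]
  stopifnot(all(c(numerator, denominator) %in% hist$levels),
            numerator != denominator)
  if (is.null(eps)) eps <- 1 / max(hist$counts)
  stopifnot(eps > 0)
  f_num <- hist$freq[[numerator]]
  f_den <- hist$freq[[denominator]]
  if (!all(dim(f_num) == dim(f_den)))
    stop("histogram grids do not match")
  structure(list(field = log10((f_num + eps) / (f_den + eps)),
                 x_edges = hist$x_edges, y_edges = hist$y_edges,
                 eps = eps, tau = tau,
                 numerator = numerator, denominator = denominator),
            class = "log_ratio_field")
}

#' @export
print.log_ratio_field <- function(x, ...) {
  cat(sprintf("log10 ratio field %s/%s: %d x %d bins, eps %.3g, tau %g\n",
              x$numerator, x$denominator, nrow(x$field), ncol(x$field),
              x$eps, x$tau))
  cat(sprintf("  field range [%.3f, %.3f]; %d bins > tau, %d bins < -tau\n",
              min(x$field), max(x$field), sum(x$field > x$tau),
              sum(x$field < -x$tau)))
  invisible(x)
}

#' Cells in group-prevalent histogram bins
#'
#' Numerator-prevalent cells are numerator-group cells lying in bins with
#' field value above `tau`; denominator-prevalent cells are
#' denominator-group cells in bins below `-tau`. The two bin sets are
#' disjoint by construction.
#'
#' @param field A [log_ratio_field()].
#' @param hist The [group_histograms()] the field was computed on (carries
#'   the per-cell bin indices).
#' @param groups The group vector used to build the histogram.
#' @return List with integer cell indices `numerator_cells`,
#'   `denominator_cells` and logical bin masks `numerator_bins`,
#'   `denominator_bins`.
#' @export
prevalence_cells <- function(field, hist, groups) {
  stopifnot(inherits(field, "log_ratio_field"),
            inherits(hist, "group_histogram"))
  if (!all(dim(field$field) == c(length(hist$x_edges) - 1L,
                                 length(hist$y_edges) - 1L)))
    stop("field grid does not match histogram grid")
  groups <- as.factor(groups)
  bins_num <- field$field > field$tau
  bins_den <- field$field < -field$tau
  in_num <- bins_num[cbind(hist$bin_x, hist$bin_y)]
  in_den <- bins_den[cbind(hist$bin_x, hist$bin_y)]
  list(numerator_cells = which(in_num & groups == field$numerator),
       denominator_cells = which(in_den & groups == field$denominator),
       numerator_bins = bins_num, denominator_bins = bins_den)
}

#' Davies-Bouldin index of a partition
#'
#' `DB = mean_i max_{j != i} (S_i + S_j) / d(c_i, c_j)` where `S_i` is the
#' mean Euclidean distance of cluster members to their centroid and `c_i`
#' the centroid. Lower is better.
#'
#' @param points Numeric matrix of observations.
#' @param labels Integer cluster labels (1..k), one per row.
#' @return The index value.
#' @export
davies_bouldin_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin index needs at least 2 clusters")
  centers <- t(vapply(seq_len(k), function(i)
    colMeans(points[labels == i, , drop = FALSE]), numeric(ncol(points))))
  S <- vapply(seq_len(k), function(i) {
    P <- points[labels == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(P, 2L, centers[i, ])^2)))
  }, numeric(1))
  D <- as.matrix(stats::dist(centers))
  R <- outer(S, S, "+") / D
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

# k-means++ seeding (Arthur & Vassilvitskii)
.kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1L, ] <- points[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(points, 2L, centers[1L, ])^2)
  for (i in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[i, ] <- points[sample.int(n, 1L), ]
    } else {
      centers[i, ] <- points[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(points, 2L, centers[i, ])^2))
  }
  centers
}

#' Adaptive k-means with Davies-Bouldin model selection
#'
#' For each candidate k, runs k-means (k-means++ initialisation,
#' `restarts` restarts, best within-cluster sum of squares kept) and
#' evaluates the Davies-Bouldin index of the resulting partition; the k
#' minimising the index is selected, ties broken toward smaller k.
#' Clusters are renamed by descending size as `<prefix>1`, `<prefix>2`, ...
#'
#' @param points `n x 2` (or `n x d`) numeric matrix.
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param seed Integer seed.
#' @param restarts Restarts per k (default 10).
#' @param name_prefix Cluster-name prefix, e.g. `"D"` for deceased-derived
#'   niches (D1, D2, ...) or `"A"` for alive.
#' @return Object of class `cluster_set`: `k`, `db_value`, `db_by_k`,
#'   `labels` (integer, 1 = largest cluster), `cluster_names`, `sizes`,
#'   `centers`, `name_prefix`.
#' @export
adaptive_kmeans <- function(points, k_range = 2:10, seed = 1L,
                            restarts = 10L, name_prefix = "C") {
  points <- as.matrix(points)
  n <- nrow(points)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1L), restarts >= 1L)
  if (n <= max(k_range))
    stop("need more points (", n, ") than max(k_range) (",
         max(k_range), ")")
  n_distinct <- nrow(unique(points))
  if (n_distinct < max(k_range))
    stop("only ", n_distinct, " distinct points; cannot form ",
         max(k_range), " clusters")
  set.seed(as.integer(seed))
  fits <- vector("list", length(k_range))
  db_by_k <- stats::setNames(rep(NA_real_, length(k_range)),
                             paste0("k", k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- suppressWarnings(
        stats::kmeans(points, centers = .kmeanspp_centers(points, k),
                      iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    fits[[ki]] <- best
    db_by_k[ki] <- if (k == 1L) Inf else
      davies_bouldin_index(points, best$cluster)
  }
  ki <- which.min(db_by_k)         # first minimum = smallest k on ties
  fit <- fits[[ki]]
  # relabel by descending cluster size
  ord <- order(fit$size, decreasing = TRUE)
  relabel <- match(fit$cluster, ord)
  structure(list(k = k_range[ki], db_value = unname(db_by_k[ki]),
                 db_by_k = db_by_k,
                 labels = relabel,
                 cluster_names = paste0(name_prefix, seq_len(k_range[ki])),
                 sizes = fit$size[ord],
                 centers = fit$centers[ord, , drop = FALSE],
                 name_prefix = name_prefix),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Adaptive k-means: k = %d (Davies-Bouldin %.4f)\n",
              x$k, x$db_value))
  cat("  sizes:", paste(sprintf("%s=%d", x$cluster_names, x$sizes),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Mean and SEM neighborhood profile per cluster
#'
#' @param labels Cluster labels (integers or names), one per profile row.
#' @param profiles Profile matrix aligned with `labels`.
#' @return Named list per cluster with `mean`, `sem` (sd/sqrt(n); 0 with a
#'   warning for singleton clusters) and `n`.
#' @export
cluster_mean_profile <- function(labels, profiles) {
  profiles <- as.matrix(profiles)
  stopifnot(length(labels) == nrow(profiles))
  out <- lapply(split(seq_along(labels), labels), function(idx) {
    P <- profiles[idx, , drop = FALSE]
    m <- colMeans(P)
    if (length(idx) == 1L) {
      warning("cluster of size 1: SEM reported as 0")
      s <- stats::setNames(rep(0, ncol(P)), colnames(P))
    } else {
      s <- matrixStats::colSds(P) / sqrt(length(idx))
      names(s) <- colnames(P)
    }
    list(mean = m, sem = s, n = length(idx))
  })
  out
}

#' Per-phenotype per-bin ratio of two cluster mean profiles
#'
#' @param numerator,denominator Mean-profile vectors (or `cluster_mean_profile`
#'   entries, whose `$mean` is used).
#' @param floor Denominator floor `delta` guarding division by zero;
#'   default 0, in which case an all-zero denominator entry is an error.
#' @return Ratio vector, same layout as the profiles.
#' @export
cluster_ratio_profile <- function(numerator, denominator, floor = 0) {
  get_mean <- function(x) if (is.list(x)) x$mean else x
  num <- get_mean(numerator)
  den <- get_mean(denominator)
  stopifnot(length(num) == length(den), floor >= 0)
  if (floor == 0 && any(den == 0))
    stop("denominator profile has zero entries; set a positive 'floor'")
  num / pmax(den, floor)
}

#' Cluster prevalence as a fraction of group cells
#'
#' @param cluster_set A [adaptive_kmeans()] result (or a vector of cluster
#'   sizes).
#' @param group_total Total number of cells in the originating group.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
cluster_prevalence <- function(cluster_set, group_total) {
  sizes <- if (inherits(cluster_set, "cluster_set")) {
    stats::setNames(cluster_set$sizes, cluster_set$cluster_names)
  } else cluster_set
  stopifnot(group_total >= sum(sizes))
  sizes / group_total
}
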