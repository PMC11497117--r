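test_that("embedding obeys shape, determinism and input contracts", {
  set.seed(1)
  X <- matrix(runif(60 * 40), 60, 40)
  e1 <- embed_profiles(X, n_neighbors = 10, seed = 3)
  expect_equal(dim(e1), c(60L, 2L))
  e2 <- embed_profiles(X, n_neighbors = 10, seed = 3)
  expect_equal(unname(e1), unname(e2))
  expect_error(embed_profiles(X[1:5, ], n_neighbors = 3), "at least 10")
  expect_error(embed_profiles(X, n_neighbors = 60), "n_neighbors")
  X[1, 1] <- NA
  expect_error(embed_profiles(X, n_neighbors = 10), "non-finite")
})

test_that("well-separated profile populations stay separated in 2D", {
  set.seed(5)
  a <- matrix(abs(rnorm(150 * 40, 0, 1)), 150, 40)
  b <- matrix(abs(rnorm(150 * 40, 0, 1)), 150, 40)
  b[, 1:10] <- b[, 1:10] + 50       # disjoint support in 10 coordinates
  e <- embed_profiles(rbind(a, b), n_neighbors = 15, seed = 9)
  ia <- 1:150; ib <- 151:300
  centroid_a <- colMeans(e[ia, ]); centroid_b <- colMeans(e[ib, ])
  inter <- sqrt(sum((centroid_a - centroid_b)^2))
  intra <- mean(c(sqrt(rowSums(sweep(e[ia, ], 2, centroid_a)^2)),
                  sqrt(rowSums(sweep(e[ib, ], 2, centroid_b)^2))))
  expect_gt(inter, intra)
})

test_that("count scaling multiplies density columns by annulus areas", {
  set.seed(2)
  X <- matrix(runif(40 * 40), 40, 40)
  areas <- distance_bins()$areas_mm2
  e1 <- embed_profiles(X, n_neighbors = 10, seed = 1, bin_areas = areas)
  e2 <- embed_profiles(sweep(X, 2, rep(areas, 8), "*"),
                       n_neighbors = 10, seed = 1)
  expect_equal(e1, e2, ignore_attr = TRUE)
})

test_that("group histograms are normalized on a shared grid", {
  set.seed(4)
  coords <- cbind(runif(200), runif(200))
  groups <- rep(c("deceased", "alive"), each = 100)
  h <- group_histograms(coords, groups, n_bins = 20)
  expect_equal(sum(h$freq$deceased), 1, tolerance = 1e-9)
  expect_equal(sum(h$freq$alive), 1, tolerance = 1e-9)
  expect_true(all(h$freq$deceased >= 0))
  # scale invariance: duplicating every cell of one group changes nothing
  coords2 <- rbind(coords, coords[groups == "alive", ])
  groups2 <- c(groups, rep("alive", 100))
  h2 <- group_histograms(coords2, groups2, n_bins = 20)
  expect_equal(h2$freq$alive, h$freq$alive, tolerance = 1e-12)
  expect_error(group_histograms(coords, rep("one", 200)), "two levels")
})

test_that("log-ratio fields are zero at equality and antisymmetric", {
  set.seed(6)
  coords <- cbind(runif(300), runif(300))
  groups <- rep(c("deceased", "alive"), 150)
  h <- group_histograms(coords, groups, n_bins = 15)
  # identical frequencies => exactly zero field
  h0 <- h
  h0$freq$alive <- h0$freq$deceased
  f0 <- log_ratio_field(h0, "deceased", "alive")
  expect_true(all(f0$field == 0))
  # antisymmetry under group swap
  f <- log_ratio_field(h, "deceased", "alive")
  f_swap <- log_ratio_field(h, "alive", "deceased")
  expect_equal(f_swap$field, -f$field, tolerance = 1e-12)
})

test_that("a frequency doubling gives log10(2) at small pseudofrequency", {
  h <- structure(list(
    x_edges = 0:1, y_edges = 0:1,
    freq = list(deceased = matrix(0.02), alive = matrix(0.01)),
    counts = c(1e9, 1e9), levels = c("deceased", "alive"),
    bin_x = 1L, bin_y = 1L), class = "group_histogram")
  f <- log_ratio_field(h, "deceased", "alive")
  expect_equal(f$field[1, 1], log10(2), tolerance = 1e-4)
  expect_equal(round(f$field[1, 1], 5), 0.30103)
})

test_that("prevalence selection is group-restricted and bin-disjoint", {
  set.seed(8)
  coords <- cbind(c(runif(100, 0, 1), runif(100, 2, 3)),
                  runif(200))
  groups <- factor(rep(c("deceased", "alive"), each = 100),
                   levels = c("deceased", "alive"))
  h <- group_histograms(coords, groups, n_bins = 10)
  f <- log_ratio_field(h, "deceased", "alive")
  pv <- prevalence_cells(f, h, groups)
  expect_false(any(pv$numerator_bins & pv$denominator_bins))
  expect_true(all(groups[pv$numerator_cells] == "deceased"))
  expect_true(all(groups[pv$denominator_cells] == "alive"))
  # disjoint supports: essentially all cells are group-prevalent
  expect_gt(length(pv$numerator_cells), 90)
  expect_gt(length(pv$denominator_cells), 90)
  # zero field selects nothing
  f0 <- f; f0$field[] <- 0
  pv0 <- prevalence_cells(f0, h, groups)
  expect_length(pv0$numerator_cells, 0L)
  expect_length(pv0$denominator_cells, 0L)
})

test_that("Davies-Bouldin matches the hand-computed 4-point value", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  # clusters {1,2} and {3,4}: S_i = 0.5 each, centroid distance 10
  expect_equal(davies_bouldin_index(pts, c(1, 1, 2, 2)), 0.1)
  cs <- adaptive_kmeans(pts, k_range = 2, seed = 1, restarts = 5)
  expect_equal(cs$k, 2L)
  expect_equal(cs$db_value, 0.1)
})

test_that("adaptive k-means recovers planted cluster counts", {
  for (k in 2:4) {
    hits <- sapply(1:8, function(seed) {
      blobs <- make_blobs(k, n_per = 120, sep = 10, sigma = 0.5,
                          seed = seed)
      cs <- adaptive_kmeans(blobs$points, k_range = 2:8, seed = seed,
                            restarts = 5)
      cs$k == k
    })
    expect_gte(mean(hits), 0.875)   # allow at most one miss in eight
  }
})

test_that("partitions are stable under input shuffling up to relabeling", {
  blobs <- make_blobs(3, n_per = 100, seed = 31)
  cs1 <- adaptive_kmeans(blobs$points, k_range = 2:6, seed = 7)
  perm <- sample(nrow(blobs$points))
  cs2 <- adaptive_kmeans(blobs$points[perm, ], k_range = 2:6, seed = 7)
  expect_equal(cs1$k, cs2$k)
  # same partition as sets: contingency table has one nonzero per row
  tab <- table(cs1$labels[perm], cs2$labels)
  expect_equal(sum(tab > 0), cs1$k)
})

test_that("degenerate point sets are rejected", {
  pts <- rbind(c(0, 0), c(0, 0), c(0, 0), c(1, 1))
  expect_error(adaptive_kmeans(pts, k_range = 3), "distinct")
  expect_error(adaptive_kmeans(make_blobs(2, n_per = 3)$points,
                               k_range = 2:10), "more points")
})

test_that("clusters are named by descending size", {
  set.seed(2)
  pts <- rbind(cbind(rnorm(300, 0, 0.3), rnorm(300, 0, 0.3)),
               cbind(rnorm(50, 20, 0.3), rnorm(50, 20, 0.3)))
  cs <- adaptive_kmeans(pts, k_range = 2:4, seed = 3, name_prefix = "D")
  expect_equal(cs$cluster_names[1], "D1")
  expect_true(all(diff(cs$sizes) <= 0))
  expect_equal(sum(cs$labels == 1L), cs$sizes[1])
})

test_that("cluster mean and SEM profiles follow closed forms", {
  v <- matrix(rep(c(3, 7), each = 4), 4, 2)
  mp <- cluster_mean_profile(rep("a", 4), v)
  expect_equal(unname(mp$a$mean), c(3, 7))
  expect_equal(unname(mp$a$sem), c(0, 0))
  two <- rbind(rep(0, 40), rep(2, 40))
  mp2 <- cluster_mean_profile(c("x", "x"), two)
  expect_equal(unname(mp2$x$mean), rep(1, 40))
  expect_equal(unname(mp2$x$sem), rep(1, 40))   # sd = sqrt(2), /sqrt(2)
  expect_warning(mp1 <- cluster_mean_profile(c("a", "b", "b"),
                                             matrix(1, 3, 5)),
                 "size 1")
  expect_equal(unname(mp1$a$sem), rep(0, 5))
})

test_that("ratio profiles divide mean profiles with a floor guard", {
  expect_equal(cluster_ratio_profile(rep(5, 4), rep(5, 4)), rep(1, 4))
  expect_equal(cluster_ratio_profile(c(10, 1), c(1, 1))[1], 10)
  expect_error(cluster_ratio_profile(c(1, 1), c(1, 0)), "floor")
  expect_equal(cluster_ratio_profile(c(1, 1), c(1, 0), floor = 0.5),
               c(1, 2))
  # reciprocal orientation
  num <- c(2, 8); den <- c(4, 2)
  expect_equal(cluster_ratio_profile(num, den) *
               cluster_ratio_profile(den, num), c(1, 1))
})

test_that("cluster prevalence fractions are bounded and exact", {
  expect_equal(unname(cluster_prevalence(c(a = 30, b = 20), 100)),
               c(0.3, 0.2))
  expect_equal(unname(cluster_prevalence(c(a = 50), 50)), 1)
  expect_equal(unname(cluster_prevalence(c(a = 0, b = 10), 10)), c(0, 1))
  expect_error(cluster_prevalence(c(a = 60), 50))
})
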