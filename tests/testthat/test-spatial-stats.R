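test_that("density grids count and conserve exactly", {
  cells <- make_cells(runif(100, 0, 1000), runif(100, 0, 1000))
  g <- density_grid(cells, NULL, bin_size_um = 1000,
                    bounds = c(0, 1000, 0, 1000))
  expect_equal(dim(g$density), c(1L, 1L))
  expect_equal(g$density[1, 1], 100)   # 100 cells in one 1 mm^2 bin
  g2 <- density_grid(cells, NULL, bin_size_um = 100,
                     bounds = c(0, 1000, 0, 1000))
  expect_equal(sum(g2$density) * g2$bin_area_mm2, 100)
  expect_warning(density_grid(cells, rep(FALSE, 100), 100), "empty")
})

test_that("Poisson-field grid variation matches the CSR prediction", {
  # CV of bin densities ~ 1/sqrt(lambda * bin area)
  lam <- 1000; bin <- 500
  cv <- sapply(1:10, function(seed) {
    set.seed(seed)
    n <- rpois(1, lam * 16)         # 4 x 4 mm field
    cells <- make_cells(runif(n, 0, 4000), runif(n, 0, 4000))
    g <- density_grid(cells, NULL, bin, bounds = c(0, 4000, 0, 4000))
    sd(g$density) / mean(g$density)
  })
  expected <- 1 / sqrt(lam * (bin / 1000)^2)
  expect_lt(abs(mean(cv) - expected) / expected, 0.2)
})

test_that("region percentages use local denominators and priorities", {
  square <- function(label, x0, y0, side)
    region_annotation(label, x0 + c(0, side, side, 0),
                      y0 + c(0, 0, side, side))
  cells <- rbind(make_cells(c(10, 20, 30), c(10, 20, 30), 4L),
                 make_cells(c(110, 120), c(10, 20), 0L, "S2"))
  cells$sample_id <- "S1"
  ann <- list(square("tumor_core", 0, 0, 50),
              square("stroma", 100, 0, 50),
              square("lymphoid_aggregate", 200, 0, 50))
  cd8 <- cells$phenotype >= 4
  out <- region_percentages(cells, ann, cd8)
  expect_equal(out$percent[out$label == "tumor_core"], 100)
  expect_equal(out$percent[out$label == "stroma"], 0)
  expect_true(is.na(out$percent[out$label == "lymphoid_aggregate"]))
  # overlapping annotations: aggregate outranks core
  ann2 <- list(square("tumor_core", 0, 0, 50),
               square("lymphoid_aggregate", 0, 0, 50))
  expect_warning(out2 <- region_percentages(cells, ann2, cd8),
                 "overlapping")
  expect_equal(out2$n_cells[out2$label == "lymphoid_aggregate"], 3L)
  expect_equal(out2$n_cells[out2$label == "tumor_core"], 0L)
})

test_that("boundary cells count as inside their region", {
  sq <- region_annotation("tumor_core", c(0, 100, 100, 0),
                          c(0, 0, 100, 100))
  cells <- make_cells(c(0, 50, 100, 150), c(0, 50, 100, 50), 4L)
  out <- region_percentages(cells, list(sq), rep(TRUE, 4))
  expect_equal(out$n_cells, 3L)   # corner, interior and far-corner points
})

test_that("simulated deceased tumors show CD8 exclusion from the core", {
  cfg <- small_config("immune_desert", seed = 17)
  s <- simulate_sample(cfg)
  ctr <- cfg$tumor_center_um
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  core <- region_annotation("tumor_core",
                            ctr[1] + 395 * cos(th), ctr[2] + 395 * sin(th))
  stroma_box <- region_annotation("stroma", c(0, 200, 200, 0),
                                  c(0, 0, 200, 200))
  cd8 <- s$truth$phenotype >= 4
  out <- region_percentages(s$cells, list(core, stroma_box), cd8)
  expect_equal(out$percent[out$label == "tumor_core"], 0)
  expect_gt(out$percent[out$label == "stroma"], 0)
})

test_that("immune desert calls use a strict density threshold", {
  cells99 <- make_cells(runif(99, 0, 1000), runif(99, 0, 1000), 4L)
  cells100 <- make_cells(runif(100, 0, 1000), runif(100, 0, 1000), 4L)
  expect_true(immune_desert_call(cells99, region = 1))
  expect_false(immune_desert_call(cells100, region = 1))   # boundary: < is strict
  expect_error(immune_desert_call(cells99, region = 0), "positive")
  # simulated desert cores are deserts for any seed
  for (seed in c(1, 2, 3)) {
    cfg <- small_config("immune_desert", seed = seed)
    s <- simulate_sample(cfg)
    ctr <- cfg$tumor_center_um
    th <- seq(0, 2 * pi, length.out = 80)[-80]
    core <- region_annotation("tumor_core",
                              ctr[1] + 400 * cos(th),
                              ctr[2] + 400 * sin(th))
    cells <- s$cells
    cells$cd8_pos <- s$truth$phenotype >= 4
    expect_true(immune_desert_call(cells, core))
  }
})

test_that("nearest-neighbor gaps follow geometry and set relations", {
  gap <- crosstype_nn_gap(make_cells(0, 0), make_cells(30, 40))
  expect_equal(gap$mean, 50)       # 3-4-5 triangle
  a <- make_cells(runif(20, 0, 100), runif(20, 0, 100))
  ab <- rbind(a, make_cells(runif(10, 0, 100), runif(10, 0, 100), 0, "S9"))
  expect_true(all(crosstype_nn_gap(a, a)$distances == 0))   # A subset of B
  # superset monotonicity: adding candidates can only shrink gaps
  b <- make_cells(runif(5, 200, 300), runif(5, 200, 300))
  g_b <- crosstype_nn_gap(a, b)$distances
  g_ab <- crosstype_nn_gap(a, rbind(b, a))$distances
  expect_true(all(g_ab <= g_b + 1e-12))
  expect_error(crosstype_nn_gap(a, a[0, ]), "nonempty")
})

test_that("tumor-edge to stroma-restricted CD8 gaps track the config", {
  # dense CD8 band immediately beyond the 50-um gap, so the mean
  # edge-cell-to-CD8 distance approaches the configured gap
  cfg <- simulation_config("immune_desert",
                           field_size_um = c(2000, 2000),
                           tumor_radius_um = 600, stroma_margin_um = 300,
                           cd8_gap_um = 50, cd8_band_um = 30,
                           intensities = list(
                             core = c("0" = 500, "1" = 300),
                             margin = c("0" = 100, "4" = 8000),
                             stroma = c("0" = 100)),
                           aggregate_clusters = list(n_parents = 0,
                                                     offspring_mean = 0,
                                                     sigma_um = 40),
                           seed = 23)
  s <- simulate_sample(cfg)
  r <- sqrt((s$cells$x_um - 1000)^2 + (s$cells$y_um - 1000)^2)
  edge_cells <- s$cells[r >= 595 & r < 600 & s$truth$phenotype < 4, ]
  cd8_cells <- s$cells[s$truth$phenotype >= 4, ]
  expect_gt(nrow(edge_cells), 5)
  gap <- crosstype_nn_gap(edge_cells, cd8_cells)
  expect_lt(abs(gap$mean - cfg$cd8_gap_um), 10)
  expect_gte(min(gap$distances), cfg$cd8_gap_um - 5)  # planted exclusion
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:20
  r <- pearson_r2(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  r2 <- pearson_r2(x, -x)
  expect_equal(r2$r, -1)
  expect_equal(r2$r_squared, 1)
  expect_error(pearson_r2(x, rep(3, 20)), "variance")
  expect_error(pearson_r2(1:2, 1:2))
  # null distribution: independent permutations are weakly correlated
  set.seed(10)
  small <- sapply(1:40, function(i) abs(pearson_r2(
    rnorm(100), rnorm(100))$r) < 0.3)
  expect_gte(mean(small), 0.95)
})

test_that("tumor volume follows the caliper formula", {
  expect_equal(tumor_volume(4, 8), 64)
  expect_equal(tumor_volume(5, 10), 125)
  expect_equal(tumor_volume(3, 3), 27 / 2)   # equal diameters: d^3/2
  expect_error(tumor_volume(8, 4), "swapped")
  expect_error(tumor_volume(0, 4))
  # strictly increasing in each argument
  expect_gt(tumor_volume(4.1, 8), tumor_volume(4, 8))
  expect_gt(tumor_volume(4, 8.1), tumor_volume(4, 8))
})
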