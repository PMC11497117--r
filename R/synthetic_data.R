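# Synthetic marked-point-pattern tissue generator.
#
# Emulates the three tumor architectures the analysis distinguishes:
#   immune_desert  - CD8-NOS2-COX2+ core devoid of CD8+ T cells
#   inflamed_margin- CD8-NOS2+COX2+ satellite clusters at the tumor edge,
#                    CD8+ cells stroma-restricted beyond a gap
#   fully_inflamed - diffuse CD8+NOS2-COX2- infiltration into the core
# Geometry: coordinates in um, origin bottom-left, y-up. The tumor core is a
# disk; the margin is the surrounding annulus; stroma is the rest of the
# rectangular field. Cells are homogeneous Poisson within region x phenotype,
# plus Thomas-type (Poisson parent, Gaussian offspring) clusters for edge
# satellites and stromal lymphoid aggregates.

.PHENO_CODES <- as.character(0:7)
.LEVEL_MEANS <- c(negative = 0.5, weak = 1.5, moderate = 2.5, strong = 3.5)

.default_intensities <- function(archetype) {
  z <- stats::setNames(numeric(8), .PHENO_CODES)
  lam <- function(...) { v <- z; a <- c(...); v[names(a)] <- a; v }
  switch(archetype,
    immune_desert = list(
      core   = lam("0" = 155, "1" = 495),
      margin = lam("0" = 185, "1" = 155, "3" = 20, "4" = 1000),
      stroma = lam("0" = 215, "4" = 75)),
    inflamed_margin = list(
      core   = lam("0" = 310, "1" = 250),
      margin = lam("0" = 155, "1" = 60, "3" = 250, "4" = 1000, "5" = 20),
      stroma = lam("0" = 215, "4" = 75)),
    fully_inflamed = list(
      core   = lam("0" = 220, "1" = 30, "2" = 20, "3" = 25, "4" = 340),
      margin = lam("0" = 220, "1" = 30, "2" = 20, "3" = 25, "4" = 340),
      stroma = lam("0" = 220, "1" = 30, "3" = 25, "4" = 280)),
    stop("unknown archetype: ", archetype))
}

#' Configuration for a synthetic tissue sample
#'
#' Defines the geometry, per-region phenotype intensities, cluster processes
#' and marker-noise model for one simulated sample. Defaults plant the
#' spatial structure each archetype stands for; in particular the
#' `inflamed_margin` margin carries a CD8-NOS2+COX2+ inflamed-edge zone
#' (250 cells/mm^2 background plus Thomas satellite clusters) calibrated so
#' that the realized local density within 25 um of a margin cell - after
#' annulus-boundary losses and the satellite offspring field - is
#' ~250 cells/mm^2, i.e. 10x the `fully_inflamed` background density of
#' that phenotype (25 cells/mm^2). The margin is wider (500 um) than the
#' 200 um neighborhood radius so that zone neighborhoods are not dominated
#' by cells straddling the zone boundary.
#'
#' @param archetype One of `"immune_desert"`, `"inflamed_margin"`,
#'   `"fully_inflamed"`.
#' @param field_size_um Width and height of the rectangular field (um).
#' @param tumor_center_um Tumor-core disk center; default field midpoint.
#' @param tumor_radius_um Tumor-core disk radius (um).
#' @param stroma_margin_um Width of the margin annulus around the core (um).
#' @param intensities Per-region list (`core`, `margin`, `stroma`) of named
#'   numeric vectors giving Poisson intensities (cells/mm^2) per phenotype
#'   code `"0"`..`"7"`. Default depends on `archetype`.
#' @param satellite_clusters Thomas-process parameters for CD8-NOS2+COX2+
#'   edge satellites (`inflamed_margin` only): `n_parents`, `offspring_mean`,
#'   `sigma_um`, `band_um` (radial band beyond the core edge where parents
#'   sit).
#' @param aggregate_clusters Thomas-process parameters for stromal CD8+
#'   lymphoid aggregates (deceased archetypes): `n_parents`,
#'   `offspring_mean`, `sigma_um`.
#' @param cd8_gap_um Minimum distance of CD8+ cells from the tumor edge in
#'   deceased archetypes (um).
#' @param cd8_band_um Width of the stroma-restricted CD8+ band in deceased
#'   archetypes: margin CD8+ intensities apply within
#'   `[gap, gap + band]` of the tumor edge (default 50 um, i.e. CD8+ cells
#'   sit 50-100 um from the margin); `Inf` disables the banding.
#' @param aggregate_offset_um Range of lymphoid-aggregate center distances
#'   from the tumor edge (um).
#' @param noise_sd Gaussian noise sd added to marker level means; 0 makes
#'   quantization by [canonical_rule()] exactly invertible.
#' @param nos2_strong_fraction Fraction of NOS2+ cells drawn at the strong
#'   (rather than moderate) level.
#' @param cox2_strong_fraction Fraction of COX2+ cells drawn at the strong
#'   level (default 0: COX2+ cells are moderate).
#' @param seed Integer RNG seed; identical config implies byte-identical
#'   output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(archetype = c("immune_desert",
                                            "inflamed_margin",
                                            "fully_inflamed"),
                              field_size_um = c(3000, 3000),
                              tumor_center_um = field_size_um / 2,
                              tumor_radius_um = 800,
                              stroma_margin_um = 500,
                              intensities = NULL,
                              satellite_clusters = list(n_parents = 12,
                                                        offspring_mean = 3,
                                                        sigma_um = 30,
                                                        band_um = 100),
                              aggregate_clusters = list(n_parents = 4,
                                                        offspring_mean = 40,
                                                        sigma_um = 40),
                              cd8_gap_um = 50,
                              cd8_band_um = 50,
                              aggregate_offset_um = c(500, 1000),
                              noise_sd = 0.15,
                              nos2_strong_fraction = 0.5,
                              cox2_strong_fraction = 0,
                              seed = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(length(field_size_um) == 2L, all(field_size_um > 0),
            length(tumor_center_um) == 2L,
            tumor_radius_um > 0, stroma_margin_um > 0,
            cd8_gap_um >= 0, cd8_band_um > 0,
            length(aggregate_offset_um) == 2L,
            all(aggregate_offset_um >= 0),
            !is.unsorted(aggregate_offset_um),
            noise_sd >= 0,
            nos2_strong_fraction >= 0, nos2_strong_fraction <= 1,
            cox2_strong_fraction >= 0, cox2_strong_fraction <= 1)
  for (cl in list(satellite_clusters, aggregate_clusters))
    stopifnot(cl$n_parents >= 0, cl$offspring_mean >= 0, cl$sigma_um > 0)
  outer_r <- tumor_radius_um + stroma_margin_um
  if (any(tumor_center_um - outer_r < 0) ||
      any(tumor_center_um + outer_r > field_size_um))
    stop("tumor core plus margin annulus must fit inside the field")
  if (prod(field_size_um) - pi * outer_r^2 <= 0)
    stop("stroma region has zero area; enlarge the field")
  if (is.null(intensities)) intensities <- .default_intensities(archetype)
  stopifnot(setequal(names(intensities), c("core", "margin", "stroma")))
  intensities <- lapply(intensities, function(v) {
    full <- stats::setNames(numeric(8), .PHENO_CODES)
    full[names(v)] <- v
    if (any(full < 0)) stop("intensities must be non-negative")
    full
  })
  if (archetype != "fully_inflamed" &&
      any(intensities$core[as.character(4:7)] > 0))
    stop("deceased archetypes confine CD8+ cells beyond cd8_gap_um; ",
         "core intensities for codes 4-7 must be 0")
  structure(list(archetype = archetype,
                 field_size_um = as.numeric(field_size_um),
                 tumor_center_um = as.numeric(tumor_center_um),
                 tumor_radius_um = tumor_radius_um,
                 stroma_margin_um = stroma_margin_um,
                 intensities = intensities,
                 satellite_clusters = satellite_clusters,
                 aggregate_clusters = aggregate_clusters,
                 cd8_gap_um = cd8_gap_um,
                 cd8_band_um = cd8_band_um,
                 aggregate_offset_um = as.numeric(aggregate_offset_um),
                 noise_sd = noise_sd,
                 nos2_strong_fraction = nos2_strong_fraction,
                 cox2_strong_fraction = cox2_strong_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$archetype, "archetype\n")
  cat(sprintf("  field %g x %g um, core r=%g um, margin %g um, seed %d\n",
              x$field_size_um[1], x$field_size_um[2], x$tumor_radius_um,
              x$stroma_margin_um, x$seed))
  invisible(x)
}

# region areas in mm^2 (core disk, margin annulus, stroma = rect minus disk)
.region_areas_mm2 <- function(config) {
  r0 <- config$tumor_radius_um
  r1 <- r0 + config$stroma_margin_um
  c(core = pi * r0^2,
    margin = pi * (r1^2 - r0^2),
    stroma = prod(config$field_size_um) - pi * r1^2) * 1e-6
}

# uniform points in annulus [r_lo, r_hi) around center (annulus inside field)
.runif_annulus <- function(n, center, r_lo, r_hi) {
  r <- sqrt(stats::runif(n, r_lo^2, r_hi^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# uniform points in field rectangle outside radius r_min (rejection)
.runif_stroma <- function(n, field, center, r_min) {
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- stats::runif(m, 0, field[1]); y <- stats::runif(m, 0, field[2])
    keep <- (x - center[1])^2 + (y - center[2])^2 >= r_min^2
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

.in_field <- function(xy, field) {
  xy[, 1] >= 0 & xy[, 1] <= field[1] & xy[, 2] >= 0 & xy[, 2] <= field[2]
}

# draw marker levels implied by a phenotype code, then noisy intensities
.draw_markers <- function(code, config) {
  n <- length(code)
  cd8_pos <- bitwAnd(code, 4L) > 0
  nos2_pos <- bitwAnd(code, 2L) > 0
  cox2_pos <- bitwAnd(code, 1L) > 0
  lv_cd8 <- ifelse(cd8_pos,
                   sample(c("weak", "moderate", "strong"), n, replace = TRUE),
                   "negative")
  lv_nos2 <- ifelse(nos2_pos,
                    ifelse(stats::runif(n) < config$nos2_strong_fraction,
                           "strong", "moderate"),
                    sample(c("negative", "weak"), n, replace = TRUE))
  lv_cox2 <- ifelse(cox2_pos,
                    ifelse(stats::runif(n) < config$cox2_strong_fraction,
                           "strong", "moderate"),
                    sample(c("negative", "weak"), n, replace = TRUE))
  noisy <- function(lv) pmax(.LEVEL_MEANS[lv] +
                               stats::rnorm(n, 0, config$noise_sd), 0)
  list(levels = data.frame(level_cd8 = lv_cd8, level_nos2 = lv_nos2,
                           level_cox2 = lv_cox2,
                           stringsAsFactors = FALSE),
       cd8 = unname(noisy(lv_cd8)), nos2 = unname(noisy(lv_nos2)),
       cox2 = unname(noisy(lv_cox2)))
}

#' Simulate one tissue sample
#'
#' Generates a marked point pattern according to `config` and returns the
#' cell table together with full ground truth (true phenotype, region and
#' niche membership per cell, realized per-region densities).
#'
#' In the two deceased archetypes all CD8+ cells (codes 4-7) are placed at
#' least `cd8_gap_um` beyond the tumor edge; in `fully_inflamed` they are
#' uniform across the core. Edge satellites and stromal lymphoid
#' aggregates are Thomas-type parent-offspring clusters.
#'
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier used in cell ids.
#' @return List with `cells` (data frame: cell_id, sample_id, x_um, y_um,
#'   cd8, nos2, cox2, region, true_phenotype), `truth` (per-cell niche
#'   labels, true levels, realized densities) and the `config`.
#' @export
simulate_sample <- function(config, sample_id = "S1") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  field <- config$field_size_um
  ctr <- config$tumor_center_um
  r0 <- config$tumor_radius_um
  r1 <- r0 + config$stroma_margin_um
  areas <- .region_areas_mm2(config)
  deceased <- config$archetype != "fully_inflamed"
  gap_r <- r0 + config$cd8_gap_um

  xs <- ys <- numeric(0)
  code <- integer(0)
  region <- niche <- character(0)
  add <- function(xy, cd, reg, ni) {
    if (!nrow(xy)) return()
    xs <<- c(xs, xy[, 1]); ys <<- c(ys, xy[, 2])
    code <<- c(code, rep(as.integer(cd), nrow(xy)))
    region <<- c(region, rep(reg, nrow(xy)))
    niche <<- c(niche, rep(ni, nrow(xy)))
  }

  # background Poisson per region x phenotype
  for (reg in names(config$intensities)) {
    lam <- config$intensities[[reg]]
    for (cd in .PHENO_CODES) {
      if (lam[cd] <= 0) next
      cd8_pos <- bitwAnd(as.integer(cd), 4L) > 0
      if (reg == "core") {
        n <- stats::rpois(1, lam[cd] * areas["core"])
        xy <- .runif_annulus(n, ctr, 0, r0)
      } else if (reg == "margin") {
        if (deceased && cd8_pos) {
          # stroma-restricted band beyond the CD8 gap
          lo <- min(gap_r, r1)
          hi <- min(gap_r + config$cd8_band_um, r1)
          if (hi <= lo) next
          area <- pi * (hi^2 - lo^2) * 1e-6
          n <- stats::rpois(1, lam[cd] * area)
          xy <- .runif_annulus(n, ctr, lo, hi)
        } else {
          n <- stats::rpois(1, lam[cd] * areas["margin"])
          xy <- .runif_annulus(n, ctr, r0, r1)
        }
      } else {
        n <- stats::rpois(1, lam[cd] * areas["stroma"])
        xy <- .runif_stroma(n, field, ctr, r1)
      }
      add(xy, cd, reg, "background")
    }
  }

  # CD8-NOS2+COX2+ satellite clusters at the tumor edge (inflamed margin)
  if (config$archetype == "inflamed_margin") {
    sc <- config$satellite_clusters
    if (sc$n_parents > 0 && sc$offspring_mean > 0) {
      band <- min(sc$band_um, config$stroma_margin_um)
      parents <- .runif_annulus(sc$n_parents, ctr, r0, r0 + band)
      for (p in seq_len(sc$n_parents)) {
        m <- stats::rpois(1, sc$offspring_mean)
        if (!m) next
        xy <- cbind(parents[p, 1] + stats::rnorm(m, 0, sc$sigma_um),
                    parents[p, 2] + stats::rnorm(m, 0, sc$sigma_um))
        xy <- xy[.in_field(xy, field), , drop = FALSE]
        add(xy, 3L, NA_character_, "satellite")
      }
    }
  }

  # stroma-restricted CD8+ lymphoid aggregates (deceased archetypes)
  if (deceased) {
    ac <- config$aggregate_clusters
    if (ac$n_parents > 0 && ac$offspring_mean > 0) {
      placed <- 0L; tries <- 0L
      while (placed < ac$n_parents && tries < 1000L) {
        tries <- tries + 1L
        p <- .runif_annulus(1, ctr, r0 + config$aggregate_offset_um[1],
                            r0 + config$aggregate_offset_um[2])
        if (!.in_field(p, field)) next
        placed <- placed + 1L
        m <- stats::rpois(1, ac$offspring_mean)
        if (!m) next
        xy <- cbind(p[1] + stats::rnorm(m, 0, ac$sigma_um),
                    p[2] + stats::rnorm(m, 0, ac$sigma_um))
        keep <- .in_field(xy, field) &
          (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 >= gap_r^2
        add(xy[keep, , drop = FALSE], 4L, NA_character_, "aggregate")
      }
      if (placed < ac$n_parents)
        warning("could not place all lymphoid aggregates inside the field")
    }
  }

  n <- length(xs)
  if (n == 0L) warning("simulated sample contains no cells")
  # region label from final position for cluster offspring
  r2 <- (xs - ctr[1])^2 + (ys - ctr[2])^2
  region_pos <- ifelse(r2 < r0^2, "core", ifelse(r2 < r1^2, "margin",
                                                 "stroma"))
  region[is.na(region)] <- region_pos[is.na(region)]
  for (reg in c("core", "margin", "stroma"))
    if (!any(region_pos == reg))
      warning("region '", reg, "' is empty in sample ", sample_id)

  mk <- .draw_markers(code, config)
  cells <- data.frame(
    cell_id = sprintf("%s_c%06d", sample_id, seq_len(n)),
    sample_id = rep(sample_id, n),
    x_um = xs, y_um = ys,
    cd8 = mk$cd8, nos2 = mk$nos2, cox2 = mk$cox2,
    region = region, true_phenotype = code,
    stringsAsFactors = FALSE)

  dens <- do.call(rbind, lapply(c("core", "margin", "stroma"), function(reg) {
    cnt <- tabulate(code[region_pos == reg] + 1L, nbins = 8L)
    data.frame(region = reg, phenotype = 0:7,
               lambda_config = unname(config$intensities[[reg]]),
               realized = cnt / areas[[reg]])
  }))
  truth <- list(phenotype = code, region = region_pos, niche = niche,
                levels = mk$levels, realized_density = dens)
  list(cells = cells, truth = truth, config = config)
}

# deterministic per-sample seed derived from a master seed (counter split)
.derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 104729 * i) %% 2147483647)
}

#' Simulate a two-outcome cohort
#'
#' Deceased samples alternate between the `inflamed_margin` and
#' `immune_desert` archetypes; alive samples are `fully_inflamed`.
#' Per-sample seeds are derived deterministically from the master seed, so
#' a fixed master seed reproduces the cohort exactly. Simple survival marks
#' are attached to the metadata (deceased: event within 5 years; alive:
#' censored at 5 years).
#'
#' @param n_deceased,n_alive Sample counts (each >= 1).
#' @param base_config Optional named list of [simulation_config()] arguments
#'   (geometry, noise, cluster settings) applied to every sample; archetype
#'   and seed are set per sample.
#' @param seed Master integer seed.
#' @return List with `cells` (all samples row-bound), `meta` (sample_id,
#'   group, archetype, seed, time_years, event) and `truth` (per-sample
#'   ground truth).
#' @export
simulate_cohort <- function(n_deceased, n_alive, base_config = NULL,
                            seed = 1L) {
  stopifnot(n_deceased >= 1, n_alive >= 1)
  if (inherits(base_config, "simulation_config"))
    base_config <- base_config[c("field_size_um", "tumor_center_um",
                                 "tumor_radius_um", "stroma_margin_um",
                                 "satellite_clusters", "aggregate_clusters",
                                 "cd8_gap_um", "cd8_band_um",
                                 "aggregate_offset_um",
                                 "noise_sd", "nos2_strong_fraction",
                                 "cox2_strong_fraction")]
  base_config <- as.list(base_config)
  archetypes <- c(rep_len(c("inflamed_margin", "immune_desert"), n_deceased),
                  rep("fully_inflamed", n_alive))
  groups <- rep(c("deceased", "alive"), c(n_deceased, n_alive))
  ids <- c(sprintf("D%02d", seq_len(n_deceased)),
           sprintf("A%02d", seq_len(n_alive)))
  n <- n_deceased + n_alive
  seeds <- vapply(seq_len(n), function(i) .derive_seed(seed, i), integer(1))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- do.call(simulation_config,
                   c(list(archetype = archetypes[i], seed = seeds[i]),
                     base_config))
    samples[[i]] <- simulate_sample(cfg, sample_id = ids[i])
  }
  set.seed(.derive_seed(seed, 0L))
  time <- ifelse(groups == "deceased", stats::runif(n, 0.5, 4.5), 5)
  meta <- data.frame(sample_id = ids, group = groups,
                     archetype = archetypes, seed = seeds,
                     time_years = time,
                     event = as.integer(groups == "deceased"),
                     stringsAsFactors = FALSE)
  list(cells = do.call(rbind, lapply(samples, `[[`, "cells")),
       meta = meta,
       truth = stats::setNames(lapply(samples, `[[`, "truth"), ids))
}

#' Simulate a survival cohort with a planted hazard ratio
#'
#' Event times are exponential with baseline hazard in the low stratum and
#' hazard multiplied by `true_hr` in the high stratum; optional random
#' censoring and administrative censoring at `horizon_years`.
#'
#' @param n Total number of subjects (split evenly into high/low strata;
#'   each stratum must receive >= 2).
#' @param true_hr Planted hazard ratio (> 0), high vs low.
#' @param censor_rate Probability that a subject is randomly censored
#'   before its event (0 <= rate < 1).
#' @param horizon_years Administrative censoring horizon; default `Inf`
#'   (no horizon), so `censor_rate = 0` yields all-events data.
#' @param baseline_rate Baseline exponential hazard (events/year); the
#'   default 0.04 is typical of 5-year survival in breast-cancer cohorts
#'   and keeps event fractions in the regime where observed/expected
#'   hazard-ratio estimators are well calibrated (they are biased toward
#'   the null when nearly all subjects have events).
#' @param seed Integer RNG seed.
#' @return Data frame: sample_id, time, event, stratum (`"high"`/`"low"`).
#' @export
simulate_survival_cohort <- function(n, true_hr, censor_rate = 0,
                                     horizon_years = Inf,
                                     baseline_rate = 0.04, seed = 1L) {
  stopifnot(true_hr > 0, censor_rate >= 0, censor_rate < 1,
            baseline_rate > 0, horizon_years > 0)
  n_high <- n %/% 2L
  n_low <- n - n_high
  if (n_high < 2L || n_low < 2L)
    stop("need at least 2 subjects per stratum (n >= 4)")
  set.seed(as.integer(seed))
  stratum <- rep(c("high", "low"), c(n_high, n_low))
  rate <- ifelse(stratum == "high", baseline_rate * true_hr, baseline_rate)
  time <- stats::rexp(n, rate)
  event <- rep(1L, n)
  if (censor_rate > 0) {
    cens <- stats::runif(n) < censor_rate
    time[cens] <- time[cens] * stats::runif(sum(cens))
    event[cens] <- 0L
  }
  over <- time > horizon_years
  time[over] <- horizon_years
  event[over] <- 0L
  data.frame(sample_id = sprintf("P%04d", seq_len(n)),
             time = time, event = event, stratum = stratum,
             stringsAsFactors = FALSE)
}
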