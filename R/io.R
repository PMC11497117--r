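# Readers/writers for the package's tabular formats and the umbrella
# pipeline driver. All file writes are atomic (write to a temp file in the
# target directory, then rename).

.REQUIRED_CELL_COLS <- c("cell_id", "sample_id", "x_um", "y_um")

.atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Read and validate a cell table
#'
#' Comma-separated, UTF-8, header required, '.' decimal. Requires
#' `cell_id`, `sample_id`, `x_um`, `y_um` and at least one marker
#' intensity column. Duplicate cell ids are an error; missing values and
#' non-finite coordinates are collected into the validation report.
#'
#' @param path CSV file path.
#' @param markers Marker columns expected (at least one must be present).
#' @return List with `cells` (data frame) and `report` (rows read, missing
#'   values per column, non-finite coordinate count).
#' @export
read_cell_table <- function(path, markers = c("cd8", "nos2", "cox2")) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.REQUIRED_CELL_COLS, names(cells))
  if (length(missing))
    stop("cell table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!any(markers %in% names(cells)))
    stop("cell table has none of the marker columns: ",
         paste(markers, collapse = ", "))
  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup))
    stop("duplicated cell_id(s): ", paste(utils::head(dup, 5),
                                          collapse = ", "))
  report <- list(
    n_rows = nrow(cells),
    missing_values = vapply(cells, function(v) sum(is.na(v)), integer(1)),
    nonfinite_coords = sum(!is.finite(cells$x_um) | !is.finite(cells$y_um)))
  list(cells = cells, report = report)
}

#' Write a cell table (atomically)
#'
#' @param cells Cell table data frame.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  .atomic_write(function(tmp)
    utils::write.csv(cells, tmp, row.names = FALSE, quote = FALSE), path)
}

#' Parse a GEO series-matrix file
#'
#' Minimal parser for the plain-text series-matrix format: `!`-prefixed
#' metadata lines plus the tab-separated expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`.
#'
#' @param path Path to an (uncompressed) series-matrix text file.
#' @return List with `expression` (numeric matrix, probes/genes x samples)
#'   and `metadata` (named list of character vectors from the sample
#'   metadata lines).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("not a series-matrix file: table delimiters not found")
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(expr) <- as.character(tab[[1L]])
  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  metadata <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t")[[1L]]
    key <- sub("^!", "", parts[1L])
    metadata[[key]] <- c(metadata[[key]], list(gsub("^\"|\"$", "",
                                                    parts[-1L])))
  }
  metadata <- lapply(metadata, function(x) if (length(x) == 1L) x[[1L]]
                     else x)
  list(expression = expr, metadata = metadata)
}

.write_json <- function(x, path) {
  .atomic_write(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), path)
}

#' Run the full neighborhood-niche pipeline on a cohort
#'
#' Chains phenotyping, per-sample neighborhood censuses, UMAP embedding,
#' group-contrast 2D histograms with log-ratio thresholding, adaptive
#' k-means niche discovery in both prevalent cell sets, per-cluster
#' mean/SEM and ratio profiles, and marker/CD8 ratio survival analysis.
#'
#' @param cohort List with `cells` (cell table across samples) and `meta`
#'   (sample_id, group in deceased/alive, optionally time_years/event),
#'   e.g. the output of [simulate_cohort()].
#' @param rule Quantization rule; `NULL` derives cohort quantile
#'   thresholds via [derive_rule()].
#' @param bins [distance_bins()] for the census.
#' @param edge_policy Census edge handling (see [census_all()]).
#' @param n_bins_grid Histogram bins per axis.
#' @param tau Log-ratio prevalence threshold.
#' @param k_range,restarts Adaptive k-means settings.
#' @param n_neighbors,min_dist UMAP settings.
#' @param embed_on `"count"` (default) embeds per-bin neighbor counts
#'   (densities times annulus area), equalising Poisson noise across
#'   annuli; `"density"` embeds the raw density profiles.
#' @param ratio_floor Denominator floor for cluster ratio profiles
#'   (cells/mm^2).
#' @param seed Master seed; embedding and clustering seeds derive from it.
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV and reports as JSON, plus a manifest of all parameters and seeds.
#' @return List with the phenotyped `cells`, `profiles`, `embedding`,
#'   `groups`, `hist`, `field`, `prevalence`, `clusters` (deceased/alive
#'   `cluster_set`s with mean profiles and prevalence), `ratio_profiles`
#'   (per deceased cluster vs the alive-prevalent mean), `survival`
#'   (per-sample ratios and hazard-ratio results) and `manifest`.
#' @export
run_pipeline <- function(cohort, rule = NULL, bins = distance_bins(),
                         edge_policy = "flag", n_bins_grid = 100,
                         tau = 0.01, k_range = 2:10, restarts = 10L,
                         n_neighbors = 30, min_dist = 0.1,
                         embed_on = c("count", "density"),
                         ratio_floor = 1e-6, seed = 42L, out_dir = NULL) {
  embed_on <- match.arg(embed_on)
  stopifnot(is.list(cohort), !is.null(cohort$cells), !is.null(cohort$meta))
  cells <- cohort$cells
  meta <- cohort$meta
  stopifnot(all(c("sample_id", "group") %in% names(meta)),
            all(meta$group %in% c("deceased", "alive")),
            all(cells$sample_id %in% meta$sample_id))
  if (!is.null(k_range)) stopifnot(length(k_range) >= 1L,
                                   max(k_range) >= min(k_range))
  if (is.null(rule)) rule <- derive_rule(cells)
  cells <- phenotype_cells(cells, rule)

  # per-sample censuses, preserving sample blocks in meta order
  sample_ids <- meta$sample_id
  by_sample <- lapply(sample_ids, function(s)
    cells[cells$sample_id == s, , drop = FALSE])
  profiles <- do.call(rbind, lapply(by_sample, census_all, bins = bins,
                                    edge_policy = edge_policy))
  cells <- do.call(rbind, by_sample)
  rownames(cells) <- NULL
  groups <- factor(meta$group[match(cells$sample_id, meta$sample_id)],
                   levels = c("deceased", "alive"))

  coords <- embed_profiles(profiles, n_neighbors = n_neighbors,
                           min_dist = min_dist, seed = seed,
                           bin_areas = if (embed_on == "count")
                             bins$areas_mm2)
  hist <- group_histograms(coords, groups, n_bins = n_bins_grid)
  field <- log_ratio_field(hist, "deceased", "alive", tau = tau)
  prev <- prevalence_cells(field, hist, groups)

  cluster_one <- function(idx, prefix, sub_seed) {
    if (length(idx) <= max(k_range)) {
      warning("too few ", prefix, "-prevalent cells to cluster")
      return(NULL)
    }
    cs <- adaptive_kmeans(coords[idx, , drop = FALSE], k_range = k_range,
                          seed = sub_seed, restarts = restarts,
                          name_prefix = prefix)
    cs$cell_index <- idx
    cs$mean_profiles <- cluster_mean_profile(
      cs$cluster_names[cs$labels], profiles[idx, , drop = FALSE])
    cs$prevalence <- cluster_prevalence(cs, sum(groups == ifelse(
      prefix == "D", "deceased", "alive")))
    cs
  }
  clusters <- list(
    deceased = cluster_one(prev$numerator_cells, "D",
                           .derive_seed(seed, 101L)),
    alive = cluster_one(prev$denominator_cells, "A",
                        .derive_seed(seed, 102L)))

  # ratio of each deceased niche to the pooled alive-prevalent neighborhood
  ratio_profiles <- NULL
  if (!is.null(clusters$deceased) && length(prev$denominator_cells)) {
    alive_mean <- colMeans(profiles[prev$denominator_cells, , drop = FALSE])
    ratio_profiles <- lapply(clusters$deceased$mean_profiles, function(cl)
      cluster_ratio_profile(cl$mean, alive_mean, floor = ratio_floor))
  }

  # per-sample marker/CD8 ratios and dichotomized survival
  ratios <- data.frame(
    sample_id = sample_ids,
    group = meta$group,
    nos2s_cd8 = vapply(by_sample, sample_ratio, numeric(1),
                       numerator = "nos2s", rule = rule, pseudocount = 1),
    cox2_cd8 = vapply(by_sample, sample_ratio, numeric(1),
                      numerator = "cox2", rule = rule, pseudocount = 1))
  surv <- list(ratios = ratios)
  if (all(c("time_years", "event") %in% names(meta))) {
    rec <- data.frame(sample_id = meta$sample_id, time = meta$time_years,
                      event = meta$event)
    for (rcol in c("nos2s_cd8", "cox2_cd8")) {
      stratum <- dichotomize_median(ratios[[rcol]])
      surv[[rcol]] <- tryCatch(
        hazard_ratio_mh(rec[stratum == "high", ], rec[stratum == "low", ]),
        error = function(e) {
          warning("survival analysis for ", rcol, " failed: ",
                  conditionMessage(e))
          NULL
        })
    }
  }

  manifest <- list(
    package = "spatialniche",
    version = as.character(utils::packageVersion("spatialniche")),
    seed = seed,
    derived_seeds = list(deceased_kmeans = .derive_seed(seed, 101L),
                         alive_kmeans = .derive_seed(seed, 102L)),
    parameters = list(bins = bins$edges, edge_policy = edge_policy,
                      n_bins_grid = n_bins_grid, tau = tau,
                      k_range = range(k_range), restarts = restarts,
                      n_neighbors = n_neighbors, min_dist = min_dist,
                      embed_on = embed_on, ratio_floor = ratio_floor,
                      rule = list(thresholds = rule$thresholds,
                                  positivity = rule$positivity)),
    samples = meta$sample_id,
    n_cells = nrow(cells),
    input_digest = sum(cells$x_um) + sum(cells$y_um))

  result <- list(cells = cells, profiles = profiles, embedding = coords,
                 groups = groups, hist = hist, field = field,
                 prevalence = prev, clusters = clusters,
                 ratio_profiles = ratio_profiles, survival = surv,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(cells, file.path(out_dir, "cells_phenotyped.csv"))
    .atomic_write(function(tmp) utils::write.csv(
      data.frame(cell_id = cells$cell_id, profiles, check.names = FALSE),
      tmp, row.names = FALSE), file.path(out_dir, "profiles.csv"))
    .atomic_write(function(tmp) utils::write.csv(
      data.frame(cell_id = cells$cell_id, coords, group = groups),
      tmp, row.names = FALSE), file.path(out_dir, "embedding.csv"))
    .atomic_write(function(tmp) utils::write.csv(field$field, tmp,
                                                 row.names = FALSE),
                  file.path(out_dir, "log_ratio_field.csv"))
    report <- lapply(clusters, function(cs) if (is.null(cs)) NULL else
      list(k = cs$k, db_value = cs$db_value, db_by_k = as.list(cs$db_by_k),
           sizes = as.list(stats::setNames(cs$sizes, cs$cluster_names)),
           prevalence = as.list(cs$prevalence),
           mean_profiles = lapply(cs$mean_profiles, function(m)
             list(mean = as.list(m$mean), sem = as.list(m$sem), n = m$n))))
    .write_json(report, file.path(out_dir, "clusters.json"))
    surv_report <- list(ratios = ratios)
    for (rcol in c("nos2s_cd8", "cox2_cd8"))
      if (!is.null(surv[[rcol]]))
        surv_report[[rcol]] <- list(hr = surv[[rcol]]$hr,
                                    ci = surv[[rcol]]$ci,
                                    chisq = surv[[rcol]]$chisq,
                                    p = surv[[rcol]]$p)
    .write_json(surv_report, file.path(out_dir, "survival.json"))
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  result
}
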