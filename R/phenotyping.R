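# Marker quantization and 8-way CD8/NOS2/COX2 phenotype assignment.

.LEVELS <- c("negative", "weak", "moderate", "strong")
.MARKERS <- c("cd8", "nos2", "cox2")

#' Quantization rule for marker intensities
#'
#' A rule holds, per marker, the three intensity thresholds separating
#' negative / weak / moderate / strong levels, and the set of levels that
#' count as "positive" for that marker. Thresholds are lower-inclusive:
#' a value equal to `t_moderate` is called moderate.
#'
#' Default positivity reflects marker biology: NOS2 and COX2 are scored
#' positive at moderate-or-stronger signal, while CD8, a lineage marker,
#' is positive at any detectable (weak or stronger) signal. Positivity sets
#' must be upward-closed in the level order, which guarantees that raising
#' an intensity can never turn a positive cell negative.
#'
#' @param thresholds Named list; one entry per marker, each a numeric vector
#'   of length 3 `c(t_weak, t_moderate, t_strong)` with
#'   `0 <= t_weak <= t_moderate <= t_strong`.
#' @param positivity Named list; per marker, a character subset of
#'   `c("weak", "moderate", "strong")`, upward-closed. Defaults: CD8 any
#'   signal; NOS2 and COX2 moderate-or-above.
#' @return An object of class `quantization_rule`.
#' @examples
#' rule <- quantization_rule(list(cd8 = c(1, 2, 3), nos2 = c(1, 2, 3),
#'                                cox2 = c(1, 2, 3)))
#' quantize_intensity(2.5, rule, "nos2")
#' @export
quantization_rule <- function(thresholds, positivity = NULL) {
  stopifnot(is.list(thresholds), length(thresholds) >= 1)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("'thresholds' must be a named list (one entry per marker)")
  names(thresholds) <- tolower(names(thresholds))
  for (m in names(thresholds)) {
    t <- thresholds[[m]]
    if (!is.numeric(t) || length(t) != 3L || anyNA(t))
      stop("thresholds for marker '", m, "' must be 3 finite numbers")
    if (t[1] < 0 || is.unsorted(t))
      stop("thresholds for marker '", m,
           "' must satisfy 0 <= t_weak <= t_moderate <= t_strong")
    thresholds[[m]] <- stats::setNames(as.numeric(t),
                                       c("weak", "moderate", "strong"))
  }
  default_pos <- list(cd8 = c("weak", "moderate", "strong"),
                      nos2 = c("moderate", "strong"),
                      cox2 = c("moderate", "strong"))
  if (is.null(positivity)) positivity <- list()
  names(positivity) <- tolower(names(positivity))
  for (m in names(thresholds)) {
    if (is.null(positivity[[m]]))
      positivity[[m]] <- if (!is.null(default_pos[[m]])) default_pos[[m]]
                         else c("moderate", "strong")
    p <- match.arg(positivity[[m]], .LEVELS[-1], several.ok = TRUE)
    # upward closure: if a level is positive, all higher levels are too
    idx <- match(p, .LEVELS)
    if (!setequal(idx, seq(min(idx), 4L)))
      stop("positivity for marker '", m,
           "' must be upward-closed in the level order")
    positivity[[m]] <- .LEVELS[sort(idx)]
  }
  structure(list(thresholds = thresholds,
                 positivity = positivity[names(thresholds)]),
            class = "quantization_rule")
}

#' @export
print.quantization_rule <- function(x, ...) {
  cat("Quantization rule for markers:", paste(names(x$thresholds),
                                              collapse = ", "), "\n")
  for (m in names(x$thresholds)) {
    cat(sprintf("  %-5s thresholds (w/m/s): %s   positive: %s\n", m,
                paste(signif(x$thresholds[[m]], 4), collapse = "/"),
                paste(x$positivity[[m]], collapse = "+")))
  }
  invisible(x)
}

#' Derive a quantization rule from cohort intensity quantiles
#'
#' Numeric level thresholds are rarely published for visually scored
#' intensities, so the reproducible default places them at fixed quantiles
#' of the pooled per-cell intensity distribution of each marker.
#'
#' @param cells Cell table with one intensity column per marker.
#' @param markers Marker column names to derive thresholds for.
#' @param probs Quantile probabilities for the weak/moderate/strong cuts.
#' @param positivity Passed to [quantization_rule()].
#' @return A `quantization_rule`.
#' @export
derive_rule <- function(cells, markers = .MARKERS,
                        probs = c(0.5, 0.75, 0.9), positivity = NULL) {
  stopifnot(is.data.frame(cells), length(probs) == 3L, !is.unsorted(probs))
  missing <- setdiff(markers, names(cells))
  if (length(missing))
    stop("cell table lacks marker columns: ", paste(missing, collapse = ", "))
  thr <- lapply(markers, function(m)
    unname(stats::quantile(cells[[m]], probs = probs, na.rm = TRUE)))
  names(thr) <- markers
  quantization_rule(thr, positivity = positivity)
}

#' Canonical unit-spaced rule
#'
#' Thresholds 1/2/3 for every marker; the synthetic generator draws level
#' means at 0.5, 1.5, 2.5 and 3.5 so that this rule inverts the simulation
#' exactly at zero noise.
#'
#' @param markers Marker names.
#' @param positivity Passed to [quantization_rule()].
#' @return A `quantization_rule`.
#' @export
canonical_rule <- function(markers = .MARKERS, positivity = NULL) {
  thr <- stats::setNames(rep(list(c(1, 2, 3)), length(markers)), markers)
  quantization_rule(thr, positivity = positivity)
}

#' Quantize intensities into negative/weak/moderate/strong levels
#'
#' Boundaries are lower-inclusive: `level = negative` if `value < t_weak`,
#' `weak` if `t_weak <= value < t_moderate`, `moderate` if
#' `t_moderate <= value < t_strong`, else `strong`.
#'
#' @param value Numeric vector of non-negative intensities.
#' @param rule A [quantization_rule()].
#' @param marker Marker name (must be present in the rule).
#' @param cell_id Optional ids used in error messages for NA intensities.
#' @return Factor with levels negative/weak/moderate/strong.
#' @export
quantize_intensity <- function(value, rule, marker, cell_id = NULL) {
  stopifnot(inherits(rule, "quantization_rule"))
  marker <- tolower(marker)
  t <- rule$thresholds[[marker]]
  if (is.null(t)) stop("rule has no thresholds for marker '", marker, "'")
  bad <- !is.finite(value)
  if (any(bad)) {
    ids <- if (!is.null(cell_id)) cell_id[bad] else which(bad)
    stop("non-finite ", marker, " intensity for cell(s): ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  lev <- findInterval(value, t) + 1L   # lower-inclusive cuts
  factor(.LEVELS[lev], levels = .LEVELS)
}

#' Map marker levels to an 8-way phenotype code
#'
#' Codes 0-7 encode positivity as `code = 4*CD8 + 2*NOS2 + COX2`, e.g.
#' code 7 is CD8+NOS2+COX2+ and code 0 triple-negative. Positivity per
#' marker follows the rule's positivity sets.
#'
#' @param cd8_level,nos2_level,cox2_level Level vectors (outputs of
#'   [quantize_intensity()], or character).
#' @param rule A [quantization_rule()].
#' @return Integer vector of codes in 0..7.
#' @export
assign_phenotype <- function(cd8_level, nos2_level, cox2_level, rule) {
  stopifnot(inherits(rule, "quantization_rule"))
  pos <- function(lev, m) as.character(lev) %in% rule$positivity[[m]]
  4L * pos(cd8_level, "cd8") + 2L * pos(nos2_level, "nos2") +
    pos(cox2_level, "cox2")
}

#' Human-readable phenotype label for a code
#'
#' @param code Integer vector in 0..7.
#' @return Character labels such as `"CD8-NOS2+COX2+"`.
#' @export
phenotype_label <- function(code) {
  stopifnot(all(code %in% 0:7))
  sgn <- function(bit) ifelse(bit, "+", "-")
  paste0("CD8", sgn(bitwAnd(code, 4L) > 0),
         "NOS2", sgn(bitwAnd(code, 2L) > 0),
         "COX2", sgn(bitwAnd(code, 1L) > 0))
}

#' Quantize and phenotype a cell table
#'
#' Appends `level_<marker>` columns and an integer `phenotype` column
#' (0..7). The NOS2 level is retained even for NOS2-negative cells so that
#' strong-NOS2 ("NOS2s") analyses remain possible downstream.
#'
#' @param cells Cell table with intensity columns named as in the rule.
#' @param rule A [quantization_rule()]; default [canonical_rule()].
#' @return The cell table with level and phenotype columns appended.
#' @export
phenotype_cells <- function(cells, rule = canonical_rule()) {
  stopifnot(is.data.frame(cells))
  need <- c("cd8", "nos2", "cox2")
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop("cell table lacks intensity columns: ",
         paste(missing, collapse = ", "))
  ids <- if ("cell_id" %in% names(cells)) cells$cell_id else NULL
  for (m in need)
    cells[[paste0("level_", m)]] <- quantize_intensity(cells[[m]], rule, m,
                                                       cell_id = ids)
  cells$phenotype <- assign_phenotype(cells$level_cd8, cells$level_nos2,
                                      cells$level_cox2, rule)
  cells
}

#' Per-phenotype counts and percentages for a sample
#'
#' @param cells Phenotyped cell table (integer `phenotype` column), or an
#'   integer vector of codes.
#' @return Data frame with one row per code 0..7: `phenotype`, `label`,
#'   `count`, `percent`. Percentages sum to 100 (all-zero with a warning
#'   for an empty sample).
#' @export
phenotype_counts <- function(cells) {
  code <- if (is.data.frame(cells)) cells$phenotype else cells
  if (is.data.frame(cells) && is.null(code))
    stop("cell table has no 'phenotype' column; run phenotype_cells() first")
  stopifnot(all(code %in% 0:7))
  cnt <- tabulate(code + 1L, nbins = 8L)
  n <- sum(cnt)
  if (n == 0L) {
    warning("empty sample: all phenotype counts are zero")
    pct <- rep(0, 8L)
  } else pct <- 100 * cnt / n
  data.frame(phenotype = 0:7, label = phenotype_label(0:7),
             count = cnt, percent = pct)
}
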