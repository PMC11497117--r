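# Marker/CD8 ratio construction, median dichotomization, Kaplan-Meier
# estimation, log-rank (Mantel-Cox) testing and Mantel-Haenszel hazard
# ratios, including the expression-ratio application for public
# expression/survival series.
#
# KM and the pooled O/E/V tabulation are delegated to the survival package
# (survfit/survdiff); the Mantel-Haenszel hazard ratio
# HR = (O_high/E_high) / (O_low/E_low) with se(log HR) = 1/sqrt(V) is
# assembled here from that output.

.check_records <- function(records, what = "records") {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop(what, ": negative survival times")
  if (!all(records$event %in% c(0, 1)))
    stop(what, ": event must be 0 (censored) or 1")
  invisible(records)
}

#' Marker/CD8 ratio for one sample
#'
#' Ratio of marker-positive to CD8+ cell counts in a phenotyped cell
#' table. `"nos2s"` counts only strong-level NOS2 cells (the strong-signal
#' compartment); `"cox2"` counts COX2+ cells per the quantization rule's
#' positivity.
#'
#' @param cells Phenotyped cell table (output of [phenotype_cells()]).
#' @param numerator `"nos2s"` or `"cox2"`.
#' @param rule The [quantization_rule()] used for phenotyping (for
#'   positivity sets).
#' @param pseudocount Added to the CD8+ count; default 0, in which case a
#'   zero CD8+ count is an error.
#' @return The dimensionless ratio.
#' @export
sample_ratio <- function(cells, numerator = c("nos2s", "cox2"),
                         rule = canonical_rule(), pseudocount = 0) {
  numerator <- match.arg(numerator)
  stopifnot(all(c("level_nos2", "level_cox2", "level_cd8") %in% names(cells)))
  num <- switch(numerator,
    nos2s = sum(cells$level_nos2 == "strong"),
    cox2 = sum(as.character(cells$level_cox2) %in% rule$positivity$cox2))
  den <- sum(as.character(cells$level_cd8) %in% rule$positivity$cd8) +
    pseudocount
  if (den <= 0)
    stop("no CD8+ cells in sample; set a positive 'pseudocount'")
  num / den
}

#' Dichotomize values at the median
#'
#' `low` for values at or below the median, `high` above; ties go to low.
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_median <- function(values) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  if (length(unique(values)) == 1L)
    stop("all values identical; no median split possible")
  med <- stats::median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimates via [survival::survfit()].
#'
#' @param records Data frame with `time`, `event` and optionally a
#'   `stratum` column.
#' @return Data frame with `stratum`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (step-function values at the event/censoring
#'   times).
#' @export
km_estimate <- function(records) {
  .check_records(records)
  if (is.null(records$stratum)) records$stratum <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ stratum, data = records)
  strata <- if (is.null(fit$strata)) {
    rep(unique(records$stratum), length(fit$time))
  } else {
    rep(sub("^stratum=", "", names(fit$strata)), fit$strata)
  }
  data.frame(stratum = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

# pooled log-rank tabulation for two strata: O, E per stratum and variance
.logrank_oe <- function(stratum_a, stratum_b) {
  .check_records(stratum_a, "stratum A")
  .check_records(stratum_b, "stratum B")
  if (sum(stratum_a$event) + sum(stratum_b$event) == 0L)
    stop("no events in either stratum")
  df <- rbind(data.frame(time = stratum_a$time, event = stratum_a$event,
                         g = "A"),
              data.frame(time = stratum_b$time, event = stratum_b$event,
                         g = "B"))
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  v <- if (is.matrix(fit$var)) fit$var[1, 1] else fit$var[1]
  list(obs = fit$obs, exp = fit$exp, var = v, chisq = fit$chisq)
}

#' Log-rank (Mantel-Cox) test between two strata
#'
#' @param stratum_a,stratum_b Data frames with `time` and `event`.
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_mantel_cox <- function(stratum_a, stratum_b) {
  oe <- .logrank_oe(stratum_a, stratum_b)
  list(chisq = oe$chisq,
       p = stats::pchisq(oe$chisq, df = 1, lower.tail = FALSE))
}

#' Mantel-Haenszel hazard ratio, high vs low
#'
#' `HR = (O_high/E_high) / (O_low/E_low)` from the pooled log-rank
#' observed/expected tabulation; `se(log HR) = 1/sqrt(V)` with `V` the
#' log-rank variance, giving `CI = exp(log HR +/- 1.96 se)`. HR > 1 means
#' the high stratum fares worse.
#'
#' @param stratum_high,stratum_low Data frames with `time` and `event`.
#' @return Object of class `hazard_ratio_result`: `hr`, `ci` (95%),
#'   `log_hr`, `se_log_hr`, `chisq`, `p`, `obs`, `exp`.
#' @export
hazard_ratio_mh <- function(stratum_high, stratum_low) {
  oe <- .logrank_oe(stratum_high, stratum_low)
  if (any(oe$exp <= 0)) stop("zero expected events in a stratum")
  hr <- (oe$obs[1] / oe$exp[1]) / (oe$obs[2] / oe$exp[2])
  se <- 1 / sqrt(oe$var)
  log_hr <- log(hr)
  structure(list(hr = unname(hr),
                 ci = exp(log_hr + c(-1, 1) * 1.96 * se),
                 log_hr = unname(log_hr), se_log_hr = se,
                 chisq = oe$chisq,
                 p = stats::pchisq(oe$chisq, df = 1, lower.tail = FALSE),
                 obs = unname(oe$obs), exp = unname(oe$exp)),
            class = "hazard_ratio_result")
}

#' @export
print.hazard_ratio_result <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel HR %.3f (95%% CI %.3f-%.3f), ", x$hr,
              x$ci[1], x$ci[2]))
  cat(sprintf("log-rank chi-square %.3f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Administrative censoring at a horizon
#'
#' Events after the horizon are converted to censorings at the horizon.
#'
#' @param records Data frame with `time`, `event`.
#' @param horizon_years Censoring horizon; `Inf` leaves records unchanged.
#' @return The truncated records.
#' @export
censor_at_horizon <- function(records, horizon_years = 5) {
  .check_records(records)
  stopifnot(horizon_years > 0)
  over <- records$time > horizon_years
  records$event[over] <- 0L
  records$time[over] <- horizon_years
  records
}

#' Expression-ratio survival analysis
#'
#' For each sample, forms NOS2/CD8A and COX2/CD8A expression ratios,
#' dichotomizes each at its median, censors administratively at the
#' horizon, and reports log-rank and Mantel-Haenszel HR (high vs low) per
#' ratio. Suitable for a locally available expression/survival series
#' (e.g. a downloaded GEO series matrix parsed with
#' [read_series_matrix()]).
#'
#' @param expression Numeric matrix, genes x samples (rownames = gene
#'   ids).
#' @param records Data frame with `sample_id`, `time`, `event`; sample ids
#'   must match expression columns.
#' @param genes Named character vector mapping `nos2`, `cox2`, `cd8a` to
#'   rownames of `expression`.
#' @param horizon_years Administrative censoring horizon (default 5).
#' @return Named list of two `hazard_ratio_result`s (`nos2_cd8a`,
#'   `cox2_cd8a`) plus the per-sample `ratios` data frame.
#' @export
geo_ratio_survival <- function(expression, records,
                               genes = c(nos2 = "NOS2", cox2 = "PTGS2",
                                         cd8a = "CD8A"),
                               horizon_years = 5) {
  expression <- as.matrix(expression)
  stopifnot(all(c("nos2", "cox2", "cd8a") %in% names(genes)))
  missing_genes <- setdiff(genes, rownames(expression))
  if (length(missing_genes))
    stop("genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  .check_records(records)
  missing_samples <- setdiff(records$sample_id, colnames(expression))
  if (length(missing_samples))
    stop("samples absent from expression matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  expr <- expression[, records$sample_id, drop = FALSE]
  if (any(expr[genes[["cd8a"]], ] <= 0))
    stop("non-positive CD8A expression; ratios undefined")
  ratios <- data.frame(
    sample_id = records$sample_id,
    nos2_cd8a = expr[genes[["nos2"]], ] / expr[genes[["cd8a"]], ],
    cox2_cd8a = expr[genes[["cox2"]], ] / expr[genes[["cd8a"]], ])
  records <- censor_at_horizon(records, horizon_years)
  analyse <- function(r) {
    stratum <- dichotomize_median(r)
    hazard_ratio_mh(records[stratum == "high", ],
                    records[stratum == "low", ])
  }
  list(nos2_cd8a = analyse(ratios$nos2_cd8a),
       cox2_cd8a = analyse(ratios$cox2_cd8a),
       ratios = ratios)
}
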