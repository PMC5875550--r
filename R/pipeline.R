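#' Pearson product-moment correlation with significance
#'
#' Sample Pearson r with a two-sided p-value from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("Pearson correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-case record: geometric metrics plus dosimetric statistics
#'
#' The full per-structure analysis: the observer contours are fused with
#' [staple()] into the reference standard; the six geometric metrics compare
#' the auto contour to that reference; mean doses to both give the
#' dosimetric accuracy; the observers' mean doses against the reference give
#' the interobserver variation and the outside-range flag.
#'
#' @param truth Optional known ground truth (synthetic cohorts); carried
#'   through for validation but the reference standard is always the STAPLE
#'   consensus, as in the clinical workflow.
#' @param raters A [rater_set()] of observer contours.
#' @param auto The evaluated [voxel_structure()].
#' @param dose A [dose_grid()].
#' @param case_id,organ_group Identifiers carried into the record.
#' @param staple_threshold Consensus probability threshold.
#' @return An object of class `case_record`: `case_id`, `organ_group`,
#'   `metrics` ([compute_metrics()] record), `dose` ([dosimetric_accuracy()]
#'   record), `iov` ([interobserver_variation()] record), `outside_iov`,
#'   `reference` (the STAPLE consensus structure), `staple` (fit summary).
#' @export
build_case_record <- function(truth = NULL, raters, auto, dose,
                              case_id = "case", organ_group = "organ",
                              staple_threshold = 0.5) {
  if (!inherits(raters, "rater_set")) raters <- rater_set(raters)
  fit <- staple(raters)
  reference <- staple_consensus(fit, threshold = staple_threshold,
                                label = paste0(case_id, "_STAPLE"))
  stop_if_empty(reference, "STAPLE consensus")
  metrics <- compute_metrics(auto, reference)
  acc <- dosimetric_accuracy(mean_dose(dose, auto), mean_dose(dose, reference))
  iov <- interobserver_variation(dose, raters, reference)
  structure(list(case_id = case_id, organ_group = organ_group,
                 metrics = metrics, dose = acc, iov = iov,
                 outside_iov = outside_iov(acc$accuracy_pct, iov),
                 reference = reference,
                 staple = list(sensitivity = fit$sensitivity,
                               specificity = fit$specificity,
                               iterations = fit$iterations,
                               converged = fit$converged),
                 truth = truth),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("case_record %s (%s): DSC %.3f, centroid %.2f mm, accuracy %+.2f%%, %s IOV\n",
              x$case_id, x$organ_group, x$metrics$dsc,
              x$metrics$centroid_sep_mm, x$dose$accuracy_pct,
              if (x$outside_iov) "OUTSIDE" else "within"))
  invisible(x)
}

#' Build case records for a whole cohort
#'
#' Runs [build_case_record()] for every case. A failing case is excluded
#' with a warning naming it and the reason, rather than aborting the study.
#'
#' @param cohort A [generate_cohort()] result.
#' @return List of `case_record` objects.
#' @export
cohort_case_records <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  records <- lapply(cohort$cases, function(cs) {
    tryCatch(
      build_case_record(truth = cs$truth, raters = cs$raters, auto = cs$auto,
                        dose = cs$dose, case_id = cs$case_id,
                        organ_group = cs$organ_group),
      error = function(e) {
        warning(sprintf("case %s excluded: %s", cs$case_id, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  })
  Filter(Negate(is.null), records)
}

#' Flatten case records to a data frame
#'
#' @param records List of `case_record` objects.
#' @return Data frame with one row per record: identifiers, the six metrics,
#'   mean doses, accuracy, IOV summaries and the outside-IOV flag.
#' @export
case_records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(case_id = r$case_id, organ_group = r$organ_group),
          as.data.frame(r$metrics),
          data.frame(mean_auto_cGy = r$dose$mean_auto_cGy,
                     mean_truth_cGy = r$dose$mean_truth_cGy,
                     accuracy_pct = r$dose$accuracy_pct,
                     iov_min_pct = r$iov$min_pct, iov_q1_pct = r$iov$q1_pct,
                     iov_median_pct = r$iov$median_pct,
                     iov_q3_pct = r$iov$q3_pct, iov_max_pct = r$iov$max_pct,
                     outside_iov = r$outside_iov))
  }))
}

metric_columns <- c("dsc", "ci", "centroid_sep_mm", "mean_dta_mm",
                    "max_dta_mm", "hd95_mm")

#' Pooled correlation table
#'
#' For each organ group with at least `min_n` records, the Pearson
#' correlation (with two-sided p) between the dosimetric accuracy and each of
#' the six geometric metrics, flagged for significance at p < 0.05 (no
#' multiple-testing correction; one test per metric, per group).
#'
#' @param records List of `case_record` objects.
#' @param min_n Minimum records per group; smaller groups are skipped with a
#'   warning.
#' @return Data frame: `organ_group`, `metric`, `r`, `p`, `n`, `significant`.
#' @export
correlate_study <- function(records, min_n = 3L) {
  tab <- case_records_table(records)
  out <- list()
  for (grp in unique(tab$organ_group)) {
    sub <- tab[tab$organ_group == grp, ]
    if (nrow(sub) < min_n) {
      warning(sprintf("organ group '%s' has %d records (< %d); skipped",
                      grp, nrow(sub), min_n), call. = FALSE)
      next
    }
    for (m in metric_columns) {
      ct <- pearson(sub[[m]], sub$accuracy_pct)
      out[[length(out) + 1]] <- data.frame(organ_group = grp, metric = m,
                                           r = ct$r, p = ct$p, n = ct$n,
                                           significant = ct$p < 0.05)
    }
  }
  do.call(rbind, out)
}

#' Count cases whose auto-contour dose falls outside the observer range
#'
#' @param records List of `case_record` objects.
#' @return Data frame: `organ_group`, `k_outside`, `n_total`.
#' @export
count_outside_iov <- function(records) {
  tab <- case_records_table(records)
  agg <- stats::aggregate(outside_iov ~ organ_group, data = tab,
                          FUN = function(v) c(sum(v), length(v)))
  data.frame(organ_group = agg$organ_group,
             k_outside = agg$outside_iov[, 1],
             n_total = agg$outside_iov[, 2])
}

#' Run the complete study on one or more cohorts
#'
#' Convenience wrapper: builds case records for each cohort, pools them, and
#' returns the per-case table, the correlation table, outside-IOV counts and
#' per-group summary statistics (mean +- sd of accuracy and DSC).
#'
#' @param cohorts A `cohort` or list of cohorts.
#' @return List with `records`, `case_table`, `correlations`, `outside_iov`,
#'   `group_summary`.
#' @export
run_study <- function(cohorts) {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  records <- unlist(lapply(cohorts, cohort_case_records), recursive = FALSE)
  tab <- case_records_table(records)
  summ <- do.call(rbind, lapply(split(tab, tab$organ_group), function(sub) {
    data.frame(organ_group = sub$organ_group[1], n = nrow(sub),
               mean_accuracy_pct = mean(sub$accuracy_pct),
               sd_accuracy_pct = stats::sd(sub$accuracy_pct),
               mean_dsc = mean(sub$dsc), sd_dsc = stats::sd(sub$dsc))
  }))
  rownames(summ) <- NULL
  list(records = records, case_table = tab,
       correlations = correlate_study(records),
       outside_iov = count_outside_iov(records),
       group_summary = summ)
}
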