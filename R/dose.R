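#' Dose grid
#'
#' A 3D scalar absorbed-dose field in cGy on its own physical grid (which may
#' differ from any structure grid), using the same voxel-center convention as
#' [grid_spec()].
#'
#' @param values Numeric 3D array (cGy, finite and non-negative) with
#'   dimensions `grid$dim`.
#' @param grid A [grid_spec()].
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- array(as.numeric(values), dim(values))
  if (is.null(dim(values)) || !all(dim(values) == grid$dim))
    stop("dose array dimensions must equal grid dim")
  if (any(!is.finite(values))) stop("dose values must be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, grid = grid), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid on %s: range %.0f-%.0f cGy\n", format(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample a dose grid at points
#'
#' Trilinear interpolation of the 8 surrounding voxel-center dose values.
#' Points outside the voxel-center bounding box are an error naming the
#' offending point.
#'
#' @param d A [dose_grid()].
#' @param points_mm Numeric length-3 vector or n x 3 matrix of mm
#'   coordinates.
#' @return Dose in cGy (vector of length n).
#' @export
sample_dose <- function(d, points_mm) {
  stopifnot(inherits(d, "dose_grid"))
  if (is.null(dim(points_mm))) points_mm <- matrix(points_mm, ncol = 3)
  trilinear_sample(d$values, d$grid, points_mm, outside = "error")
}

#' Mean dose to a structure
#'
#' Arithmetic mean of the dose sampled (trilinearly) at every foreground
#' voxel center of the structure. The structure grid may differ from the dose
#' grid; dose is sampled at structure voxel centers rather than resampled,
#' avoiding double interpolation, as in DVH-style mean-dose estimation.
#'
#' @param d A [dose_grid()].
#' @param s A non-empty [voxel_structure()] fully inside the dose grid.
#' @return Mean dose in cGy.
#' @export
mean_dose <- function(d, s) {
  stopifnot(inherits(d, "dose_grid"), inherits(s, "voxel_structure"))
  stop_if_empty(s)
  idx <- which(s$mask, arr.ind = TRUE)
  pts <- voxel_centers(s$grid, idx)
  lo <- d$grid$origin - 1e-9
  hi <- d$grid$origin + (d$grid$dim - 1) * d$grid$spacing + 1e-9
  bad <- pts[, 1] < lo[1] | pts[, 1] > hi[1] |
         pts[, 2] < lo[2] | pts[, 2] > hi[2] |
         pts[, 3] < lo[3] | pts[, 3] > hi[3]
  if (any(bad)) {
    ext <- apply(pts[bad, , drop = FALSE], 2, range)
    stop(sprintf(paste0("structure '%s' extends outside the dose grid: offending voxel ",
                        "centers span x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f] mm"),
                 s$label, ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  }
  mean(trilinear_sample(d$values, d$grid, pts, outside = "error"))
}

#' Dosimetric accuracy of an evaluated contour
#'
#' Signed percentage difference between the mean dose to the evaluated
#' (automatically generated) contour and the mean dose to the ground-truth
#' contour, relative to the ground truth:
#' `100 * (mean_auto - mean_truth) / mean_truth`. Negative values mean the
#' evaluated contour reports a lower dose than the truth.
#'
#' @param mean_auto Mean dose to the evaluated contour (cGy).
#' @param mean_truth Mean dose to the ground-truth contour (cGy, > 0).
#' @return An object of class `dose_accuracy`: `mean_auto_cGy`,
#'   `mean_truth_cGy`, `accuracy_pct`.
#' @examples
#' dosimetric_accuracy(2470, 2600)$accuracy_pct  # -5
#' @export
dosimetric_accuracy <- function(mean_auto, mean_truth) {
  if (!is.finite(mean_truth) || mean_truth <= 0)
    stop("ground-truth mean dose must be positive")
  structure(list(mean_auto_cGy = as.numeric(mean_auto),
                 mean_truth_cGy = as.numeric(mean_truth),
                 accuracy_pct = 100 * (mean_auto - mean_truth) / mean_truth),
            class = "dose_accuracy")
}

#' @export
print.dose_accuracy <- function(x, ...) {
  cat(sprintf("dose_accuracy: auto %.1f cGy vs truth %.1f cGy -> %+.2f%%\n",
              x$mean_auto_cGy, x$mean_truth_cGy, x$accuracy_pct))
  invisible(x)
}

#' Dosimetric interobserver variation
#'
#' Signed percent difference in mean dose for each individual observer
#' contour relative to the fused (STAPLE) ground truth, with box-plot order
#' statistics: min, lower quartile, median, upper quartile, max. Quartiles
#' use linear interpolation between order statistics (R quantile type 7); the
#' whiskers of the corresponding box plot are the full min-max range.
#'
#' @param d A [dose_grid()].
#' @param raters A [rater_set()] of observer contours.
#' @param staple_mask The fused ground-truth [voxel_structure()].
#' @return An object of class `iov`: `per_rater_pct` (named), `min_pct`,
#'   `q1_pct`, `median_pct`, `q3_pct`, `max_pct`.
#' @export
interobserver_variation <- function(d, raters, staple_mask) {
  if (!inherits(raters, "rater_set")) raters <- rater_set(raters)
  truth <- mean_dose(d, staple_mask)
  per <- vapply(raters$raters, function(r) {
    dosimetric_accuracy(mean_dose(d, r), truth)$accuracy_pct
  }, numeric(1))
  names(per) <- raters$rater_ids
  qs <- unname(stats::quantile(per, c(0.25, 0.5, 0.75), type = 7))
  structure(list(per_rater_pct = per,
                 min_pct = min(per), q1_pct = qs[1], median_pct = qs[2],
                 q3_pct = qs[3], max_pct = max(per)),
            class = "iov")
}

#' @export
print.iov <- function(x, ...) {
  cat(sprintf("iov: min %+.2f%% | Q1 %+.2f%% | median %+.2f%% | Q3 %+.2f%% | max %+.2f%%\n",
              x$min_pct, x$q1_pct, x$median_pct, x$q3_pct, x$max_pct))
  invisible(x)
}

#' Is an accuracy outside the interobserver range?
#'
#' TRUE iff the evaluated contour's dosimetric accuracy falls strictly
#' outside the full min-max range of the observers (the box-plot whiskers).
#' A value exactly on a whisker counts as inside.
#'
#' @param auto_pct Dosimetric accuracy (%) of the evaluated contour.
#' @param iov An [interobserver_variation()] result.
#' @return Logical flag.
#' @export
outside_iov <- function(auto_pct, iov) {
  stopifnot(inherits(iov, "iov"))
  auto_pct < iov$min_pct || auto_pct > iov$max_pct
}
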