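#' Dice similarity coefficient
#'
#' Volume-overlap metric `DSC = 2|A n B| / (|A| + |B|)` computed from voxel
#' counts on a shared grid. Symmetric in its arguments; 1 for identical
#' non-empty masks, 0 for disjoint masks.
#'
#' @param a,b [voxel_structure()] objects; if their grids differ, `b` is
#'   resampled onto `a`'s grid by nearest neighbor.
#' @return Unitless value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  al <- align_structures(a, b); a <- al$a; b <- al$b
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na == 0 && nb == 0) stop("DSC undefined for two empty structures")
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Conformity index (volume ratio)
#'
#' The ratio of the two structures' volumes, `volume(auto) / volume(ref)`.
#' Values above 1 mean the evaluated structure is larger than the reference;
#' the orientation (auto over reference) is fixed so the sign of any volume
#' bias is interpretable.
#'
#' @param auto Evaluated [voxel_structure()] (may be empty, giving 0).
#' @param ref Reference [voxel_structure()]; must be non-empty.
#' @return Unitless positive ratio.
#' @export
conformity_index <- function(auto, ref) {
  stop_if_empty(ref, "reference structure")
  volume_mm3(auto) / volume_mm3(ref)
}

#' Centroid separation
#'
#' Euclidean distance (mm) between the centers of mass of two structures.
#'
#' @param auto,ref Non-empty [voxel_structure()] objects.
#' @return Distance in mm.
#' @export
centroid_separation <- function(auto, ref) {
  sqrt(sum((centroid_mm(auto) - centroid_mm(ref))^2))
}

#' Directed distance-to-agreement histogram
#'
#' For every point on the reference surface, the shortest Euclidean distance
#' to any point on the target surface (directed, reference to target). The
#' nearest-neighbor search is exact: each distance equals the all-pairs
#' minimum.
#'
#' @param ref_surface,target_surface Non-empty `surface_cloud` objects (see
#'   [extract_surface()]).
#' @return An object of class `dta_histogram`: list with `distances` (mm, one
#'   per reference point) and `direction_note`.
#' @export
dta_histogram <- function(ref_surface, target_surface) {
  stopifnot(inherits(ref_surface, "surface_cloud"),
            inherits(target_surface, "surface_cloud"))
  if (nrow(ref_surface$points) < 1 || nrow(target_surface$points) < 1)
    stop("DTA requires non-empty surface clouds")
  d <- cpp_min_dists(ref_surface$points, target_surface$points)
  structure(list(distances = as.numeric(d),
                 direction_note = sprintf("%s -> %s", ref_surface$source_label,
                                          target_surface$source_label)),
            class = "dta_histogram")
}

#' Symmetric distance-to-agreement distances
#'
#' Pooled directed distances in both directions (reference to target and
#' target to reference). Provided for completeness; the headline analysis
#' uses the directed histogram from the ground-truth surface.
#'
#' @inheritParams dta_histogram
#' @return A `dta_histogram` whose distances pool both directions.
#' @export
dta_histogram_symmetric <- function(ref_surface, target_surface) {
  h1 <- dta_histogram(ref_surface, target_surface)
  h2 <- dta_histogram(target_surface, ref_surface)
  structure(list(distances = c(h1$distances, h2$distances),
                 direction_note = "symmetric (both directions pooled)"),
            class = "dta_histogram")
}

#' Summarize a DTA histogram
#'
#' Mean and maximum distance-to-agreement, and the 95th percentile of the
#' cumulative DTA histogram (95%-Hausdorff distance). The percentile uses
#' linear interpolation between the closest order statistics (R quantile
#' type 7).
#'
#' @param h A [dta_histogram()].
#' @return Named list `mean_dta_mm`, `max_dta_mm`, `hd95_mm`.
#' @export
summarize_dta <- function(h) {
  stopifnot(inherits(h, "dta_histogram"))
  d <- h$distances
  if (length(d) == 0) stop("empty DTA histogram")
  list(mean_dta_mm = mean(d),
       max_dta_mm = max(d),
       hd95_mm = unname(stats::quantile(d, 0.95, type = 7)))
}

#' All six geometric comparison metrics for a structure pair
#'
#' Computes the Dice similarity coefficient, conformity index (auto volume
#' over reference volume), centroid separation, and the mean, maximum and
#' 95th-percentile distance-to-agreement. The DTA histogram is directed from
#' the reference (ground-truth) surface to the evaluated surface.
#'
#' @param auto Evaluated (e.g., automatically generated) [voxel_structure()].
#' @param ref Reference (ground-truth) [voxel_structure()]. Both must be
#'   non-empty; a differing grid on `auto` is resampled onto `ref`'s grid.
#' @return An object of class `metric_record`: named list with fields `dsc`,
#'   `ci`, `centroid_sep_mm`, `mean_dta_mm`, `max_dta_mm`, `hd95_mm` and a
#'   `direction` attribute recording the DTA orientation.
#' @examples
#' g <- grid_spec(c(0, 0, 0), c(1, 1, 1), c(20, 20, 20))
#' m <- array(FALSE, g$dim); m[5:14, 5:14, 5:14] <- TRUE
#' s <- voxel_structure(m, g)
#' unlist(compute_metrics(s, s)[1:6])  # identity: 1, 1, 0, 0, 0, 0
#' @export
compute_metrics <- function(auto, ref) {
  stop_if_empty(auto, "evaluated structure")
  stop_if_empty(ref, "reference structure")
  al <- align_structures(ref, auto); ref <- al$a; auto <- al$b
  h <- dta_histogram(extract_surface(ref), extract_surface(auto))
  sdta <- summarize_dta(h)
  rec <- list(dsc = dice(auto, ref),
              ci = conformity_index(auto, ref),
              centroid_sep_mm = centroid_separation(auto, ref),
              mean_dta_mm = sdta$mean_dta_mm,
              max_dta_mm = sdta$max_dta_mm,
              hd95_mm = sdta$hd95_mm)
  attr(rec, "direction") <- h$direction_note
  class(rec) <- "metric_record"
  rec
}

#' @export
print.metric_record <- function(x, ...) {
  cat(sprintf(paste0("metric_record: DSC %.3f | CI %.3f | centroid %.2f mm | ",
                     "meanDTA %.2f mm | maxDTA %.2f mm | 95%%-HD %.2f mm\n"),
              x$dsc, x$ci, x$centroid_sep_mm, x$mean_dta_mm, x$max_dta_mm,
              x$hd95_mm))
  invisible(x)
}

#' @export
as.data.frame.metric_record <- function(x, ...) {
  data.frame(dsc = x$dsc, ci = x$ci, centroid_sep_mm = x$centroid_sep_mm,
             mean_dta_mm = x$mean_dta_mm, max_dta_mm = x$max_dta_mm,
             hd95_mm = x$hd95_mm)
}

#' Batch metrics over a manifest of NIfTI mask pairs
#'
#' Reads a manifest data frame (columns `case_id`, `organ`, `path_auto`,
#' `path_ref`), computes [compute_metrics()] for each pair, and returns one
#' row per pair with the metric fields as columns.
#'
#' @param manifest Data frame or path to a CSV with the columns above.
#' @return Data frame: `case_id`, `organ`, then the six metric columns.
#' @export
batch_metrics <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("case_id", "organ", "path_auto", "path_ref")
  if (!all(needed %in% names(manifest)))
    stop("manifest needs columns: ", paste(needed, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    auto <- read_mask_nifti(manifest$path_auto[i], label = "auto")
    ref <- read_mask_nifti(manifest$path_ref[i], label = "reference")
    cbind(data.frame(case_id = manifest$case_id[i], organ = manifest$organ[i]),
          as.data.frame(compute_metrics(auto, ref)))
  })
  do.call(rbind, rows)
}
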