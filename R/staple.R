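#' Multi-observer rater set
#'
#' A set of two or more observer delineations of the same structure on one
#' shared grid, ready for STAPLE fusion.
#'
#' @param raters List of non-empty [voxel_structure()] objects on identical
#'   grids.
#' @param rater_ids Character labels, one per rater.
#' @return An object of class `rater_set`.
#' @export
rater_set <- function(raters, rater_ids = NULL) {
  if (length(raters) < 2) stop("a rater set needs at least 2 raters")
  for (r in raters) stopifnot(inherits(r, "voxel_structure"))
  g <- raters[[1]]$grid
  for (r in raters[-1]) {
    if (!grids_equal(g, r$grid)) stop("all raters must share one grid")
  }
  if (is.null(rater_ids)) rater_ids <- sprintf("rater%02d", seq_along(raters))
  stopifnot(length(rater_ids) == length(raters))
  structure(list(raters = raters, rater_ids = as.character(rater_ids), grid = g),
            class = "rater_set")
}

#' @export
print.rater_set <- function(x, ...) {
  cat(sprintf("rater_set: %d raters on %s\n", length(x$raters), format(x$grid)))
  invisible(x)
}

#' STAPLE fusion of multiple delineations
#'
#' Simultaneous truth and performance level estimation: an EM algorithm that
#' treats the unknown ground-truth label of each voxel as a latent variable
#' and each rater as a binary channel with sensitivity `p_j` and specificity
#' `q_j`.
#'
#' E-step: with decisions `d_ij` and prior foreground probability `g`,
#' `W_i = a_i / (a_i + b_i)` where
#' `a_i = g * prod_j p_j^d_ij (1 - p_j)^(1 - d_ij)` and
#' `b_i = (1 - g) * prod_j q_j^(1 - d_ij) (1 - q_j)^d_ij`.
#' M-step: `p_j = sum_i W_i d_ij / sum_i W_i`,
#' `q_j = sum_i (1 - W_i)(1 - d_ij) / sum_i (1 - W_i)`.
#' Iteration stops when the change in `sum_i W_i` falls below `tol` or after
#' `max_iter` iterations (the result is then flagged unconverged).
#'
#' Computation is restricted to a region of interest — the union of the rater
#' masks dilated by `roi_margin_mm` — because an unbounded background both
#' inflates specificity estimates and stalls the EM. Voxels outside the ROI
#' get probability 0.
#'
#' @param raters A [rater_set()] (or list of structures accepted by it).
#' @param tol Convergence tolerance on the change in the total foreground
#'   weight; default `1e-5` per ROI voxel.
#' @param max_iter Maximum EM iterations.
#' @param prior Scalar prior probability of foreground, or `"auto"` (the mean
#'   foreground fraction across raters within the ROI).
#' @param roi_margin_mm Dilation margin (mm) applied to the rater-mask union
#'   to form the ROI.
#' @return An object of class `staple_result`: `probability` (3D array in
#'   `[0, 1]`), `sensitivity` and `specificity` (per rater, named),
#'   `iterations`, `converged`, `roi` (logical array), `prior`, `grid`,
#'   `trace` (total weight per iteration).
#' @references Warfield, Zou and Wells, IEEE Trans Med Imaging 23(7), 2004.
#' @export
staple <- function(raters, tol = NULL, max_iter = 100L, prior = "auto",
                   roi_margin_mm = 10) {
  if (!inherits(raters, "rater_set")) raters <- rater_set(raters)
  grid <- raters$grid
  n_raters <- length(raters$raters)
  masks <- lapply(raters$raters, function(r) as.logical(r$mask))
  for (j in seq_len(n_raters)) {
    if (!any(masks[[j]]))
      stop(sprintf("rater '%s' is empty", raters$rater_ids[j]))
  }

  union_mask <- Reduce(`|`, masks)
  roi <- if (roi_margin_mm > 0) {
    d_out <- cpp_edt(as.vector(union_mask), grid$dim, grid$spacing)
    array(d_out <= roi_margin_mm + 1e-9, grid$dim)
  } else {
    array(union_mask, grid$dim)
  }
  n_roi <- sum(roi)
  if (is.null(tol)) tol <- 1e-5 * n_roi

  D <- vapply(masks, function(m) as.numeric(m[roi]), numeric(n_roi))
  for (j in seq_len(n_raters)) {
    if (all(D[, j] == 0) || all(D[, j] == 1))
      stop(sprintf("rater '%s' is degenerate within the ROI (all-foreground or all-background)",
                   raters$rater_ids[j]))
  }

  g <- if (identical(prior, "auto")) mean(D) else as.numeric(prior)
  if (!is.finite(g) || g <= 0 || g >= 1)
    stop("prior must lie strictly between 0 and 1")

  p <- rep(0.9999, n_raters)
  q <- rep(0.9999, n_raters)
  clamp <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)

  W <- NULL
  trace <- numeric(0)
  s_old <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step in log space to avoid underflow across raters
    la <- log(g) + D %*% log(clamp(p)) + (1 - D) %*% log(clamp(1 - p))
    lb <- log(1 - g) + (1 - D) %*% log(clamp(q)) + D %*% log(clamp(1 - q))
    W <- as.numeric(1 / (1 + exp(lb - la)))
    s_new <- sum(W)
    trace <- c(trace, s_new)
    # M-step
    sw <- sum(W); swc <- n_roi - sw
    p <- clamp(colSums(W * D) / sw)
    q <- clamp(colSums((1 - W) * (1 - D)) / swc)
    if (is.finite(s_old) && abs(s_new - s_old) < tol) {
      converged <- TRUE
      break
    }
    s_old <- s_new
  }

  probability <- array(0, grid$dim)
  probability[roi] <- W
  structure(list(probability = probability,
                 sensitivity = stats::setNames(p, raters$rater_ids),
                 specificity = stats::setNames(q, raters$rater_ids),
                 iterations = it,
                 converged = converged,
                 roi = roi,
                 prior = g,
                 grid = grid,
                 trace = trace),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("staple_result: %d raters, %d iterations (%s), prior %.3f\n",
              length(x$sensitivity), x$iterations,
              if (x$converged) "converged" else "NOT converged", x$prior))
  cat("  sensitivity:", paste(sprintf("%.3f", x$sensitivity), collapse = " "), "\n")
  cat("  specificity:", paste(sprintf("%.3f", x$specificity), collapse = " "), "\n")
  invisible(x)
}

#' Binary consensus from a STAPLE probability map
#'
#' Thresholds the ground-truth probability map; voxels exactly at the
#' threshold are included.
#'
#' @param r A [staple()] result.
#' @param threshold Probability threshold in `(0, 1)`.
#' @param label Label for the resulting structure.
#' @return A [voxel_structure()] (possibly empty; a message is emitted then).
#' @export
staple_consensus <- function(r, threshold = 0.5, label = "STAPLE") {
  stopifnot(inherits(r, "staple_result"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  mask <- r$probability >= threshold
  if (!any(mask)) message("STAPLE consensus is empty at threshold ", threshold)
  voxel_structure(mask, r$grid, label)
}
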