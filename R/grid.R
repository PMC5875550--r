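#' Physical grid specification
#'
#' Describes an axis-aligned 3D voxel grid in physical (mm) coordinates using
#' the voxel-center convention: the center of voxel `(i, j, k)` (1-based R
#' indices) lies at `origin + (c(i, j, k) - 1) * spacing`. All structure,
#' surface and dose computations in the package go through this single
#' convention, so no half-voxel offsets can accumulate between metrics and
#' dose sampling.
#'
#' @param origin Numeric length-3, world coordinate (mm) of the center of the
#'   first voxel.
#' @param spacing Numeric length-3, voxel size (mm) along x, y, z; all
#'   strictly positive.
#' @param dim Integer length-3, number of voxels along x, y, z; all positive.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(origin = c(0, 0, 0), spacing = c(2, 2, 2), dim = c(32, 32, 32))
#' @export
grid_spec <- function(origin, spacing, dim) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dim) == 3)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be strictly positive on all axes")
  if (any(is.na(dim)) || any(dim < 1L)) stop("grid dim must be positive integers")
  structure(list(origin = origin, spacing = spacing, dim = dim),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$dim[1], x$dim[2], x$dim[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' World coordinates of voxel centers
#'
#' @param grid A [grid_spec()].
#' @param idx Integer matrix (n x 3) of 1-based voxel indices; if `NULL`, all
#'   voxels in grid order (x fastest).
#' @return Numeric n x 3 matrix of mm coordinates.
#' @keywords internal
voxel_centers <- function(grid, idx = NULL) {
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(i = seq_len(grid$dim[1]),
                                 j = seq_len(grid$dim[2]),
                                 k = seq_len(grid$dim[3])))
  }
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# Continuous (fractional, 1-based) grid index of world points; rows of `pts`
# are mm coordinates.
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 1
}

# Axis coordinate vectors of voxel centers.
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 1) * grid$spacing[axis]
}

#' Trilinear interpolation of a gridded scalar field
#'
#' Samples a scalar array defined at voxel centers of `grid` at arbitrary
#' points, interpolating linearly between the 8 surrounding voxel centers.
#'
#' @param values Numeric 3D array with dimensions `grid$dim`.
#' @param grid A [grid_spec()].
#' @param points Numeric n x 3 matrix of mm coordinates.
#' @param outside One of `"error"` (points outside the voxel-center bounding
#'   box are an error) or `"fill"` (they evaluate to `fill`).
#' @param fill Value returned for outside points when `outside = "fill"`.
#' @return Numeric vector of length n.
#' @keywords internal
trilinear_sample <- function(values, grid, points,
                             outside = c("error", "fill"), fill = NA_real_) {
  outside <- match.arg(outside)
  points <- matrix(as.numeric(points), ncol = 3)
  ci <- world_to_index(grid, points)
  n <- nrow(points)
  lo <- matrix(1, n, 3)
  out_of_bounds <- rep(FALSE, n)
  for (a in 1:3) {
    out_of_bounds <- out_of_bounds | ci[, a] < 1 - 1e-9 | ci[, a] > grid$dim[a] + 1e-9
  }
  if (any(out_of_bounds)) {
    if (outside == "error") {
      p <- points[which(out_of_bounds)[1], ]
      stop(sprintf("point (%.3f, %.3f, %.3f) mm lies outside the grid bounding box",
                   p[1], p[2], p[3]))
    }
  }
  # clamp to the valid cell range so interpolation weights stay in [0, 1]
  frac <- matrix(0, n, 3)
  for (a in 1:3) {
    x <- pmin(pmax(ci[, a], 1), grid$dim[a])
    l <- pmin(floor(x), grid$dim[a] - 1)
    l <- pmax(l, 1)
    lo[, a] <- l
    frac[, a] <- x - l
  }
  if (any(grid$dim == 1L)) {
    for (a in which(grid$dim == 1L)) {
      lo[, a] <- 1
      frac[, a] <- 0
    }
  }
  d1 <- grid$dim[1]; d12 <- grid$dim[1] * grid$dim[2]
  flat <- function(i, j, k) (k - 1) * d12 + (j - 1) * d1 + i
  v <- as.numeric(values)
  acc <- numeric(n)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    i <- pmin(lo[, 1] + dx, grid$dim[1])
    j <- pmin(lo[, 2] + dy, grid$dim[2])
    k <- pmin(lo[, 3] + dz, grid$dim[3])
    w <- (if (dx) frac[, 1] else 1 - frac[, 1]) *
         (if (dy) frac[, 2] else 1 - frac[, 2]) *
         (if (dz) frac[, 3] else 1 - frac[, 3])
    acc <- acc + w * v[flat(i, j, k)]
  }
  if (outside == "fill" && any(out_of_bounds)) acc[out_of_bounds] <- fill
  acc
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
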