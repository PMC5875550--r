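#' Voxelized binary structure on a physical grid
#'
#' The universal structure representation: a logical 3D mask tied to a
#' [grid_spec()]. Foreground voxels are structure; everything else is
#' background.
#'
#' @param mask Logical 3D array with dimensions `grid$dim` (numeric arrays are
#'   coerced with `> 0.5`).
#' @param grid A [grid_spec()].
#' @param label Character label carried through metric and study outputs.
#' @return An object of class `voxel_structure`.
#' @export
voxel_structure <- function(mask, grid, label = "structure") {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.logical(mask)) stop("mask must be a logical array")
  if (!identical(dim(mask), NULL) && length(dim(mask)) != 3)
    stop("mask must be a 3D array")
  if (is.null(dim(mask)) || !all(dim(mask) == grid$dim))
    stop("mask dimensions must equal grid dim")
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, grid = grid, label = as.character(label)),
            class = "voxel_structure")
}

#' @export
print.voxel_structure <- function(x, ...) {
  cat(sprintf("voxel_structure '%s': %d foreground voxels (%.1f mm^3) on %s\n",
              x$label, sum(x$mask), volume_mm3(x), format(x$grid)))
  invisible(x)
}

is_empty_structure <- function(s) !any(s$mask)

stop_if_empty <- function(s, what = "structure") {
  if (is_empty_structure(s)) stop(sprintf("empty %s not allowed here", what))
  invisible(s)
}

#' Structure volume
#'
#' Foreground voxel count times the voxel volume. Zero for an empty mask.
#'
#' @param s A [voxel_structure()].
#' @return Volume in mm^3.
#' @examples
#' g <- grid_spec(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
#' s <- voxel_structure(array(TRUE, g$dim), g)
#' volume_mm3(s)  # 1000
#' @export
volume_mm3 <- function(s) {
  stopifnot(inherits(s, "voxel_structure"))
  sum(s$mask) * prod(s$grid$spacing)
}

#' Structure centroid (center of mass)
#'
#' Unweighted mean of the world coordinates of foreground voxel centers.
#'
#' @param s A non-empty [voxel_structure()].
#' @return Numeric length-3 mm coordinate.
#' @export
centroid_mm <- function(s) {
  stopifnot(inherits(s, "voxel_structure"))
  stop_if_empty(s)
  idx <- which(s$mask, arr.ind = TRUE)
  unname(colMeans(voxel_centers(s$grid, idx)))
}

#' Resample a structure onto another grid
#'
#' Nearest-neighbor resampling of mask values: each voxel of the target grid
#' takes the value of the nearest source voxel center (voxels whose center
#' falls outside the source grid are background). Used to bring two structures
#' onto a common lattice before voxel-based comparison.
#'
#' @param s A [voxel_structure()].
#' @param grid Target [grid_spec()].
#' @return A [voxel_structure()] on `grid`.
#' @export
resample_structure <- function(s, grid) {
  stopifnot(inherits(s, "voxel_structure"), inherits(grid, "grid_spec"))
  if (grids_equal(s$grid, grid)) return(voxel_structure(s$mask, grid, s$label))
  pts <- voxel_centers(grid)
  ci <- world_to_index(s$grid, pts)
  near <- round(ci)
  ok <- near[, 1] >= 1 & near[, 1] <= s$grid$dim[1] &
        near[, 2] >= 1 & near[, 2] <= s$grid$dim[2] &
        near[, 3] >= 1 & near[, 3] <= s$grid$dim[3]
  vals <- rep(FALSE, nrow(pts))
  d1 <- s$grid$dim[1]; d12 <- s$grid$dim[1] * s$grid$dim[2]
  flat <- (near[ok, 3] - 1) * d12 + (near[ok, 2] - 1) * d1 + near[ok, 1]
  vals[ok] <- as.logical(s$mask)[flat]
  voxel_structure(array(vals, grid$dim), grid, s$label)
}

# Shared-grid guard; resamples b onto a's grid when they differ.
align_structures <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) b <- resample_structure(b, a$grid)
  list(a = a, b = b)
}

#' Surface point cloud of a structure
#'
#' The structure surface is represented as the centers of exposed voxel faces:
#' for each foreground voxel, any of its 6 faces adjacent to background (or to
#' the grid edge) contributes one point, placed at the face center in mm. This
#' gives a deterministic, resolution-controlled surface approximation whose
#' error is bounded by half a voxel diagonal.
#'
#' @param s A non-empty [voxel_structure()].
#' @return An object of class `surface_cloud`: list with `points` (n x 3 mm
#'   matrix) and `source_label`.
#' @examples
#' g <- grid_spec(c(0, 0, 0), c(1, 1, 1), c(3, 3, 3))
#' m <- array(FALSE, g$dim); m[2, 2, 2] <- TRUE
#' nrow(extract_surface(voxel_structure(m, g))$points)  # 6 faces
#' @export
extract_surface <- function(s) {
  stopifnot(inherits(s, "voxel_structure"))
  if (is_empty_structure(s)) stop("empty structure has no surface")
  m <- s$mask
  d <- s$grid$dim
  sp <- s$grid$spacing
  pts <- vector("list", 6)
  n <- 0L
  # exposure along each axis and direction: foreground with background (or
  # grid edge) neighbor
  shift_bg <- function(axis, dir) {
    # TRUE where the neighbor at +dir along axis is background/outside
    nb <- array(TRUE, d)
    if (axis == 1) {
      if (dir > 0) nb[-d[1], , ] <- !m[-1, , ] else nb[-1, , ] <- !m[-d[1], , ]
    } else if (axis == 2) {
      if (dir > 0) nb[, -d[2], ] <- !m[, -1, ] else nb[, -1, ] <- !m[, -d[2], ]
    } else {
      if (dir > 0) nb[, , -d[3]] <- !m[, , -1] else nb[, , -1] <- !m[, , -d[3]]
    }
    nb
  }
  out <- list()
  for (axis in 1:3) for (dir in c(-1, 1)) {
    exposed <- m & shift_bg(axis, dir)
    if (!any(exposed)) next
    idx <- which(exposed, arr.ind = TRUE)
    p <- voxel_centers(s$grid, idx)
    p[, axis] <- p[, axis] + dir * sp[axis] / 2
    out[[length(out) + 1]] <- p
  }
  points <- do.call(rbind, out)
  dimnames(points) <- NULL
  structure(list(points = points, source_label = s$label),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("surface_cloud '%s': %d face-center points\n",
              x$source_label, nrow(x$points)))
  invisible(x)
}

#' Planar contour stack
#'
#' DICOM-RT-style planar contours: a list of axial planes, each holding one or
#' more closed polygons in mm. Polygons store each vertex once (the closing
#' edge back to the first vertex is implicit) and need at least 3 vertices.
#'
#' @param planes List of `list(z = <mm>, polygons = <list of n x 2 mm
#'   matrices>)`.
#' @param label Character label.
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(planes, label = "contour") {
  for (p in planes) {
    if (is.null(p$z) || !is.finite(p$z)) stop("each plane needs a finite z (mm)")
    for (poly in p$polygons) {
      poly <- as.matrix(poly)
      if (nrow(poly) < 3)
        stop(sprintf("degenerate polygon with %d vertices on plane z = %g mm",
                     nrow(poly), p$z))
    }
  }
  structure(list(planes = planes, label = as.character(label)),
            class = "contour_stack")
}

# Even-odd point-in-polygon test, vectorized over points. Points exactly on a
# polygon edge count as inside (deterministic tie-break).
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
      on_edge <- on_edge | (crosses & abs(px - xint) < eps)
    }
    # on-segment test (covers horizontal edges the crossing rule skips)
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      tc <- pmin(pmax(t, 0), 1)
      ddx <- px - (x1 + tc * dx); ddy <- py - (y1 + tc * dy)
      on_edge <- on_edge | (ddx * ddx + ddy * ddy) < eps * eps
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize planar contours onto a grid
#'
#' Each contour plane is assigned to the nearest grid slice (its z must fall
#' within half a slice spacing of that slice, else an error names the plane).
#' A voxel on that slice is foreground iff its center lies inside an odd
#' number of the plane's polygons (even-odd rule, so nested polygons cut
#' holes); centers exactly on an edge count as inside. Slices without a
#' contour plane are background.
#'
#' @param contours A [contour_stack()].
#' @param grid A [grid_spec()].
#' @return A [voxel_structure()].
#' @export
rasterize <- function(contours, grid) {
  stopifnot(inherits(contours, "contour_stack"), inherits(grid, "grid_spec"))
  mask <- array(FALSE, grid$dim)
  zc <- axis_coords(grid, 3)
  xc <- axis_coords(grid, 1)
  yc <- axis_coords(grid, 2)
  cell <- expand.grid(x = xc, y = yc)
  for (p in contours$planes) {
    k <- which.min(abs(zc - p$z))
    if (abs(zc[k] - p$z) > grid$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour plane z = %g mm lies outside the grid extent", p$z))
    inside <- rep(FALSE, nrow(cell))
    for (poly in p$polygons) {
      poly <- as.matrix(poly)
      inside <- xor(inside, points_in_polygon(cell$x, cell$y, poly))
    }
    slice <- matrix(inside, grid$dim[1], grid$dim[2])
    mask[, , k] <- mask[, , k] | slice
  }
  voxel_structure(mask, grid, contours$label)
}
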