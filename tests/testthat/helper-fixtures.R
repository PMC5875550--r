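# Small programmatic fixtures shared across test files.

unit_grid <- function(n = 20, spacing = 1, origin = 0) {
  grid_spec(rep(origin, 3), rep(spacing, 3), rep(n, 3))
}

# axis-aligned solid box given inclusive index ranges
box_structure <- function(grid, ir, jr, kr, label = "box") {
  m <- array(FALSE, grid$dim)
  m[ir[1]:ir[2], jr[1]:jr[2], kr[1]:kr[2]] <- TRUE
  voxel_structure(m, grid, label)
}

# random blob: union of a few random balls, guaranteed non-empty
random_blob <- function(grid, n_balls = 3, label = "blob") {
  pts <- voxel_centers(grid)
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1) * grid$spacing
  m <- rep(FALSE, nrow(pts))
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
    rad <- runif(1, 0.1, 0.3) * min(hi - lo)
    m <- m | (rowSums(sweep(pts, 2, ctr)^2) <= rad^2)
  }
  if (!any(m)) m[sample(length(m), 5)] <- TRUE
  voxel_structure(array(m, grid$dim), grid, label)
}

# Bernoulli observer: truth voxels kept with prob `sens`, background voxels
# flipped on with prob `1 - spec` (the STAPLE generative model)
bernoulli_rater <- function(truth, sens, spec, label = "rater") {
  n <- length(truth$mask)
  m <- ifelse(as.vector(truth$mask), runif(n) < sens, runif(n) >= spec)
  voxel_structure(array(m, truth$grid$dim), truth$grid, label)
}

ellipsoid_structure <- function(grid, semi_axes, center = c(0, 0, 0),
                                label = "ellipsoid") {
  make_organ(organ_spec("ellipsoid", semi_axes, center, bumpiness = 0), grid)
}
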