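#' Synthetic cohort generation
#'
#' Generators for the study inputs: smooth organ-like structures, observer
#' and auto-contour perturbations with controlled error modes, and dose
#' fields reproducing two clinical gradient regimes — a steep unidirectional
#' gradient across the organ (parotid-like) and opposing gradients with a
#' central trough (larynx-like). Every generator is a pure function of its
#' spec plus seed.
#'
#' @name synthetic_cohort
NULL

# --- smooth angular noise fields -------------------------------------------

# Real spherical-harmonic-style basis (unnormalized) up to degree 3,
# evaluated at unit direction vectors; 15 columns. Normalization constants
# are irrelevant because fields built on it are rescaled empirically.
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x, y, z,                                     # l = 1
        x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1, # l = 2
        z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
        z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2), y * (3 * x^2 - y^2))
}

# Quasi-uniform unit directions (Fibonacci sphere), used to normalize the
# angular field to unit standard deviation over the sphere.
fibonacci_sphere <- function(n = 500) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Seeded smooth field on the sphere with (empirical) zero mean; coefficients
# decay as 1/l so the field stays low-order smooth. `normalize = "sd"` scales
# to unit standard deviation over the sphere (boundary noise, where sigma in
# mm is the contract); `"peak"` scales to unit maximum absolute value (organ
# bumps, where bumpiness reads as the largest relative bump).
sh_noise_field <- function(seed, normalize = c("sd", "peak")) {
  normalize <- match.arg(normalize)
  coefs <- with_seed(seed, stats::rnorm(15)) * rep(c(1, 1 / 2, 1 / 3), c(3, 5, 7))
  ref <- sh_basis(fibonacci_sphere(500)) %*% coefs
  ctr <- mean(ref)
  scale <- if (normalize == "sd") stats::sd(ref) else max(abs(ref - ctr))
  list(coefs = coefs, center = ctr, scale = scale)
}

eval_sh_field <- function(field, u) {
  as.numeric((sh_basis(u) %*% field$coefs - field$center) / field$scale)
}

# Unit directions of points relative to a center; degenerate zero-length
# vectors map to +x (their field value is irrelevant at the organ center).
unit_directions <- function(pts, center) {
  rel <- sweep(pts, 2, center)
  r <- sqrt(rowSums(rel^2))
  r0 <- r < 1e-12
  rel[r0, ] <- matrix(rep(c(1, 0, 0), sum(r0)), ncol = 3, byrow = TRUE)
  r[r0] <- 1
  list(u = rel / r, r = sqrt(rowSums(sweep(pts, 2, center)^2)))
}

# --- organ generation -------------------------------------------------------

#' Organ specification
#'
#' @param shape One of `"ellipsoid"`, `"superellipsoid"` (exponent-4, boxier)
#'   or `"lobed_blob"` (ellipsoid with three fixed azimuthal lobes).
#' @param semi_axes_mm Positive length-3 semi-axes (mm).
#' @param center_mm Organ center (mm).
#' @param bumpiness Relative amplitude (sd) of seeded smooth radial bumps;
#'   0 disables them.
#' @param seed Integer seed controlling the bumps; the same spec and seed
#'   give a bit-identical mask.
#' @return An object of class `organ_spec`.
#' @export
organ_spec <- function(shape = c("ellipsoid", "superellipsoid", "lobed_blob"),
                       semi_axes_mm, center_mm, bumpiness = 0, seed = 1L) {
  shape <- match.arg(shape)
  semi_axes_mm <- as.numeric(semi_axes_mm)
  stopifnot(length(semi_axes_mm) == 3, all(semi_axes_mm > 0),
            length(center_mm) == 3, bumpiness >= 0)
  structure(list(shape = shape, semi_axes_mm = semi_axes_mm,
                 center_mm = as.numeric(center_mm),
                 bumpiness = bumpiness, seed = as.integer(seed)),
            class = "organ_spec")
}

# Directional radius of the base shape (distance from center to surface
# along unit direction u).
base_radius <- function(spec, u) {
  a <- spec$semi_axes_mm
  if (spec$shape == "ellipsoid") {
    1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2)
  } else if (spec$shape == "superellipsoid") {
    ((abs(u[, 1]) / a[1])^4 + (abs(u[, 2]) / a[2])^4 +
       (abs(u[, 3]) / a[3])^4)^(-1 / 4)
  } else { # lobed_blob: three smooth azimuthal lobes, strongest at the equator
    rho <- 1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 + (u[, 3] / a[3])^2)
    phi <- atan2(u[, 2], u[, 1])
    rho * (1 + 0.15 * sin(3 * phi) * (1 - u[, 3]^2))
  }
}

#' Generate an organ-like structure
#'
#' Builds the implicit-surface mask: a voxel center at distance `r` along
#' direction `u` from the organ center is foreground iff
#' `r <= rho(u) * (1 + bumpiness * h(u))`, where `rho` is the base shape's
#' directional radius and `h` a seeded smooth angular field normalized to a
#' peak of 1, so `bumpiness` is the largest relative bump amplitude.
#'
#' @param spec An [organ_spec()].
#' @param grid A [grid_spec()]; the organ must fit strictly inside it.
#' @return A [voxel_structure()].
#' @export
make_organ <- function(spec, grid) {
  stopifnot(inherits(spec, "organ_spec"), inherits(grid, "grid_spec"))
  pts <- voxel_centers(grid)
  ud <- unit_directions(pts, spec$center_mm)
  radius <- base_radius(spec, ud$u)
  if (spec$bumpiness > 0) {
    h <- eval_sh_field(sh_noise_field(spec$seed, normalize = "peak"), ud$u)
    radius <- radius * pmax(1 + spec$bumpiness * h, 0.05)
  }
  mask <- array(ud$r <= radius, grid$dim)
  if (!any(mask)) stop("organ spec produced an empty mask on this grid")
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx == 1) || any(sweep(idx, 2, grid$dim) == 0))
    stop("organ exceeds the grid (foreground touches the grid boundary)")
  voxel_structure(mask, grid, "organ")
}

# --- perturbation -----------------------------------------------------------

#' Contour error model
#'
#' Describes a perturbation applied to a structure: smooth radial boundary
#' noise, a signed uniform dilation (negative = erosion), then a rigid shift.
#' The zero model reproduces the input exactly; a fixed seed makes the noise
#' reproducible.
#'
#' @param shift_mm Rigid translation (mm, length 3).
#' @param dilation_mm Signed uniform margin (mm); positive grows the
#'   structure.
#' @param boundary_noise_mm Standard deviation (mm) of the smooth radial
#'   boundary perturbation.
#' @param seed Integer seed for the noise field.
#' @return An object of class `error_model`.
#' @export
error_model <- function(shift_mm = c(0, 0, 0), dilation_mm = 0,
                        boundary_noise_mm = 0, seed = 1L) {
  stopifnot(length(shift_mm) == 3, boundary_noise_mm >= 0)
  structure(list(shift_mm = as.numeric(shift_mm),
                 dilation_mm = as.numeric(dilation_mm),
                 boundary_noise_mm = as.numeric(boundary_noise_mm),
                 seed = as.integer(seed)),
            class = "error_model")
}

# Signed distance (mm) from voxel centers to the mask boundary: negative
# inside, positive outside, zero level on the voxel faces. Built from two
# exact voxel-center distance transforms with a half-voxel boundary
# correction (exact for flat axis-aligned boundaries, approximate otherwise).
signed_distance <- function(s) {
  h <- mean(s$grid$spacing) / 2
  a <- cpp_edt(as.vector(s$mask), s$grid$dim, s$grid$spacing)   # dist to foreground
  b <- cpp_edt(as.vector(!s$mask), s$grid$dim, s$grid$spacing)  # dist to background
  d <- ifelse(as.vector(s$mask), -(b - h), a - h)
  array(d, s$grid$dim)
}

#' Perturb a structure with a controlled error model
#'
#' Applies, in order: smooth radial boundary noise (a seeded angular field of
#' sd `boundary_noise_mm` added to the structure's signed distance level),
#' signed uniform dilation/erosion by `dilation_mm`, and a rigid shift by
#' `shift_mm`. Implemented on the structure's signed distance field with
#' trilinear resampling, so sub-voxel shifts and margins behave correctly.
#'
#' @param s A non-empty [voxel_structure()].
#' @param e An [error_model()].
#' @return A perturbed [voxel_structure()] on the same grid.
#' @export
perturb <- function(s, e) {
  stopifnot(inherits(s, "voxel_structure"), inherits(e, "error_model"))
  stop_if_empty(s)
  if (all(e$shift_mm == 0) && e$dilation_mm == 0 && e$boundary_noise_mm == 0)
    return(voxel_structure(s$mask, s$grid, s$label))
  sdf <- signed_distance(s)
  pts <- voxel_centers(s$grid)
  src <- sweep(pts, 2, e$shift_mm)  # pull-back: output voxel x samples x - shift
  far <- max(s$grid$spacing) * max(s$grid$dim)
  d <- trilinear_sample(sdf, s$grid, src, outside = "fill", fill = far)
  level <- e$dilation_mm
  if (e$boundary_noise_mm > 0) {
    ctr <- centroid_mm(s)
    ud <- unit_directions(src, ctr)
    noise <- eval_sh_field(sh_noise_field(e$seed), ud$u) * e$boundary_noise_mm
    level <- level + noise
  }
  mask <- array(d <= level, s$grid$dim)
  if (!any(mask)) stop("perturbation (erosion/noise) emptied the structure")
  voxel_structure(mask, s$grid, s$label)
}

#' Simulate observer contours
#'
#' `n` independently perturbed copies of the truth with smooth boundary noise
#' of sd `noise_mm` and no systematic shift or dilation; per-rater seeds are
#' derived deterministically from the master seed.
#'
#' @param truth Ground-truth [voxel_structure()].
#' @param n Number of observers (>= 2).
#' @param noise_mm Boundary-noise sd per observer (mm).
#' @param seed Master seed.
#' @return A [rater_set()].
#' @export
simulate_raters <- function(truth, n = 5L, noise_mm = 1.5, seed = 1L) {
  if (n < 2) stop("need at least 2 raters")
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  raters <- lapply(seq_len(n), function(j) {
    r <- perturb(truth, error_model(boundary_noise_mm = noise_mm, seed = sub[j]))
    r$label <- sprintf("rater%02d", j)
    r
  })
  rater_set(raters)
}

# --- dose fields ------------------------------------------------------------

#' Dose field specification
#'
#' @param regime `"unidirectional"` — a single sigmoid ramp from `d_low_cGy`
#'   to `d_high_cGy` along `direction` (the direction of increasing dose); or
#'   `"opposing"` — two ramps rising away from the center along the rows of
#'   `direction`, forming a central trough, rescaled to span
#'   `[d_low_cGy, d_high_cGy]` over the grid.
#' @param d_high_cGy,d_low_cGy Plateau dose levels (cGy), `d_high > d_low >=
#'   0`.
#' @param gradient_width_mm Width of the sigmoid transition (central 12-88%
#'   span); must be positive.
#' @param direction Unit 3-vector (unidirectional) or 2 x 3 matrix of unit
#'   vectors (opposing).
#' @param center_mm Ramp/trough center (mm); `NULL` means the grid center.
#' @param trough_halfwidth_mm Opposing regime only: distance from the center
#'   to each ramp's midpoint (mm).
#' @return An object of class `dose_field_spec`.
#' @export
dose_field_spec <- function(regime = c("unidirectional", "opposing"),
                            d_high_cGy, d_low_cGy, gradient_width_mm,
                            direction = c(1, 0, 0), center_mm = NULL,
                            trough_halfwidth_mm = 15) {
  regime <- match.arg(regime)
  stopifnot(d_high_cGy > d_low_cGy, d_low_cGy >= 0, gradient_width_mm > 0)
  direction <- if (regime == "unidirectional") {
    matrix(direction / sqrt(sum(direction^2)), nrow = 1)
  } else {
    direction <- as.matrix(direction)
    if (nrow(direction) != 2) stop("opposing regime needs two direction rows")
    direction / sqrt(rowSums(direction^2))
  }
  structure(list(regime = regime, d_high_cGy = d_high_cGy,
                 d_low_cGy = d_low_cGy,
                 gradient_width_mm = gradient_width_mm,
                 direction = direction,
                 center_mm = if (is.null(center_mm)) NULL else as.numeric(center_mm),
                 trough_halfwidth_mm = trough_halfwidth_mm),
            class = "dose_field_spec")
}

#' Generate a dose grid from a field specification
#'
#' @param spec A [dose_field_spec()].
#' @param grid A [grid_spec()].
#' @return A [dose_grid()].
#' @export
make_dose <- function(spec, grid) {
  stopifnot(inherits(spec, "dose_field_spec"), inherits(grid, "grid_spec"))
  pts <- voxel_centers(grid)
  center <- spec$center_mm
  if (is.null(center)) center <- grid$origin + (grid$dim - 1) * grid$spacing / 2
  rel <- sweep(pts, 2, center)
  k <- spec$gradient_width_mm / 4  # logistic scale: +-2k spans 12-88%
  if (spec$regime == "unidirectional") {
    s <- as.numeric(rel %*% spec$direction[1, ])
    v <- spec$d_low_cGy + (spec$d_high_cGy - spec$d_low_cGy) * stats::plogis(s / k)
  } else {
    s1 <- as.numeric(rel %*% spec$direction[1, ])
    s2 <- as.numeric(rel %*% spec$direction[2, ])
    raw <- stats::plogis((s1 - spec$trough_halfwidth_mm) / k) +
           stats::plogis((s2 - spec$trough_halfwidth_mm) / k)
    rng <- range(raw)
    v <- if (rng[2] > rng[1]) {
      spec$d_low_cGy + (spec$d_high_cGy - spec$d_low_cGy) *
        (raw - rng[1]) / (rng[2] - rng[1])
    } else {
      rep((spec$d_low_cGy + spec$d_high_cGy) / 2, length(raw))
    }
  }
  dose_grid(array(v, grid$dim), grid)
}

# --- cohort -----------------------------------------------------------------

cohort_defaults <- function(regime) {
  if (regime == "parotid-like") {
    list(semi_axes_mm = c(25, 15, 15),
         shape = "ellipsoid",
         dose = list(regime = "unidirectional", d_high_cGy = 6500,
                     d_low_cGy = 400, gradient_width_mm = 20,
                     ramp_offset_mm = 8),
         shift_mm_range = c(0, 6),
         shift_bias = c(-1, 0, 0),  # down-gradient: systematic displacement
         bias_jitter_sd = 0.35,
         dilation_mm_range = c(-2, 2),
         noise_mm_range = c(0.5, 2))
  } else {
    list(semi_axes_mm = c(20, 20, 25),
         shape = "ellipsoid",
         dose = list(regime = "opposing", d_high_cGy = 6500,
                     d_low_cGy = 3500, gradient_width_mm = 15,
                     trough_halfwidth_mm = 20),  # organ boundary on the steep part
         shift_mm_range = c(0, 2),  # well-localized; errors are boundary errors
         shift_bias = NULL,         # isotropic shifts
         bias_jitter_sd = NA,
         dilation_mm_range = c(-3, -0.5),  # systematic undersegmentation
         noise_mm_range = c(0.5, 1))
  }
}

# Grid sized to hold the organ plus shift, noise, and STAPLE ROI margins.
cohort_grid <- function(semi_axes_mm, spacing = 2, margin_mm = 24) {
  half <- semi_axes_mm + margin_mm
  dims <- 2L * ceiling(half / spacing) + 1L
  grid_spec(origin = -(dims - 1) / 2 * spacing, spacing = rep(spacing, 3),
            dim = dims)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic study cohort
#'
#' Builds `n_cases` complete cases for one dose-geometry regime. Each case
#' holds a sampled ground-truth organ (semi-axes jittered +-10%, mild
#' bumpiness), five simulated observer contours, an auto contour whose errors
#' are drawn from the stated ranges, and a matching dose field. Parotid-like
#' cases use a steep unidirectional gradient with auto-contour shifts biased
#' down-gradient (a systematically displaced auto-segmentation); larynx-like
#' cases use opposing gradients with isotropic shifts and systematic
#' undersegmentation. Fully reproducible: the output is a pure function of
#' the arguments and `seed`.
#'
#' @param n_cases Number of cases (>= 3).
#' @param regime `"parotid-like"` or `"larynx-like"`.
#' @param error_ranges Optional list overriding any of `shift_mm_range`,
#'   `dilation_mm_range`, `noise_mm_range`, `shift_bias` (unit bias direction
#'   or `NULL` for isotropic), `bias_jitter_sd`.
#' @param n_raters Observers per case.
#' @param rater_noise_mm Observer boundary-noise sd (mm).
#' @param spacing_mm Isotropic grid spacing (mm).
#' @param bumpiness Organ bumpiness passed to [organ_spec()].
#' @param seed Master seed.
#' @return An object of class `cohort`: list with `cases` (each `case_id`,
#'   `organ_group`, `truth`, `raters`, `auto`, `dose`, `params`), `manifest`
#'   (one data-frame row per case), `regime`, `seed`.
#' @export
generate_cohort <- function(n_cases, regime = c("parotid-like", "larynx-like"),
                            error_ranges = NULL, n_raters = 5L,
                            rater_noise_mm = 1.5, spacing_mm = 2,
                            bumpiness = 0.05, seed = 1L) {
  regime <- match.arg(regime)
  if (n_cases < 3) stop("a cohort needs at least 3 cases")
  def <- cohort_defaults(regime)
  if (!is.null(error_ranges)) {
    for (nm in names(error_ranges)) def[[nm]] <- error_ranges[[nm]]
  }
  grid <- cohort_grid(def$semi_axes_mm, spacing = spacing_mm)

  params <- with_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      axes <- def$semi_axes_mm * stats::runif(3, 0.9, 1.1)
      organ_seed <- sample.int(.Machine$integer.max - 1L, 1)
      rater_seed <- sample.int(.Machine$integer.max - 1L, 1)
      auto_seed <- sample.int(.Machine$integer.max - 1L, 1)
      mag <- stats::runif(1, def$shift_mm_range[1], def$shift_mm_range[2])
      dir <- if (is.null(def$shift_bias)) {
        random_unit_vector()
      } else {
        v <- def$shift_bias / sqrt(sum(def$shift_bias^2)) +
          stats::rnorm(3, 0, def$bias_jitter_sd)
        v / sqrt(sum(v^2))
      }
      list(case_id = sprintf("%s_%03d", gsub("-like", "", regime), i),
           semi_axes_mm = axes, organ_seed = organ_seed,
           rater_seed = rater_seed, auto_seed = auto_seed,
           shift_mm = mag * dir, shift_magnitude_mm = mag,
           dilation_mm = stats::runif(1, def$dilation_mm_range[1],
                                      def$dilation_mm_range[2]),
           noise_mm = stats::runif(1, def$noise_mm_range[1],
                                   def$noise_mm_range[2]))
    })
  })

  cases <- lapply(params, function(p) {
    ospec <- organ_spec(def$shape, p$semi_axes_mm, center_mm = c(0, 0, 0),
                        bumpiness = bumpiness, seed = p$organ_seed)
    truth <- make_organ(ospec, grid)
    truth$label <- paste0(p$case_id, "_truth")
    dspec <- if (def$dose$regime == "unidirectional") {
      dose_field_spec("unidirectional", d_high_cGy = def$dose$d_high_cGy,
                      d_low_cGy = def$dose$d_low_cGy,
                      gradient_width_mm = def$dose$gradient_width_mm,
                      direction = c(1, 0, 0),
                      center_mm = c(def$dose$ramp_offset_mm, 0, 0))
    } else {
      dose_field_spec("opposing", d_high_cGy = def$dose$d_high_cGy,
                      d_low_cGy = def$dose$d_low_cGy,
                      gradient_width_mm = def$dose$gradient_width_mm,
                      direction = rbind(c(1, 0, 0), c(-1, 0, 0)),
                      center_mm = c(0, 0, 0),
                      trough_halfwidth_mm = def$dose$trough_halfwidth_mm)
    }
    dose <- make_dose(dspec, grid)
    raters <- simulate_raters(truth, n = n_raters, noise_mm = rater_noise_mm,
                              seed = p$rater_seed)
    auto <- perturb(truth, error_model(shift_mm = p$shift_mm,
                                       dilation_mm = p$dilation_mm,
                                       boundary_noise_mm = p$noise_mm,
                                       seed = p$auto_seed))
    auto$label <- paste0(p$case_id, "_auto")
    list(case_id = p$case_id, organ_group = regime, truth = truth,
         raters = raters, auto = auto, dose = dose, params = p)
  })

  manifest <- do.call(rbind, lapply(params, function(p) {
    data.frame(case_id = p$case_id, organ_group = regime,
               semi_x_mm = p$semi_axes_mm[1], semi_y_mm = p$semi_axes_mm[2],
               semi_z_mm = p$semi_axes_mm[3],
               organ_seed = p$organ_seed, rater_seed = p$rater_seed,
               auto_seed = p$auto_seed,
               shift_x_mm = p$shift_mm[1], shift_y_mm = p$shift_mm[2],
               shift_z_mm = p$shift_mm[3],
               shift_magnitude_mm = p$shift_magnitude_mm,
               dilation_mm = p$dilation_mm, noise_mm = p$noise_mm)
  }))

  structure(list(cases = cases, manifest = manifest, regime = regime,
                 seed = as.integer(seed), grid = grid),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d %s cases on %s (seed %d)\n", length(x$cases),
              x$regime, format(x$grid), x$seed))
  invisible(x)
}

#' Write a cohort manifest to CSV
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
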