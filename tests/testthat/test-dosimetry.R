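make_linear_dose <- function(grid, a, b_mm) {
  pts <- voxel_centers(grid)
  dose_grid(array(a + b_mm * pts[, 1], grid$dim), grid)
}

test_that("trilinear dose sampling interpolates voxel-center values", {
  g <- unit_grid(10, spacing = 2)
  d_unif <- dose_grid(array(1234, g$dim), g)
  pts <- rbind(c(3.3, 5.7, 9.1), c(0, 0, 0), c(17.9, 2.2, 11))
  expect_equal(sample_dose(d_unif, pts), rep(1234, 3))

  vals <- array(0, g$dim); vals[3, 4, 5] <- 777
  d <- dose_grid(vals, g)
  expect_equal(sample_dose(d, c(4, 6, 8)), 777)  # exactly at center (3,4,5)

  # midpoint between centers valued 100 and 200 -> 150
  ramp <- array(0, g$dim); ramp[3, 4, 5] <- 100; ramp[4, 4, 5] <- 200
  expect_equal(sample_dose(dose_grid(ramp, g), c(5, 6, 8)), 150)

  expect_error(sample_dose(d, c(-5, 0, 0)), "outside")
})

test_that("mean dose is linear in the field and exact for linear gradients", {
  g <- grid_spec(c(-15, -15, -15), c(1, 1, 1), c(31, 31, 31))
  s <- ellipsoid_structure(g, c(9, 7, 7))
  d_unif <- dose_grid(array(500, g$dim), g)
  expect_equal(mean_dose(d_unif, s), 500)

  # linear field: mean dose = field at the centroid (x-symmetric structure)
  d_lin <- make_linear_dose(g, 2000, 40)
  expect_equal(mean_dose(d_lin, s), 2000 + 40 * centroid_mm(s)[1],
               tolerance = 1e-9)

  # linearity: mean(alpha D1 + beta D2) = alpha mean(D1) + beta mean(D2)
  d_mix <- dose_grid(0.3 * d_unif$values + 1.7 * d_lin$values, g)
  expect_equal(mean_dose(d_mix, s),
               0.3 * mean_dose(d_unif, s) + 1.7 * mean_dose(d_lin, s),
               tolerance = 1e-9)

  # structure on a finer grid than the dose: mean within 1%
  g2 <- grid_spec(c(-15, -15, -15), c(0.5, 0.5, 0.5), c(61, 61, 61))
  s2 <- ellipsoid_structure(g2, c(9, 7, 7))
  expect_equal(mean_dose(d_lin, s2), mean_dose(d_lin, s),
               tolerance = 0.01)

  # structure poking out of the dose grid is an error
  g_small <- grid_spec(c(-3, -3, -3), c(1, 1, 1), c(7, 7, 7))
  d_small <- dose_grid(array(100, g_small$dim), g_small)
  expect_error(mean_dose(d_small, s), "outside the dose grid")
})

test_that("dosimetric accuracy follows its defining formula", {
  expect_equal(dosimetric_accuracy(2470, 2600)$accuracy_pct, -5)
  expect_equal(dosimetric_accuracy(1500, 1500)$accuracy_pct, 0)
  expect_equal(dosimetric_accuracy(514, 376)$accuracy_pct, 100 * (514 - 376) / 376)
  expect_equal(round(dosimetric_accuracy(514, 376)$accuracy_pct, 1), 36.7)
  expect_error(dosimetric_accuracy(100, 0), "positive")
  expect_error(dosimetric_accuracy(100, -5), "positive")
  # no antisymmetry under swapping: denominator is the truth
  expect_false(isTRUE(all.equal(dosimetric_accuracy(514, 376)$accuracy_pct,
                                -dosimetric_accuracy(376, 514)$accuracy_pct)))
})

test_that("interobserver variation summarizes per-rater dose differences", {
  g <- grid_spec(c(-15, -15, -15), c(1, 1, 1), c(31, 31, 31))
  s <- ellipsoid_structure(g, c(8, 6, 6))
  d <- make_linear_dose(g, 3000, 50)

  rs_same <- rater_set(list(s, s, s))
  iov0 <- interobserver_variation(d, rs_same, s)
  expect_equal(unname(iov0$per_rater_pct), c(0, 0, 0))
  expect_equal(iov0$min_pct, 0)
  expect_equal(iov0$max_pct, 0)

  # one rater shifted up-gradient: exactly one nonzero entry, the maximum
  up <- voxel_structure(s$mask, grid_spec(g$origin + c(2, 0, 0), g$spacing, g$dim))
  up <- resample_structure(up, g)
  iov1 <- interobserver_variation(d, rater_set(list(s, up, s)), s)
  expect_equal(sum(iov1$per_rater_pct != 0), 1)
  expect_gt(iov1$max_pct, 0)
  expect_equal(iov1$max_pct, unname(iov1$per_rater_pct[2]))

  # order statistics match a direct sort oracle on noisy raters
  set.seed(88)
  raters <- simulate_raters(s, n = 5, noise_mm = 1.5, seed = 5)
  iov <- interobserver_variation(d, raters, s)
  v <- sort(unname(iov$per_rater_pct))
  expect_equal(iov$min_pct, v[1])
  expect_equal(iov$max_pct, v[5])
  expect_equal(iov$median_pct, v[3])
  expect_true(iov$min_pct <= iov$q1_pct && iov$q1_pct <= iov$median_pct &&
                iov$median_pct <= iov$q3_pct && iov$q3_pct <= iov$max_pct)
})

test_that("outside-IOV flag treats the whisker as inside", {
  iov <- structure(list(per_rater_pct = c(-2, -1, 0, 1, 2),
                        min_pct = -2, q1_pct = -1, median_pct = 0,
                        q3_pct = 1, max_pct = 2), class = "iov")
  expect_false(outside_iov(0, iov))
  expect_false(outside_iov(2, iov))    # boundary counts as inside
  expect_false(outside_iov(-2, iov))
  expect_true(outside_iov(2.1, iov))
  expect_true(outside_iov(-2.0001, iov))
})

test_that("accuracy of a rigid shift is proportional to its up-gradient component", {
  g <- grid_spec(c(-16, -16, -16), c(1, 1, 1), c(33, 33, 33))
  s <- ellipsoid_structure(g, c(8, 6, 6))
  d <- make_linear_dose(g, 4000, 60)
  truth_dose <- mean_dose(d, s)
  shifts <- c(1, 2, 3, 4)
  acc <- sapply(shifts, function(t) {
    sh <- perturb(s, error_model(shift_mm = c(t, 0, 0)))
    dosimetric_accuracy(mean_dose(d, sh), truth_dose)$accuracy_pct
  })
  expected <- 100 * 60 * shifts / 4000
  expect_equal(acc, expected, tolerance = 0.05)
  expect_true(all(diff(acc) > 0))
})
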