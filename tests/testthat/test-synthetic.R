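test_that("organ generation hits analytic volumes and is seed-deterministic", {
  g <- grid_spec(c(-20, -20, -20), c(1, 1, 1), c(41, 41, 41))
  smooth <- make_organ(organ_spec("ellipsoid", c(15, 10, 10), c(0, 0, 0),
                                  bumpiness = 0, seed = 1), g)
  expect_equal(volume_mm3(smooth), 4 / 3 * pi * 15 * 10 * 10, tolerance = 0.05)

  # bumpiness 0: seed is irrelevant
  other_seed <- make_organ(organ_spec("ellipsoid", c(15, 10, 10), c(0, 0, 0),
                                      bumpiness = 0, seed = 999), g)
  expect_identical(smooth$mask, other_seed$mask)

  # same spec + seed -> bit-identical; different seed -> different but close
  b1 <- make_organ(organ_spec("ellipsoid", c(15, 10, 10), c(0, 0, 0), 0.1, 7), g)
  b1b <- make_organ(organ_spec("ellipsoid", c(15, 10, 10), c(0, 0, 0), 0.1, 7), g)
  b2 <- make_organ(organ_spec("ellipsoid", c(15, 10, 10), c(0, 0, 0), 0.1, 8), g)
  expect_identical(b1$mask, b1b$mask)
  expect_false(identical(b1$mask, b2$mask))
  expect_gt(dice(smooth, b1), 0.9)  # mild perturbation

  expect_error(make_organ(organ_spec("ellipsoid", c(30, 10, 10), c(0, 0, 0)), g),
               "exceeds the grid")
  for (shape in c("superellipsoid", "lobed_blob")) {
    s <- make_organ(organ_spec(shape, c(12, 9, 9), c(0, 0, 0), 0.05, 3), g)
    expect_gt(volume_mm3(s), 0)
  }
})

test_that("perturbation applies noise, dilation and shift as specified", {
  g <- grid_spec(c(-24, -24, -24), c(2, 2, 2), c(25, 25, 25))
  org <- ellipsoid_structure(g, c(15, 10, 10))

  expect_identical(perturb(org, error_model())$mask, org$mask)

  sh <- perturb(org, error_model(shift_mm = c(3, 0, 0)))
  expect_equal(centroid_separation(sh, org), 3, tolerance = 0.2 / 3)

  dil <- perturb(org, error_model(dilation_mm = 2))
  mr <- compute_metrics(dil, org)
  expect_gt(mr$ci, 1)
  expect_equal(mr$mean_dta_mm, 2, tolerance = 0.25)

  ero <- perturb(org, error_model(dilation_mm = -2))
  expect_lt(volume_mm3(ero), volume_mm3(org))

  expect_error(perturb(org, error_model(dilation_mm = -40)), "emptied")

  n1 <- perturb(org, error_model(boundary_noise_mm = 1.5, seed = 4))
  n1b <- perturb(org, error_model(boundary_noise_mm = 1.5, seed = 4))
  n2 <- perturb(org, error_model(boundary_noise_mm = 1.5, seed = 5))
  expect_identical(n1$mask, n1b$mask)
  expect_false(identical(n1$mask, n2$mask))
})

test_that("simulated raters scatter plausibly around the truth", {
  g <- grid_spec(c(-24, -24, -24), c(2, 2, 2), c(25, 25, 25))
  truth <- ellipsoid_structure(g, c(15, 15, 15))

  zero <- simulate_raters(truth, n = 3, noise_mm = 0, seed = 1)
  for (r in zero$raters) expect_identical(r$mask, truth$mask)

  rs <- simulate_raters(truth, n = 5, noise_mm = 1.5, seed = 2)
  pair_dice <- c()
  for (i in 1:4) for (j in (i + 1):5)
    pair_dice <- c(pair_dice, dice(rs$raters[[i]], rs$raters[[j]]))
  expect_true(all(pair_dice > 0.8 & pair_dice < 1))

  # STAPLE of the raters tracks truth at least as well as any single rater
  cons <- staple_consensus(staple(rs))
  expect_gte(dice(cons, truth), max(sapply(rs$raters, dice, truth)) - 0.02)
})

test_that("dose fields realize the stated gradient regimes", {
  g <- grid_spec(c(-40, -40, -40), c(2, 2, 2), c(41, 41, 41))
  uni <- make_dose(dose_field_spec("unidirectional", d_high_cGy = 6000,
                                   d_low_cGy = 400, gradient_width_mm = 20,
                                   direction = c(1, 0, 0), center_mm = c(0, 0, 0)), g)
  expect_equal(sample_dose(uni, c(38, 0, 0)), 6000, tolerance = 0.01)
  expect_equal(sample_dose(uni, c(-38, 0, 0)), 400, tolerance = 0.01)

  opp <- make_dose(dose_field_spec("opposing", d_high_cGy = 6500,
                                   d_low_cGy = 3500, gradient_width_mm = 15,
                                   direction = rbind(c(1, 0, 0), c(-1, 0, 0)),
                                   center_mm = c(0, 0, 0),
                                   trough_halfwidth_mm = 20), g)
  # symmetric trough: center is the minimum along the midline
  midline <- sapply(seq(-38, 38, by = 2), function(x) sample_dose(opp, c(x, 0, 0)))
  expect_equal(sample_dose(opp, c(0, 0, 0)), min(midline))
  expect_equal(min(opp$values), 3500)
  expect_equal(max(opp$values), 6500)

  # shifting an organ up-gradient strictly increases its mean dose
  org <- ellipsoid_structure(g, c(15, 10, 10))
  means <- sapply(0:4, function(t) {
    s <- if (t == 0) org else perturb(org, error_model(shift_mm = c(2 * t, 0, 0)))
    mean_dose(uni, s)
  })
  expect_true(all(diff(means) > 0))

  # opposing regime: a +-x shift pair at the study's shift scale changes the
  # mean dose little, and the two changes cancel each other
  lar <- ellipsoid_structure(g, c(20, 20, 20))
  m0 <- mean_dose(opp, lar)
  mp <- mean_dose(opp, perturb(lar, error_model(shift_mm = c(2, 0, 0))))
  mm <- mean_dose(opp, perturb(lar, error_model(shift_mm = c(-2, 0, 0))))
  expect_lt(abs((mp - m0) + (mm - m0)) / m0 * 100, 2)
  expect_lt(abs(mp - m0) / m0 * 100, 2)
})

test_that("cohorts are complete and byte-for-byte reproducible", {
  co <- generate_cohort(3, "parotid-like", seed = 42)
  expect_length(co$cases, 3)
  for (cs in co$cases) {
    expect_gt(sum(cs$truth$mask), 0)
    expect_gt(sum(cs$auto$mask), 0)
    for (r in cs$raters$raters) expect_gt(sum(r$mask), 0)
    expect_s3_class(cs$dose, "dose_grid")
  }
  co2 <- generate_cohort(3, "parotid-like", seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_manifest(co, f1); write_manifest(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # masks identical too, not just the manifest
  expect_identical(co$cases[[2]]$auto$mask, co2$cases[[2]]$auto$mask)
  co3 <- generate_cohort(3, "parotid-like", seed = 43)
  expect_false(identical(co$cases[[1]]$auto$mask, co3$cases[[1]]$auto$mask))

  expect_error(generate_cohort(2, "parotid-like"), "at least 3")
})
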