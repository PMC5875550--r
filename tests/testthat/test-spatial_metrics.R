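test_that("dice matches voxel counting, is symmetric and bounded", {
  g <- unit_grid(20)
  a <- box_structure(g, c(3, 12), c(3, 12), c(3, 12))
  b <- box_structure(g, c(8, 17), c(3, 12), c(3, 12))  # 5-voxel x offset
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)  # 2*500 / (1000 + 1000)
  expect_equal(dice(a, b), dice(b, a))
  disjoint <- box_structure(g, c(15, 18), c(15, 18), c(15, 18))
  expect_equal(dice(a, disjoint), 0)
  empty <- voxel_structure(array(FALSE, g$dim), g)
  expect_equal(dice(a, empty), 0)
  expect_error(dice(empty, empty), "undefined")

  # monotone decrease with increasing axis shift of a convex mask
  d_by_shift <- sapply(0:6, function(k) {
    shifted <- box_structure(g, c(3 + k, 12 + k), c(3, 12), c(3, 12))
    dice(a, shifted)
  })
  expect_true(all(diff(d_by_shift) < 0))
})

test_that("conformity index is the auto/reference volume ratio", {
  g <- unit_grid(16)
  ref <- box_structure(g, c(4, 9), c(4, 9), c(4, 9))
  expect_equal(conformity_index(ref, ref), 1)
  bigger <- box_structure(g, c(4, 9), c(4, 9), c(2, 13))  # 2x z extent
  expect_equal(conformity_index(bigger, ref), 2)
  empty <- voxel_structure(array(FALSE, g$dim), g)
  expect_equal(conformity_index(empty, ref), 0)
  expect_error(conformity_index(ref, empty), "empty")
})

test_that("centroid separation is the Euclidean centroid distance", {
  g <- unit_grid(24)
  a <- box_structure(g, c(5, 10), c(5, 10), c(5, 10))
  expect_equal(centroid_separation(a, a), 0)
  b <- box_structure(g, c(8, 13), c(5, 10), c(5, 10))   # 3 mm along x
  expect_equal(centroid_separation(a, b), 3)
  c345 <- box_structure(g, c(8, 13), c(9, 14), c(5, 10))  # (3,4,0) mm
  expect_equal(centroid_separation(a, c345), 5)
})

test_that("directed DTA histograms equal all-pairs nearest-neighbor minima", {
  p1 <- structure(list(points = matrix(c(0, 0, 0), 1), source_label = "a"),
                  class = "surface_cloud")
  p2 <- structure(list(points = matrix(c(7, 0, 0), 1), source_label = "b"),
                  class = "surface_cloud")
  expect_equal(dta_histogram(p1, p2)$distances, 7)
  expect_equal(dta_histogram(p1, p1)$distances, 0)

  g <- unit_grid(24)
  cube <- box_structure(g, c(4, 13), c(4, 13), c(4, 13))
  shifted <- box_structure(g, c(7, 16), c(4, 13), c(4, 13))  # 3 mm along x
  sa <- extract_surface(cube); sb <- extract_surface(shifted)
  h <- dta_histogram(sa, sb)
  expect_equal(max(h$distances), 3)
  expect_equal(h$distances, oracle_min_dists(sa$points, sb$points),
               tolerance = 1e-12)

  # symmetric variant pools both directions
  hs <- dta_histogram_symmetric(sa, sb)
  expect_identical(length(hs$distances),
                   nrow(sa$points) + nrow(sb$points))
})

test_that("DTA summaries use mean, max and interpolated 95th percentile", {
  h <- structure(list(distances = rep(2.5, 40)), class = "dta_histogram")
  s <- summarize_dta(h)
  expect_equal(unlist(s), c(mean_dta_mm = 2.5, max_dta_mm = 2.5, hd95_mm = 2.5))

  h2 <- structure(list(distances = c(rep(0, 95), rep(10, 5))),
                  class = "dta_histogram")
  s2 <- summarize_dta(h2)
  expect_equal(s2$mean_dta_mm, 0.5)
  expect_equal(s2$max_dta_mm, 10)

  # 1..100: order-statistic rule gives (1-p)*x_(95) + p*x_(96) at h = 95.05
  h3 <- structure(list(distances = sample(1:100)), class = "dta_histogram")
  expect_equal(summarize_dta(h3)$hd95_mm, 95.05)
  expect_error(summarize_dta(structure(list(distances = numeric(0)),
                                       class = "dta_histogram")), "empty")
})

test_that("hd95 never exceeds max and distances scale with spacing", {
  set.seed(21)
  for (rep in 1:10) {
    d <- runif(sample(5:60, 1), 0, 20)
    h <- structure(list(distances = d), class = "dta_histogram")
    s <- summarize_dta(h)
    expect_lte(s$hd95_mm, s$max_dta_mm)
  }
  # same index mask at spacing s and 2s: all summaries double
  m <- array(FALSE, c(10, 10, 10)); m[3:7, 4:6, 5:8] <- TRUE
  m2 <- array(FALSE, c(10, 10, 10)); m2[5:9, 4:6, 5:8] <- TRUE
  g1 <- unit_grid(10, spacing = 1)
  g2 <- unit_grid(10, spacing = 2)
  r1 <- compute_metrics(voxel_structure(m2, g1), voxel_structure(m, g1))
  r2 <- compute_metrics(voxel_structure(m2, g2), voxel_structure(m, g2))
  expect_equal(r1$dsc, r2$dsc)
  expect_equal(r1$ci, r2$ci)
  for (f in c("centroid_sep_mm", "mean_dta_mm", "max_dta_mm", "hd95_mm"))
    expect_equal(2 * r1[[f]], r2[[f]], tolerance = 1e-12)
})

test_that("directed max DTA of an axis-shifted convex mask equals the shift", {
  g <- unit_grid(26)
  base <- ellipsoid_structure(grid_spec(c(-12, -12, -12), c(1, 1, 1), c(25, 25, 25)),
                              c(8, 6, 6))
  for (k in 1:4) {
    g2 <- grid_spec(base$grid$origin + c(k, 0, 0), base$grid$spacing, base$grid$dim)
    shifted <- voxel_structure(base$mask, g2)
    mr <- compute_metrics(shifted, base)
    expect_equal(mr$max_dta_mm, k)
    expect_equal(mr$centroid_sep_mm, k)
  }
})

test_that("compute_metrics agrees with brute-force oracles on random pairs", {
  set.seed(99)
  for (rep in 1:50) {
    g <- grid_spec(runif(3, -3, 3), runif(3, 0.6, 1.8), sample(6:10, 3, replace = TRUE))
    a <- random_blob(g, n_balls = 2, label = "auto")
    b <- random_blob(g, n_balls = 2, label = "ref")
    mr <- compute_metrics(a, b)
    expect_equal(mr$dsc, oracle_dice(a, b), tolerance = 1e-12)
    expect_equal(mr$ci, oracle_volume(a) / oracle_volume(b), tolerance = 1e-12)
    expect_equal(mr$centroid_sep_mm,
                 sqrt(sum((oracle_centroid(a) - oracle_centroid(b))^2)),
                 tolerance = 1e-12)
    d <- oracle_min_dists(extract_surface(b)$points, extract_surface(a)$points)
    expect_equal(mr$mean_dta_mm, mean(d), tolerance = 1e-9)
    expect_equal(mr$max_dta_mm, max(d), tolerance = 1e-9)
    expect_equal(mr$hd95_mm, unname(quantile(d, 0.95, type = 7)), tolerance = 1e-9)
  }
})

test_that("identity and dilation cases populate the metric record sensibly", {
  g <- grid_spec(c(-16, -16, -16), c(1, 1, 1), c(33, 33, 33))
  ref <- ellipsoid_structure(g, c(10, 8, 8))
  mi <- compute_metrics(ref, ref)
  expect_equal(unlist(mi[1:6]),
               c(dsc = 1, ci = 1, centroid_sep_mm = 0, mean_dta_mm = 0,
                 max_dta_mm = 0, hd95_mm = 0))
  dil <- perturb(ref, error_model(dilation_mm = 1))
  md <- compute_metrics(dil, ref)
  expect_gt(md$ci, 1)
  expect_lt(md$centroid_sep_mm, 0.3)
})
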