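well_map_1 <- function(size = 40L) {
  data.frame(well = 1L, row = 1L, col = 1L, x = size / 2, y = size / 2,
             piece = 1L)
}

test_that("segmentation recovers rendered objects per well", {
  set.seed(2)
  img <- render_test_well(data.frame(dy = 0, dx = 0), a = 5, noise_sd = 30)
  seg <- segment_wells(img, well_map_1(), well_radius_px = 12,
                       well_pitch_px = 40)
  expect_length(seg, 1L)
  expect_equal(max(seg[[1]]$label), 1L)
  rendered_area <- pi * 5 * (5 / 1.25)
  expect_lt(abs(nrow(seg[[1]]) / rendered_area - 1), 0.15)

  blank <- matrix(200 + rnorm(1600, sd = 30), 40, 40)
  expect_length(segment_wells(blank, well_map_1(), 12, 40), 0L)

  two <- render_test_well(data.frame(dy = c(-9, 9), dx = c(-9, 9)),
                          a = c(4, 4), noise_sd = 30)
  seg2 <- segment_wells(two, well_map_1(), well_radius_px = 16,
                        well_pitch_px = 40)
  expect_equal(max(seg2[[1]]$label), 2L)
})

disk_mask <- function(r) {
  o <- scopelink:::disk_offsets(r)
  data.frame(y = o$dy + 50, x = o$dx + 50)
}

ellipse_mask <- function(a, b, theta = 0) {
  px <- scopelink:::cell_pixels(60, 60, a, b, theta, 0, 0, 120, 120)
  px[, c("y", "x")]
}

test_that("feature panel has the right shape and disk symmetry", {
  m <- disk_mask(8)
  f <- compute_features(m, rep(100, nrow(m)))
  expect_named(f, imaging_feature_names())
  expect_length(f, 19L)
  expect_true(all(is.finite(f)))
  expect_lt(f["eccentricity"], 0.25)
  expect_lt(abs(f["circularity"] - 1), 0.15)
  expect_gt(f["solidity"], 0.92)
  expect_lt(abs(f["aspect_ratio"] - 1), 0.1)
  expect_error(compute_features(m[0, ], numeric(0)), "empty mask")
})

test_that("intensity features obey the homogeneity contract", {
  set.seed(9)
  m <- disk_mask(8)
  v <- rlnorm(nrow(m), log(100), 0.4)
  f1 <- compute_features(m, v)
  f2 <- compute_features(m, 2 * v)
  scale2 <- c("int_total", "int_mean", "int_sd")
  invariant <- setdiff(imaging_feature_names(), scale2)
  expect_equal(unname(f2[scale2]), unname(2 * f1[scale2]))
  expect_equal(unname(f2[invariant]), unname(f1[invariant]), tolerance = 1e-10)
})

test_that("axis features match rendered ellipse geometry", {
  m <- ellipse_mask(a = 12, b = 6, theta = pi / 5)
  f <- compute_features(m, rep(1, nrow(m)))
  expect_lt(abs(f["aspect_ratio"] - 2), 0.15)
  expect_lt(abs(f["major_axis"] / 24 - 1), 0.1)
  expect_lt(abs(f["minor_axis"] / 12 - 1), 0.1)
  expect_lt(abs(f["area"] / (pi * 12 * 6) - 1), 0.1)
})

test_that("features are invariant to whole-pixel translation", {
  set.seed(3)
  m <- ellipse_mask(7, 5, 0.3)
  v <- rlnorm(nrow(m), log(50), 0.3)
  m2 <- data.frame(y = m$y + 11L, x = m$x - 4L)
  expect_equal(compute_features(m, v), compute_features(m2, v))
})

test_that("size features scale correctly under 2x magnification", {
  f1 <- compute_features(ellipse_mask(6, 4),
                         rep(1, nrow(ellipse_mask(6, 4))))
  f2 <- compute_features(ellipse_mask(12, 8),
                         rep(1, nrow(ellipse_mask(12, 8))))
  expect_lt(abs(f2["area"] / (4 * f1["area"]) - 1), 0.05)
  expect_lt(abs(f2["perimeter"] / (2 * f1["perimeter"]) - 1), 0.05)
  expect_lt(abs(f2["equiv_diameter"] / (2 * f1["equiv_diameter"]) - 1), 0.05)
  # discretisation error at radius ~5 px dominates the shape features
  for (s in c("aspect_ratio", "eccentricity", "circularity", "solidity")) {
    expect_lt(abs(f2[s] / f1[s] - 1), 0.15)
  }
})

test_that("species label call follows threshold and mixed-band semantics", {
  expect_equal(call_species_label(1000, 10, threshold = 100),
               "speciesA")
  expect_equal(call_species_label(10, 1000, threshold = 100),
               "speciesB")
  expect_equal(call_species_label(500, 480, threshold = 100,
                                  band = c(0.8, 1.25)),
               "mixed")
  expect_equal(call_species_label(50, 40, threshold = 100), "none")
})

test_that("monochrome multiplet flag fires on count, area, or solidity", {
  expect_true(detect_multiplet_monochrome(2L, 30, 0.95, 100, 0.8))
  expect_true(detect_multiplet_monochrome(1L, 150, 0.95, 100, 0.8))
  expect_true(detect_multiplet_monochrome(1L, 30, 0.5, 100, 0.8))
  expect_false(detect_multiplet_monochrome(1L, 30, 0.95, 100, 0.8))
})

test_that("imaging records match simulation truth on the shared run", {
  run <- shared_run()
  sim <- run$sim
  rec <- run$imaging
  truth <- sim$cells$wells_truth
  n_cells <- truth$n_cells[match(rec$well, truth$well)]
  # imaging species label matches truth for nearly all singlets
  singles <- rec[n_cells == 1L, ]
  sp_truth <- sim$cells$cells$species[match(singles$well, sim$cells$cells$well)]
  agree <- mean(singles$species_label == sp_truth)
  expect_gte(agree, 0.99)
  # multiplet flag rate is monotone in the true cell count
  flag_rate <- tapply(rec$multiplet_mono, pmin(n_cells, 3L), mean)
  expect_true(all(diff(flag_rate) >= 0))
})
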