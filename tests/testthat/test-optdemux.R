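test_that("bead detection finds exactly the rendered beads", {
  cfg <- tiny_cfg(snr = 8)
  beads <- simulate_beads(cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  occ <- detect_beads(hyb$reference, hyb$wells, cfg$bead_radius_px,
                      cfg$well_radius_px, cfg$well_pitch_px)
  expect_setequal(occ, beads$well)
  # blank reference: nothing detected
  blank <- matrix(400 + rnorm(length(hyb$reference), sd = 60),
                  nrow(hyb$reference))
  expect_length(detect_beads(blank, hyb$wells, cfg$bead_radius_px,
                             cfg$well_radius_px, cfg$well_pitch_px), 0L)
})

test_that("bead detection is near-perfect at moderate SNR", {
  cfg <- scope_config(n_wells = 2500L, grid_rows = 50L, grid_cols = 50L,
                      n_pieces = 1L, bead_loading_rate = 0.6, snr = 5,
                      rng_seed = 17L)
  beads <- simulate_beads(cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  occ <- detect_beads(hyb$reference, hyb$wells, cfg$bead_radius_px,
                      cfg$well_radius_px, cfg$well_pitch_px)
  tp <- length(intersect(occ, beads$well))
  prec <- tp / length(occ)
  rec <- tp / nrow(beads)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.99)
})

test_that("frame registration recovers planted shifts and flags noise", {
  cfg <- tiny_cfg(jitter_px = 0, snr = 10)
  beads <- simulate_beads(cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  reg0 <- register_frames(hyb$stack, hyb$reference)
  expect_true(all(reg0$dy == 0 & reg0$dx == 0))
  # plant a known (+1, +2) shift into one frame by rolling the reference
  H <- nrow(hyb$reference); W <- ncol(hyb$reference)
  shifted <- matrix(400, H, W)
  shifted[2:H, 3:W] <- hyb$reference[1:(H - 1), 1:(W - 2)]
  stack2 <- hyb$stack
  stack2[, , 1] <- shifted
  reg2 <- register_frames(stack2, hyb$reference)
  expect_equal(c(reg2$dy[1], reg2$dx[1]), c(1, 2))
  # a pure-noise frame cannot be registered
  stack2[, , 2] <- matrix(400 + rnorm(H * W, sd = 60), H, W)
  reg3 <- register_frames(stack2, hyb$reference)
  expect_false(reg3$ok[2])
})

test_that("the two-class threshold separates well-separated clusters", {
  set.seed(4)
  x <- c(rnorm(60, 0, 0.5), rnorm(40, 10, 0.5))
  thr <- otsu_threshold(x)
  expect_gt(thr, 2)
  expect_lt(thr, 8)
})

test_that("noiseless stacks decode every code exactly, including code zero", {
  cfg <- tiny_cfg(bit_flip_rate = 0, jitter_px = 1, snr = 50)
  beads <- simulate_beads(cfg)
  beads$code[1] <- 0L                       # plant an all-zeros bead
  beads$bits[1] <- strrep("0", 12)
  hyb <- simulate_hybridization_stack(beads, cfg)
  calls <- demux_stack(hyb, cfg)
  m <- match(calls$well, beads$well)
  expect_true(all(!is.na(m)))
  expect_equal(calls$code, beads$code[m])
  expect_true(all(calls$flag == "pass"))
  # the code-0 bead is still present as an occupied well, not dropped
  expect_true(beads$well[1] %in% calls$well)
  # and no call is emitted for unoccupied wells
  expect_true(all(calls$well %in% beads$well))
})

test_that("pass fraction responds monotonically to noise and flips", {
  grid <- expand.grid(flip = c(0, 0.02, 0.1), snr = c(2.5, 5, 10))
  frac <- mapply(function(flip, snr) {
    cfg <- tiny_cfg(bit_flip_rate = flip, snr = snr, rng_seed = 31L)
    beads <- simulate_beads(cfg)
    hyb <- simulate_hybridization_stack(beads, cfg)
    calls <- demux_stack(hyb, cfg)
    mean(calls$flag == "pass")
  }, grid$flip, grid$snr)
  m <- matrix(frac, nrow = 3, dimnames = list(flip = NULL, snr = NULL))
  # non-decreasing in SNR at each flip rate; flips may not help (weak check)
  for (i in 1:3) expect_true(all(diff(m[i, ]) >= -0.05))
  for (j in 1:3) expect_true(all(diff(m[, j]) <= 0.05))
})
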