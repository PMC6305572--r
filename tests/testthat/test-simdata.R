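test_that("optical code encodings round-trip and index bits correctly", {
  set.seed(1)
  codes <- sample(0:4095, 50)
  bits <- code_to_bits(codes, 12L)
  expect_true(all(nchar(bits) == 12L))
  expect_identical(bits_to_code(bits), as.integer(codes))
  expect_identical(code_bit(5L, 1L), TRUE)   # 5 = 101 -> bits 1 and 3
  expect_identical(code_bit(5L, 2L), FALSE)
  expect_identical(code_bit(5L, 3L), TRUE)
})

test_that("simulated bead codes fill the configured codespace uniformly", {
  cfg <- scope_config(n_wells = 20000L, bead_loading_rate = 0.5,
                      rng_seed = 11L)
  beads <- simulate_beads(cfg)
  expect_equal(nrow(beads), 10000L)
  expect_true(all(beads$code >= 0 & beads$code < 4096))
  expect_false(anyDuplicated(beads$sequencing_barcode) > 0)
  # chi-square goodness of fit against the uniform over 2^12 codes
  obs <- tabulate(beads$code + 1L, nbins = 4096L)
  x2 <- sum((obs - 10000 / 4096)^2 / (10000 / 4096))
  expect_gt(pchisq(x2, df = 4095, lower.tail = FALSE), 0.01)
  # per-bit frequencies ~ 0.5 within the binomial 99.9% interval
  bitfreq <- colMeans(scopelink:::code_bit_matrix(beads$code, 12L))
  expect_true(all(abs(bitfreq - 0.5) < 3.3 * sqrt(0.25 / 10000)))
})

test_that("one-bead config is reproducible and bounded by the codespace", {
  cfg <- scope_config(n_obos = 2L, n_split_cycles = 1L, bits_per_cycle = 2L,
                      n_wells = 2L, grid_rows = 1L, grid_cols = 2L,
                      n_pieces = 1L, bead_loading_rate = 0.5, rng_seed = 3L)
  b1 <- simulate_beads(cfg)
  b2 <- simulate_beads(cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 1L)
  expect_true(b1$code %in% 0:3)
})

test_that("bead-free reads appear exactly in the pools of the bead's bits", {
  cfg <- tiny_cfg(seq_error_rate = 0, beadfree_depth = 12)
  beads <- simulate_beads(cfg)
  pools <- simulate_beadfree_reads(beads, cfg)
  expect_named(pools, sprintf("pool_%02d", 1:12))
  bits <- scopelink:::code_bit_matrix(beads$code, 12L)
  for (k in c(1L, 5L, 12L)) {
    in_pool <- unique(pools[[k]]$seq)
    expected <- beads$sequencing_barcode[bits[, k]]
    # Poisson depth can zero a bead out of a pool, never add one
    expect_true(all(in_pool %in% expected))
    expect_gt(length(in_pool), 0.9 * length(expected))
  }
})

test_that("hybridization stack renders codes with recorded flips and shifts", {
  cfg <- tiny_cfg(bit_flip_rate = 0, jitter_px = 0, snr = 50)
  beads <- simulate_beads(cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  expect_equal(dim(hyb$stack)[3], 12L)
  expect_equal(nrow(hyb$truth$flips), 0L)
  expect_true(all(hyb$truth$shifts$dy == 0 & hyb$truth$shifts$dx == 0))
  # bead with all its bits off leaves background; on-bits are bright
  wm <- hyb$wells
  b <- beads[1, ]
  px_y <- round(wm$y[b$well]); px_x <- round(wm$x[b$well])
  for (k in 1:12) {
    v <- hyb$stack[px_y, px_x, k]
    if (code_bit(b$code, k)) expect_gt(v, 700) else expect_lt(v, 700)
  }
  # flips are recorded when planted
  cfg2 <- cfg_with(cfg, bit_flip_rate = 0.2)
  hyb2 <- simulate_hybridization_stack(simulate_beads(cfg2), cfg2)
  expect_gt(nrow(hyb2$truth$flips), 0L)
})

test_that("per-cell transcript totals hit the configured mean", {
  cfg <- scope_config(n_wells = 900L, grid_rows = 30L, grid_cols = 30L,
                      n_pieces = 1L, cell_loading_rate = 0.5,
                      mean_transcripts_per_cell = 3600,
                      n_genes_per_species = 40L, rng_seed = 5L)
  beads <- simulate_beads(cfg)
  sim <- simulate_cells_and_expression(beads, cfg)
  expect_gt(nrow(sim$cells), 250L)
  expect_lt(abs(mean(sim$cells$total_umis) / 3600 - 1), 0.05)
})

test_that("a lone cell's counts come entirely from its species panel", {
  cfg <- tiny_cfg(crosstalk_rate = 0, ambient_umis_per_bead = 0,
                  cell_loading_rate = 0.2)
  beads <- simulate_beads(cfg)
  sim <- simulate_cells_and_expression(beads, cfg)
  singletons <- subset(sim$cells, !is.na(sequencing_barcode))
  singletons <- singletons[singletons$well %in%
    sim$wells_truth$well[sim$wells_truth$n_cells == 1L], ]
  expect_gt(nrow(singletons), 0L)
  for (i in seq_len(min(5L, nrow(singletons)))) {
    cs <- sim$counts[, singletons$sequencing_barcode[i]]
    sp <- sim$gene_ref$species[cs > 0]
    expect_true(all(sp == singletons$species[i]))
  }
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- tiny_cfg()
  s1 <- simulate_experiment(cfg, reads = TRUE)
  s2 <- simulate_experiment(cfg, reads = TRUE)
  expect_identical(s1$beads, s2$beads)
  expect_identical(s1$beadfree, s2$beadfree)
  expect_identical(s1$hyb$stack, s2$hyb$stack)
  expect_identical(s1$hyb$reference, s2$hyb$reference)
  expect_identical(s1$cells$counts, s2$cells$counts)
  expect_identical(s1$cells$cells, s2$cells$cells)
  expect_identical(s1$screads, s2$screads)
})

test_that("image and FASTQ round trips through disk preserve content", {
  cfg <- tiny_cfg()
  beads <- simulate_beads(cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  d <- withr::local_tempdir()
  f <- file.path(d, "stack.tiff")
  write_stack(hyb$stack, f)
  back <- read_stack(f)
  expect_equal(dim(back), dim(hyb$stack))
  # 16-bit quantisation: within one grey level
  expect_lt(max(abs(back - pmax(pmin(hyb$stack, 65535), 0))), 1.01)
  pools <- simulate_beadfree_reads(beads, cfg, dir = d)
  rt <- read_fastq(file.path(d, "pool_01.fastq"))
  expect_equal(rt$seq, pools[["pool_01"]]$seq)
})
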