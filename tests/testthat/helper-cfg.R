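# configuration factories for tests: small devices, desk-scale read depths

cfg_with <- function(cfg, ...) {
  args <- utils::modifyList(unclass(cfg), list(...))
  do.call(scope_config, args)
}

# 100-well device, 2 pieces: fast enough for per-module checks
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_wells = 100L, grid_rows = 10L, grid_cols = 10L,
         n_pieces = 2L, bead_loading_rate = 0.5,
         cell_loading_rate = 0.3, mean_transcripts_per_cell = 200,
         beadfree_depth = 10, n_genes_per_species = 40L,
         module_size = 8L, rng_seed = 42L),
    list(...))
  do.call(scope_config, args)
}

# 400-well device used by the shared end-to-end fixture
moderate_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_wells = 400L, grid_rows = 20L, grid_cols = 20L,
         n_pieces = 2L, bead_loading_rate = 0.6,
         cell_loading_rate = 0.3, mean_transcripts_per_cell = 300,
         n_genes_per_species = 60L, rng_seed = 7L),
    list(...))
  do.call(scope_config, args)
}

no_error_args <- function() {
  list(bit_flip_rate = 0, seq_error_rate = 0, crosstalk_rate = 0, snr = 50)
}

# one shared full-pipeline run reused across module tests
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(moderate_cfg())
    cache
  }
})

# the same device with every error rate at zero
shared_run0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(do.call(moderate_cfg, no_error_args()))
    }
    cache
  }
})

# render a standalone well image with cells at given offsets (monochrome)
render_test_well <- function(offsets, a, b = a / 1.25, theta = 0, amp = 1000,
                             size = 40L, irr = 0, noise_sd = 0) {
  img <- matrix(200, size, size)
  ctr <- size / 2
  a <- rep(a, length.out = nrow(offsets))
  b <- rep(b, length.out = nrow(offsets))
  theta <- rep(theta, length.out = nrow(offsets))
  amp <- rep(amp, length.out = nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    px <- scopelink:::cell_pixels(ctr + offsets$dy[i], ctr + offsets$dx[i],
                                  a[i], b[i], theta[i], 0, irr, size, size)
    idx <- cbind(px$y, px$x)
    img[idx] <- img[idx] + amp[i] * px$profile
  }
  if (noise_sd > 0) img <- img + rnorm(size * size, sd = noise_sd)
  img
}
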