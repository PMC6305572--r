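# Rendering constants: images are simulated in 16-bit counts with a fixed
# camera offset; peak signal over noise sd is set by cfg$snr.
.render <- list(background = 400, bead_amp = 600)

# integer pixel offsets of a filled disk of given radius
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# add `value` to img at (cy+dy, cx+dx), clipped to bounds; img modified copy
stamp_add <- function(img, cy, cx, offs, value) {
  y <- cy + offs$dy
  x <- cx + offs$dx
  keep <- y >= 1 & y <= nrow(img) & x >= 1 & x <= ncol(img)
  img[cbind(y[keep], x[keep])] <- img[cbind(y[keep], x[keep])] + value
  img
}

#' Simulate the hybridization image stack
#'
#' Renders the sequential fluorescence hybridization readout of the
#' optical barcodes: frame k shows a bright disk at the well centre of
#' every bead that carries OBO k, over Gaussian camera noise, with a
#' rigid per-frame translation (jitter) of up to `jitter_px` pixels. A
#' bead-stain reference frame in which every bead is visible is rendered
#' alongside; it is what separates an empty well from a bead whose code
#' happens to be all-zeros. With probability `bit_flip_rate` a bead's
#' rendered state in a frame is inverted (hybridization failure or
#' nonspecific binding); all flips and shifts are recorded as ground
#' truth.
#'
#' @param beads A `bead_set` from [simulate_beads()].
#' @param cfg A [scope_config()].
#' @return A list of class `hyb_stack`: `stack` (array rows x cols x
#'   n_obos), `reference` (matrix), `wells` (the [well_map()]), and
#'   `truth` (data.frames `flips` and `shifts`).
#' @export
simulate_hybridization_stack <- function(beads, cfg) {
  stopifnot(inherits(beads, "bead_set"))
  use_substream(cfg$rng_seed, "hyb")
  wm <- well_map(cfg)
  H <- cfg$grid_rows * cfg$well_pitch_px
  W <- cfg$grid_cols * cfg$well_pitch_px
  offs <- disk_offsets(cfg$bead_radius_px)
  noise_sd <- .render$bead_amp / cfg$snr
  cy <- round(wm$y[beads$well])
  cx <- round(wm$x[beads$well])

  bits <- code_bit_matrix(beads$code, cfg$n_obos)
  flips <- matrix(stats::runif(nrow(beads) * cfg$n_obos) < cfg$bit_flip_rate,
                  nrow = nrow(beads))
  shown <- xor(bits, flips)
  shifts <- data.frame(
    frame = seq_len(cfg$n_obos),
    dy = sample(seq(-cfg$jitter_px, cfg$jitter_px), cfg$n_obos, replace = TRUE),
    dx = sample(seq(-cfg$jitter_px, cfg$jitter_px), cfg$n_obos, replace = TRUE)
  )

  stack <- array(0, dim = c(H, W, cfg$n_obos))
  for (k in seq_len(cfg$n_obos)) {
    img <- matrix(.render$background, H, W)
    for (i in which(shown[, k])) {
      img <- stamp_add(img, cy[i] + shifts$dy[k], cx[i] + shifts$dx[k],
                       offs, .render$bead_amp)
    }
    stack[, , k] <- img + stats::rnorm(H * W, sd = noise_sd)
  }
  reference <- matrix(.render$background, H, W)
  for (i in seq_len(nrow(beads))) {
    reference <- stamp_add(reference, cy[i], cx[i], offs, .render$bead_amp)
  }
  reference <- reference + stats::rnorm(H * W, sd = noise_sd)

  flip_df <- data.frame(
    bead_id = rep(beads$bead_id, cfg$n_obos),
    frame = rep(seq_len(cfg$n_obos), each = nrow(beads)),
    flipped = as.vector(flips)
  )
  structure(list(stack = stack, reference = reference, wells = wm,
                 truth = list(flips = flip_df[flip_df$flipped, , drop = FALSE],
                              shifts = shifts)),
            class = "hyb_stack")
}

#' @export
print.hyb_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("Hybridization stack: %d frames of %d x %d px, %d wells, %d planted bit flips\n",
              d[3], d[1], d[2], nrow(x$wells), nrow(x$truth$flips)))
  invisible(x)
}
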