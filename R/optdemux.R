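# pixel bookkeeping for the well grid: linear-index matrices (wells x px)
# so per-well statistics over all wells are single indexing operations
well_pixel_index <- function(wells, H, W, offs) {
  cy <- round(wells$y)
  cx <- round(wells$x)
  dy <- offs$dy
  dx <- offs$dx
  y <- outer(cy, dy, "+")
  x <- outer(cx, dx, "+")
  y <- pmin(pmax(y, 1L), H)
  x <- pmin(pmax(x, 1L), W)
  (x - 1L) * H + y
}

annulus_offsets <- function(inner, outer_r) {
  r <- ceiling(outer_r)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  g[d2 > inner^2 & d2 <= outer_r^2, , drop = FALSE]
}

#' Detect bead-occupied microwells
#'
#' A well is called occupied when the mean intensity over a bead-sized
#' disk at its centre in the bead-stain reference frame exceeds the local
#' background (annulus around the well) by `k` standard errors of the
#' disk mean -- an empty-well noise model, so the false-positive rate is
#' controlled regardless of bead brightness.
#'
#' @param reference Reference-frame image matrix (all beads stained).
#' @param wells A [well_map()] data.frame.
#' @param bead_radius_px,well_radius_px,well_pitch_px Grid geometry.
#' @param k Detection threshold in standard errors (default 8).
#' @return Integer vector of occupied well indices.
#' @export
detect_beads <- function(reference, wells, bead_radius_px, well_radius_px,
                         well_pitch_px, k = 8) {
  H <- nrow(reference); W <- ncol(reference)
  disk <- disk_offsets(bead_radius_px)
  ann <- annulus_offsets(well_radius_px + 0.5, well_pitch_px / 2)
  di <- well_pixel_index(wells, H, W, disk)
  ai <- well_pixel_index(wells, H, W, ann)
  disk_mean <- rowMeans(matrix(reference[di], nrow = nrow(wells)))
  av <- matrix(reference[ai], nrow = nrow(wells))
  bg_mean <- rowMeans(av)
  bg_sd <- apply(av, 1L, stats::sd)
  z <- (disk_mean - bg_mean) / (bg_sd / sqrt(nrow(disk)))
  z[!is.finite(z)] <- -Inf
  wells$well[z > k]
}

#' Register hybridization frames to the reference
#'
#' Each frame is imaged after a fluid-handling cycle and can be rigidly
#' translated relative to the reference. Frames and reference are
#' binarised at background + 4 robust sd, and the integer shift maximising
#' the normalised overlap of the masks within `search_radius` is taken.
#' Frames whose peak overlap falls below `floor` are flagged (their bits
#' are later set ambiguous).
#'
#' @param stack Array `rows x cols x n_frames`.
#' @param reference Reference frame matrix.
#' @param search_radius Maximum shift searched, pixels (default 3).
#' @param floor Minimum acceptable peak overlap score (default 0.15).
#' @return data.frame `frame`, `dy`, `dx`, `score`, `ok`.
#' @export
register_frames <- function(stack, reference, search_radius = 3L, floor = 0.15) {
  ref_mask <- robust_mask(reference)
  shifts <- expand.grid(dy = -search_radius:search_radius,
                        dx = -search_radius:search_radius)
  out <- lapply(seq_len(dim(stack)[3]), function(k) {
    fm <- robust_mask(stack[, , k])
    sc <- vapply(seq_len(nrow(shifts)), function(s) {
      mask_overlap(ref_mask, fm, shifts$dy[s], shifts$dx[s])
    }, numeric(1))
    best <- which.max(sc)
    data.frame(frame = k, dy = shifts$dy[best], dx = shifts$dx[best],
               score = sc[best], ok = sc[best] >= floor)
  })
  do.call(rbind, out)
}

robust_mask <- function(img) {
  med <- stats::median(img)
  img > med + 4 * stats::mad(img)
}

# normalised overlap of ref[y, x] with frame[y + dy, x + dx]: the offset
# is the translation the frame content underwent, i.e. where to read the
# frame for a feature at reference position (y, x)
mask_overlap <- function(ref, frame, dy, dx) {
  H <- nrow(ref); W <- ncol(ref)
  y1 <- max(1, 1 - dy); y2 <- min(H, H - dy)
  x1 <- max(1, 1 - dx); x2 <- min(W, W - dx)
  if (y1 > y2 || x1 > x2) return(0)
  a <- ref[y1:y2, x1:x2]
  b <- frame[(y1:y2) + dy, (x1:x2) + dx]
  sa <- as.numeric(sum(a)); sb <- as.numeric(sum(b))
  if (sa == 0 || sb == 0) return(0)
  sum(a & b) / sqrt(sa * sb)
}

#' Extract per-well hybridization intensity profiles
#'
#' For each occupied well and each frame, the mean intensity over a
#' bead-sized disk at the registered well centre minus the median of the
#' surrounding annulus (local background). The same statistic on the
#' reference frame gives each well's bead-stain signal, used as the
#' absolute intensity scale by [call_codes()].
#'
#' @param stack,reference Images as in [register_frames()].
#' @param wells A [well_map()].
#' @param occupied Occupied well indices from [detect_beads()].
#' @param registration Output of [register_frames()].
#' @param bead_radius_px,well_radius_px,well_pitch_px Geometry.
#' @return A list of class `well_profiles`: `profiles` (wells x frames
#'   matrix), `ref_signal`, `occupied`, `registration`.
#' @export
extract_profiles <- function(stack, reference, wells, occupied, registration,
                             bead_radius_px, well_radius_px, well_pitch_px) {
  H <- nrow(reference); W <- ncol(reference)
  ww <- wells[match(occupied, wells$well), ]
  disk <- disk_offsets(bead_radius_px)
  ann <- annulus_offsets(well_radius_px + 0.5, well_pitch_px / 2)
  base_di <- well_pixel_index(ww, H, W, disk)
  base_ai <- well_pixel_index(ww, H, W, ann)

  prof <- matrix(NA_real_, nrow = nrow(ww), ncol = dim(stack)[3])
  for (k in seq_len(dim(stack)[3])) {
    img <- stack[, , k]
    sh <- registration[registration$frame == k, ]
    delta <- sh$dx * H + sh$dy
    di <- pmin(pmax(base_di + delta, 1L), H * W)
    ai <- pmin(pmax(base_ai + delta, 1L), H * W)
    dm <- rowMeans(matrix(img[di], nrow = nrow(ww)))
    bg <- apply(matrix(img[ai], nrow = nrow(ww)), 1L, stats::median)
    prof[, k] <- dm - bg
  }
  rm <- rowMeans(matrix(reference[base_di], nrow = nrow(ww)))
  rbg <- apply(matrix(reference[base_ai], nrow = nrow(ww)), 1L, stats::median)
  structure(list(profiles = prof, ref_signal = rm - rbg, occupied = occupied,
                 registration = registration),
            class = "well_profiles")
}

#' Exact two-class (Otsu) threshold of a numeric vector
#'
#' Maximises between-class variance over all cut points of the sorted
#' sample; the threshold is the midpoint of the optimal cut. Used to
#' split each hybridization frame's occupied-well intensities into
#' on/off classes, which is robust to per-cycle brightness drift.
#'
#' @param x Numeric vector (length >= 2).
#' @return The threshold value.
#' @export
otsu_threshold <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) return(xs[1])
  cs <- cumsum(xs)
  i <- seq_len(n - 1L)
  w1 <- i / n
  mu1 <- cs[i] / i
  mu2 <- (cs[n] - cs[i]) / (n - i)
  bcv <- w1 * (1 - w1) * (mu1 - mu2)^2
  k <- which.max(bcv)
  (xs[k] + xs[k + 1L]) / 2
}

#' Call optical barcodes from intensity profiles
#'
#' Per frame, occupied-well intensities are split into on/off classes by
#' [otsu_threshold()]. When the frame is effectively unimodal (all beads
#' on, or all off: class separation below `unimodal_frac` of the median
#' bead-stain signal) an absolute fallback threshold at half the median
#' bead-stain signal is used instead. Each bit's margin is its signed
#' distance from the threshold in units of the on/off class separation;
#' a call passes only if every bit clears `ambiguity_margin`, and bits
#' from frames that failed registration are forced ambiguous. Ambiguous
#' calls are deliberately not guessed: downstream they fail to link
#' rather than link wrongly.
#'
#' @param prof A `well_profiles` from [extract_profiles()].
#' @param ambiguity_margin Minimum |margin| for a pass call, as a
#'   fraction of the class separation (default 0.1).
#' @param unimodal_frac Separation (relative to median bead-stain signal)
#'   below which a frame is treated as unimodal (default 0.3).
#' @param wells Optional [well_map()] to annotate calls with piece labels.
#' @return A data.frame of class `optical_calls`: `well`, `piece` (if
#'   `wells` given), `code`, `bits`, `min_margin`, `flag`
#'   ("pass"/"ambiguous"); per-bit margins in `attr(, "margins")`.
#' @export
call_codes <- function(prof, ambiguity_margin = 0.1, unimodal_frac = 0.3,
                       wells = NULL) {
  stopifnot(inherits(prof, "well_profiles"))
  p <- prof$profiles
  n_obos <- ncol(p)
  ref_scale <- stats::median(prof$ref_signal)
  margins <- matrix(NA_real_, nrow(p), n_obos)
  on <- matrix(FALSE, nrow(p), n_obos)
  for (k in seq_len(n_obos)) {
    x <- p[, k]
    thr <- otsu_threshold(x)
    hi <- x > thr
    sep <- if (any(hi) && any(!hi)) mean(x[hi]) - mean(x[!hi]) else 0
    if (sep < unimodal_frac * ref_scale) {
      thr <- 0.5 * ref_scale
      sep <- ref_scale
      hi <- x > thr
    }
    on[, k] <- hi
    margins[, k] <- (x - thr) / sep
  }
  reg_ok <- prof$registration$ok[seq_len(n_obos)]
  margins[, !reg_ok] <- 0  # unregistered frames carry no evidence
  code <- as.integer(on %*% 2^(seq_len(n_obos) - 1L))
  min_margin <- apply(abs(margins), 1L, min)
  out <- data.frame(
    well = prof$occupied,
    code = code,
    bits = code_to_bits(code, n_obos),
    min_margin = min_margin,
    flag = ifelse(min_margin >= ambiguity_margin, "pass", "ambiguous")
  )
  if (!is.null(wells)) {
    out$piece <- wells$piece[match(out$well, wells$well)]
    out <- out[, c("well", "piece", "code", "bits", "min_margin", "flag")]
  }
  attr(out, "margins") <- margins
  attr(out, "n_obos") <- n_obos
  class(out) <- c("optical_calls", class(out))
  out
}

#' Optical demultiplexing of a hybridization stack
#'
#' End-to-end wrapper: detect occupied wells on the reference frame,
#' register every hybridization frame, extract background-subtracted
#' well intensity profiles, and call each bead's optical barcode.
#'
#' @param hyb A `hyb_stack` (from [simulate_hybridization_stack()]) or a
#'   list with elements `stack`, `reference`, `wells`.
#' @param cfg A [scope_config()] supplying the grid geometry.
#' @param ... Passed to [call_codes()].
#' @return An `optical_calls` data.frame (see [call_codes()]).
#' @export
demux_stack <- function(hyb, cfg, ...) {
  occ <- detect_beads(hyb$reference, hyb$wells, cfg$bead_radius_px,
                      cfg$well_radius_px, cfg$well_pitch_px)
  reg <- register_frames(hyb$stack, hyb$reference,
                         search_radius = max(3L, cfg$jitter_px + 1L))
  prof <- extract_profiles(hyb$stack, hyb$reference, hyb$wells, occ, reg,
                           cfg$bead_radius_px, cfg$well_radius_px,
                           cfg$well_pitch_px)
  call_codes(prof, wells = hyb$wells, ...)
}

#' @export
print.optical_calls <- function(x, ...) {
  cat(sprintf("Optical calls: %d occupied wells, %d pass / %d ambiguous\n",
              nrow(x), sum(x$flag == "pass"), sum(x$flag == "ambiguous")))
  invisible(x)
}
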