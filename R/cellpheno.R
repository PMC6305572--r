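#' Names of the 19 imaging features
#'
#' Fixed feature panel covering cell size (area, perimeter, equivalent
#' diameter, axis lengths, convex area), shape (aspect ratio,
#' eccentricity, circularity, solidity, extent) and intensity
#' distribution (total/mean/sd, skewness, kurtosis, entropy, radial
#' moment, edge-to-centre ratio).
#'
#' @return Character vector of length 19.
#' @export
imaging_feature_names <- function() {
  c("area", "perimeter", "equiv_diameter", "major_axis", "minor_axis",
    "aspect_ratio", "eccentricity", "circularity", "solidity", "extent",
    "convex_area", "int_total", "int_mean", "int_sd", "int_skew",
    "int_kurtosis", "int_entropy", "radial_moment", "edge_center_ratio")
}

#' Segment cells in microwell live-cell images
#'
#' The image is Gaussian-smoothed (suppressing pixel noise), then per
#' well an adaptive foreground threshold is set at the local background
#' (annulus median) plus the larger of `k` robust background sd and
#' `peak_frac` of the well's peak signal above background -- so dim cells
#' are captured whole while bright cells are not over-grown. Connected
#' components (8-connectivity, via EBImage) smaller than `min_area`
#' pixels are discarded.
#'
#' @param image Live-cell image matrix (typically the monochrome channel
#'   sum).
#' @param wells A [well_map()].
#' @param well_radius_px,well_pitch_px Grid geometry.
#' @param k Threshold in robust background sd (default 3.5).
#' @param min_area Minimum object area in pixels (default 5).
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels (default 0.8;
#'   0 disables).
#' @param peak_frac Adaptive threshold as a fraction of the well's peak
#'   signal over background (default 0.25).
#' @return Named list (one element per well with >= 1 object) of
#'   data.frames `y`, `x`, `label` giving global pixel coordinates of
#'   each labelled object.
#' @export
segment_wells <- function(image, wells, well_radius_px, well_pitch_px,
                          k = 3.5, min_area = 5L, smooth_sigma = 0.8,
                          peak_frac = 0.25) {
  if (smooth_sigma > 0) {
    image <- EBImage::gblur(image, sigma = smooth_sigma)
  }
  H <- nrow(image); W <- ncol(image)
  half <- floor(well_pitch_px / 2) - 1L
  ann <- annulus_offsets(well_radius_px + 0.5, well_pitch_px / 2)
  ai <- well_pixel_index(wells, H, W, ann)
  av <- matrix(image[ai], nrow = nrow(wells))
  bg <- apply(av, 1L, stats::median)
  noise <- apply(av, 1L, stats::mad)

  out <- list()
  for (i in seq_len(nrow(wells))) {
    cy <- round(wells$y[i]); cx <- round(wells$x[i])
    ys <- max(1, cy - half):min(H, cy + half)
    xs <- max(1, cx - half):min(W, cx + half)
    crop <- image[ys, xs, drop = FALSE]
    fg <- crop > bg[i] + max(k * noise[i],
                             peak_frac * (max(crop) - bg[i]))
    if (!any(fg)) next
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_area)
    if (length(keep) == 0L) next
    px <- which(matrix(lab %in% keep, nrow(crop), ncol(crop)), arr.ind = TRUE)
    lbl <- lab[px]
    out[[as.character(wells$well[i])]] <- data.frame(
      y = ys[px[, 1]], x = xs[px[, 2]],
      label = match(lbl, keep))
  }
  out
}

#' Compute the 19 imaging features of a segmented object mask
#'
#' Features are computed on the union mask of all objects in the well
#' (per-well microscopy granularity); the object count is carried
#' separately. Size features are in pixel units; the perimeter uses a
#' Crofton-style correction (pi/4 times the count of exposed pixel
#' edges), so a digital disk has circularity close to 1. Second-moment
#' axis lengths include the 1/12 pixel-variance correction. Intensity
#' features use background-subtracted values: total/mean/sd scale with
#' illumination, while skewness, kurtosis, entropy, radial moment and
#' edge-to-centre ratio are illumination-invariant.
#'
#' @param mask data.frame with pixel coordinates `y`, `x`.
#' @param intensity Numeric vector of background-subtracted intensities,
#'   one per mask pixel.
#' @return Named numeric vector of length 19 (see
#'   [imaging_feature_names()]).
#' @export
compute_features <- function(mask, intensity) {
  if (is.null(mask) || nrow(mask) == 0L) stop("empty mask")
  stopifnot(length(intensity) == nrow(mask))
  y <- mask$y; x <- mask$x
  n <- length(y)
  key <- (x + 1e6) * 4e6 + y
  inset <- function(yy, xx) ((xx + 1e6) * 4e6 + yy) %in% key
  exposed <- (!inset(y - 1L, x)) + (!inset(y + 1L, x)) +
    (!inset(y, x - 1L)) + (!inset(y, x + 1L))
  perimeter <- (pi / 4) * sum(exposed)

  area <- n
  equiv_diameter <- 2 * sqrt(area / pi)
  mu_y <- mean(y); mu_x <- mean(x)
  cyy <- mean((y - mu_y)^2) + 1 / 12
  cxx <- mean((x - mu_x)^2) + 1 / 12
  cxy <- mean((y - mu_y) * (x - mu_x))
  tr <- cyy + cxx
  det_ <- cyy * cxx - cxy^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det_, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det_, 0))
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  aspect <- if (minor > 0) major / minor else NA_real_
  ecc <- if (l1 > 0) sqrt(1 - max(l2, 0) / l1) else 0
  circularity <- if (perimeter > 0) 4 * pi * area / perimeter^2 else NA_real_

  hull <- convex_hull_area(y, x)
  solidity <- area / hull
  extent <- area / ((max(y) - min(y) + 1) * (max(x) - min(x) + 1))

  v <- intensity
  tot <- sum(v)
  mn <- mean(v)
  sdv <- stats::sd(v)
  if (n < 2L || !is.finite(sdv)) sdv <- 0
  skew <- if (sdv > 0) mean((v - mn)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((v - mn)^4) / sdv^4 else 0
  rng <- range(v)
  ent <- if (diff(rng) > 0) {
    p <- tabulate(pmin(16L, 1L + floor(16 * (v - rng[1]) / diff(rng))), 16L) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  } else 0

  r <- sqrt((y - mu_y)^2 + (x - mu_x)^2)
  r_eq <- equiv_diameter / 2
  w <- pmax(v, 0)
  radial <- if (sum(w) > 0 && r_eq > 0) sum(w * r) / (sum(w) * r_eq)
            else mean(r) / max(r_eq, 1)
  rmax <- max(r)
  if (rmax > 0) {
    edge <- r > 0.6 * rmax
    e_m <- mean(v[edge]); c_m <- mean(v[!edge])
    ecr <- if (is.finite(c_m) && abs(c_m) > 1e-9 && any(edge) && any(!edge))
      e_m / c_m else 1
  } else ecr <- 1

  out <- c(area = area, perimeter = perimeter,
           equiv_diameter = equiv_diameter, major_axis = major,
           minor_axis = minor, aspect_ratio = aspect, eccentricity = ecc,
           circularity = circularity, solidity = solidity, extent = extent,
           convex_area = hull, int_total = tot, int_mean = mn, int_sd = sdv,
           int_skew = skew, int_kurtosis = kurt, int_entropy = ent,
           radial_moment = radial, edge_center_ratio = ecr)
  out[imaging_feature_names()]
}

# pixel-count area of the convex hull of lattice points (Pick's theorem:
# interior + boundary lattice points = A + B/2 + 1)
convex_hull_area <- function(y, x) {
  if (length(y) <= 2L) return(length(y))
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  nxt <- c(2:m, 1L)
  A <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
  B <- sum(mapply(function(dx, dy) {
    if (dx == 0 && dy == 0) 0 else gcd2(abs(dx), abs(dy))
  }, hx[nxt] - hx, hy[nxt] - hy))
  max(A + B / 2 + 1, length(y))
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Species label call from two-channel dye intensities
#'
#' The call is the channel with the larger background-subtracted total;
#' "mixed" when both channels exceed `threshold` and their ratio lies in
#' `band`; "none" when neither clears `threshold`.
#'
#' @param ch1,ch2 Background-subtracted channel totals (vectorised).
#' @param threshold Minimum total for a channel to count as labelled.
#' @param band Length-2 ratio band (ch1/ch2) called mixed, default
#'   `c(0.5, 2)`.
#' @param species Names reported for channel-1 and channel-2 calls.
#' @return Character vector: species name, "mixed", or "none".
#' @export
call_species_label <- function(ch1, ch2, threshold, band = c(0.5, 2),
                               species = c("speciesA", "speciesB")) {
  ratio <- ch1 / pmax(ch2, 1e-9)
  out <- ifelse(ch1 >= ch2, species[1], species[2])
  out[ch1 > threshold & ch2 > threshold &
        ratio >= band[1] & ratio <= band[2]] <- "mixed"
  out[ch1 <= threshold & ch2 <= threshold] <- "none"
  out
}

#' Monochrome multiplet flag
#'
#' Automated surrogate for manual inspection of single-channel images: a
#' well is flagged as a candidate multiplet when more than one object was
#' segmented, the union mask is larger than `area_threshold`, or its
#' solidity falls below `min_solidity` (two touching cells form a
#' non-convex blob).
#'
#' @param n_objects Segmented object count.
#' @param area Union mask area (pixels).
#' @param solidity Union mask solidity.
#' @param area_threshold Area above which a single blob is suspect.
#' @param min_solidity Solidity below which a blob is suspect (default 0.8).
#' @return Logical vector.
#' @export
detect_multiplet_monochrome <- function(n_objects, area, solidity,
                                        area_threshold, min_solidity = 0.8) {
  n_objects >= 2L | area > area_threshold | solidity < min_solidity
}

#' Expected single-cell mask area under a configuration
#'
#' Median ellipse area implied by the configured cell geometry; used to
#' default the monochrome multiplet area threshold.
#'
#' @param cfg A [scope_config()].
#' @return Area in pixels.
#' @export
expected_cell_area <- function(cfg) {
  pi * cfg$cell_radius_px^2 / 1.25
}

#' Per-well imaging records
#'
#' Runs segmentation on the monochrome image, computes the 19 features of
#' each occupied well's union mask, reads both dye channels, calls the
#' imaging species label, and flags candidate multiplets from the
#' monochrome data alone.
#'
#' @param live List with image matrices `ch1`, `ch2`, `mono` (as produced
#'   by [simulate_cells_and_expression()]).
#' @param wells A [well_map()].
#' @param cfg A [scope_config()] (geometry, dye scale).
#' @param label_threshold Channel total above which a dye is considered
#'   present; default 15% of the expected single-cell on-channel total.
#' @param mixed_band Ratio band for the "mixed" two-colour call.
#' @param area_factor Monochrome multiplet area threshold, as a multiple
#'   of [expected_cell_area()] (default 2.2).
#' @param min_solidity Passed to [detect_multiplet_monochrome()].
#' @return A data.frame of class `imaging_records`: `well`, `piece`,
#'   `n_objects`, the 19 feature columns, `ch1_total`, `ch2_total`,
#'   `species_label`, `multiplet_mono`, `multiplet_two_color`.
#' @export
imaging_records <- function(live, wells, cfg,
                            label_threshold = 0.15 * cfg$dye_on_mean *
                              expected_cell_area(cfg),
                            mixed_band = c(0.5, 2),
                            area_factor = 2.2, min_solidity = 0.8) {
  segs <- segment_wells(live$mono, wells, cfg$well_radius_px,
                        cfg$well_pitch_px)
  if (length(segs) == 0L) {
    return(empty_imaging_records())
  }
  H <- nrow(live$mono)
  ann <- annulus_offsets(cfg$well_radius_px + 0.5, cfg$well_pitch_px / 2)
  widx <- match(as.integer(names(segs)), wells$well)
  ai <- well_pixel_index(wells[widx, , drop = FALSE], H, ncol(live$mono), ann)

  rows <- lapply(seq_along(segs), function(i) {
    m <- segs[[i]]
    lin <- (m$x - 1L) * H + m$y
    abg <- ai[i, ]
    f <- compute_features(m, live$mono[lin] - stats::median(live$mono[abg]))
    ch1 <- sum(live$ch1[lin] - stats::median(live$ch1[abg]))
    ch2 <- sum(live$ch2[lin] - stats::median(live$ch2[abg]))
    c(f, n_objects = max(m$label), ch1_total = ch1, ch2_total = ch2)
  })
  rec <- as.data.frame(do.call(rbind, rows))
  rec <- cbind(well = as.integer(names(segs)),
               piece = wells$piece[widx], rec)
  rec$species_label <- call_species_label(
    rec$ch1_total, rec$ch2_total, label_threshold, mixed_band,
    species = if (!is.null(cfg$species_fractions))
      names(cfg$species_fractions) else c("speciesA", "speciesB"))
  rec$multiplet_mono <- detect_multiplet_monochrome(
    rec$n_objects, rec$area, rec$solidity,
    area_factor * expected_cell_area(cfg), min_solidity)
  rec$multiplet_two_color <- rec$species_label == "mixed"
  class(rec) <- c("imaging_records", class(rec))
  rec
}

empty_imaging_records <- function() {
  cols <- c("well", "piece", imaging_feature_names(), "n_objects",
            "ch1_total", "ch2_total")
  rec <- as.data.frame(matrix(numeric(0), ncol = length(cols),
                              dimnames = list(NULL, cols)))
  rec$species_label <- character(0)
  rec$multiplet_mono <- logical(0)
  rec$multiplet_two_color <- logical(0)
  class(rec) <- c("imaging_records", class(rec))
  rec
}

#' @export
print.imaging_records <- function(x, ...) {
  cat(sprintf("Imaging records: %d occupied wells, %d flagged multiplet (mono), labels: %s\n",
              nrow(x), sum(x$multiplet_mono),
              paste(names(table(x$species_label)), table(x$species_label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
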