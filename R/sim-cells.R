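#' Simulate cell loading, live-cell images, and expression counts
#'
#' Generates the biological side of a two-species mixing experiment:
#'
#' * wells receive Poisson(`cell_loading_rate`) cells, with the
#'   probability of multi-cell wells scaled by `doublet_bias` (see
#'   [planted_doublet_rate()]);
#' * each cell gets a species (drawn from `species_fractions`), an
#'   elliptical geometry with lognormal size and aspect variation plus a
#'   sinusoidal boundary perturbation, and per-channel live-stain dye
#'   brightness keyed to its species (channel 1 = first species);
#' * two-channel live-cell images are rendered on the well grid with
#'   Gaussian camera noise (a monochrome view is the channel sum);
#' * per-cell transcript counts are drawn from species-specific gene
#'   panels (multinomial over lognormal gene weights, total UMIs Poisson
#'   around `mean_transcripts_per_cell` times a lognormal size factor).
#'   A planted module of `module_size` genes in the first species' panel
#'   has its expected expression scaled by (cell area / mean area)^
#'   `module_strength`, giving downstream phenotype-expression analyses a
#'   recoverable signal;
#' * counts are attributed to the well's bead barcode; a fraction
#'   `crosstalk_rate` of UMIs is reassigned to a random other barcode.
#'
#' Cells in wells without a bead are imaged but yield no expression;
#' beads without a cell yield (near-)zero counts. Both facts are recorded
#' in the ground truth so every downstream module can be scored without
#' re-simulation.
#'
#' @param beads A `bead_set` from [simulate_beads()].
#' @param cfg A [scope_config()].
#' @return A list of class `cell_sim`: `cells` (per-cell geometry, species,
#'   rendered pixel area, dye amplitudes, barcode), `live` (list with
#'   `ch1`, `ch2`, `mono` image matrices), `counts` (sparse genes x
#'   barcodes matrix over all bead barcodes), `gene_ref` (gene, species,
#'   module flag, 20-nt tag sequence standing in for the aligned
#'   transcript), `wells_truth` (per-well cell count, bead, species
#'   composition), and `n_crosstalk_umis`.
#' @export
simulate_cells_and_expression <- function(beads, cfg) {
  stopifnot(inherits(beads, "bead_set"))
  use_substream(cfg$rng_seed, "cells")
  wm <- well_map(cfg)
  sp_names <- names(cfg$species_fractions)

  # --- well occupancy with biased multi-cell probability ---------------
  pm <- cell_count_pmf(cfg$cell_loading_rate, cfg$doublet_bias)
  u <- stats::runif(cfg$n_wells)
  n_cells <- integer(cfg$n_wells)
  n_cells[u >= pm$p0 & u < pm$p0 + pm$p1] <- 1L
  multi <- which(u >= pm$p0 + pm$p1)
  if (length(multi)) {
    kmax <- 9L
    pk <- stats::dpois(2:kmax, cfg$cell_loading_rate)
    n_cells[multi] <- sample(2:kmax, length(multi), replace = TRUE,
                             prob = pk / sum(pk))
  }

  well_of_cell <- rep(seq_len(cfg$n_wells), n_cells)
  n <- length(well_of_cell)
  species <- sample(sp_names, n, replace = TRUE, prob = cfg$species_fractions)

  # --- geometry and dyes ----------------------------------------------
  a <- cfg$cell_radius_px * exp(stats::rnorm(n, sd = cfg$cell_radius_sdlog))
  aspect <- 1.25 * exp(stats::rnorm(n, sd = cfg$cell_aspect_sdlog))
  b <- a / aspect
  theta <- stats::runif(n, 0, pi)
  phase <- stats::runif(n, 0, 2 * pi)
  r_off <- sqrt(stats::runif(n)) * pmax(0, cfg$well_radius_px - b)
  t_off <- stats::runif(n, 0, 2 * pi)
  cy <- wm$y[well_of_cell] + r_off * sin(t_off)
  cx <- wm$x[well_of_cell] + r_off * cos(t_off)
  # cells are solid: in multi-cell wells, resample positions until centres
  # are separated (soft exclusion; co-occupying wells can still touch)
  for (w in unique(well_of_cell[duplicated(well_of_cell)])) {
    idx <- which(well_of_cell == w)
    for (try in 1:20) {
      dmat <- as.matrix(stats::dist(cbind(cx[idx], cy[idx])))
      req <- 0.8 * outer(b[idx], b[idx], "+")
      if (all(dmat[upper.tri(dmat)] >= req[upper.tri(req)])) break
      r2 <- sqrt(stats::runif(length(idx))) *
        pmax(0, cfg$well_radius_px - b[idx])
      t2 <- stats::runif(length(idx), 0, 2 * pi)
      cy[idx] <- wm$y[w] + r2 * sin(t2)
      cx[idx] <- wm$x[w] + r2 * cos(t2)
    }
  }
  dye_on <- cfg$dye_on_mean * exp(stats::rnorm(n, sd = cfg$dye_sdlog))
  dye_off <- cfg$dye_off_mean * exp(stats::rnorm(n, sd = cfg$dye_sdlog))

  # --- render the two live-stain channels -----------------------------
  H <- cfg$grid_rows * cfg$well_pitch_px
  W <- cfg$grid_cols * cfg$well_pitch_px
  bg <- 200
  ch1 <- matrix(bg, H, W)
  ch2 <- matrix(bg, H, W)
  area_px <- numeric(n)
  for (i in seq_len(n)) {
    px <- cell_pixels(cy[i], cx[i], a[i], b[i], theta[i], phase[i],
                      cfg$cell_irregularity, H, W)
    area_px[i] <- nrow(px)
    if (nrow(px) == 0L) next
    idx <- cbind(px$y, px$x)
    amp1 <- if (species[i] == sp_names[1]) dye_on[i] else dye_off[i]
    amp2 <- if (species[i] == sp_names[1]) dye_off[i] else dye_on[i]
    ch1[idx] <- ch1[idx] + amp1 * px$profile
    ch2[idx] <- ch2[idx] + amp2 * px$profile
  }
  noise_sd <- cfg$dye_on_mean / cfg$snr
  ch1 <- ch1 + stats::rnorm(H * W, sd = noise_sd)
  ch2 <- ch2 + stats::rnorm(H * W, sd = noise_sd)

  cells <- data.frame(
    cell_id = seq_len(n), well = well_of_cell, species = species,
    a = a, b = b, theta = theta, area_px = area_px,
    dye_ch1 = ifelse(species == sp_names[1], dye_on, dye_off),
    dye_ch2 = ifelse(species == sp_names[1], dye_off, dye_on)
  )
  bead_of_well <- rep(NA_integer_, cfg$n_wells)
  bead_of_well[beads$well] <- beads$bead_id
  cells$bead_id <- bead_of_well[cells$well]
  cells$sequencing_barcode <- beads$sequencing_barcode[cells$bead_id]

  # --- gene panels and per-cell counts --------------------------------
  gene_ref <- make_gene_panels(cfg, sp_names)
  base_w <- exp(stats::rnorm(nrow(gene_ref), sd = 1))
  sf <- exp(stats::rnorm(nrow(cells), sd = cfg$size_factor_sdlog) -
              cfg$size_factor_sdlog^2 / 2)
  cells$total_umis <- stats::rpois(nrow(cells),
                                   cfg$mean_transcripts_per_cell * sf)
  counts_dt <- draw_cell_counts(cells, gene_ref, base_w, cfg)
  amb_dt <- ambient_counts(beads$sequencing_barcode, gene_ref, base_w, cfg)
  counts_dt <- data.table::rbindlist(list(counts_dt, amb_dt))
  counts_dt <- counts_dt[, list(n = sum(n)), by = c("sequencing_barcode", "gene")]
  xt <- apply_crosstalk(counts_dt, beads$sequencing_barcode, cfg$crosstalk_rate)

  counts <- counts_to_matrix(xt$counts, gene_ref$gene, beads$sequencing_barcode)

  wells_truth <- data.frame(well = wm$well, piece = wm$piece,
                            bead_id = bead_of_well,
                            n_cells = n_cells)
  wells_truth$species_mix <- vapply(seq_len(cfg$n_wells), function(w) {
    sp <- cells$species[cells$well == w]
    if (length(sp) == 0L) "" else paste(sort(unique(sp)), collapse = "+")
  }, character(1))

  structure(list(cells = cells,
                 live = list(ch1 = ch1, ch2 = ch2, mono = ch1 + ch2 - bg),
                 counts = counts, gene_ref = gene_ref,
                 wells_truth = wells_truth,
                 n_crosstalk_umis = xt$n_moved,
                 species_names = sp_names),
            class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  cat(sprintf("Simulated cells: %d cells in %d wells; %d genes; %.0f UMIs total (%d cross-talk)\n",
              nrow(x$cells), sum(x$wells_truth$n_cells > 0), nrow(x$gene_ref),
              sum(x$counts), x$n_crosstalk_umis))
  invisible(x)
}

# pixels of an irregular ellipse clipped to the image; profile is a gentle
# centre-to-edge intensity falloff so intensity-distribution features are
# not degenerate
cell_pixels <- function(cy, cx, a, b, theta, phase, irr, H, W) {
  r <- ceiling(a * (1 + irr) + 1)
  ys <- max(1, round(cy) - r):min(H, round(cy) + r)
  xs <- max(1, round(cx) - r):min(W, round(cx) + r)
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy
  dx <- g$x - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  re <- sqrt((u / a)^2 + (v / b)^2)
  s <- 1 + irr * sin(3 * atan2(v, u) + phase)
  keep <- re <= s
  out <- g[keep, , drop = FALSE]
  out$profile <- 1 - 0.3 * pmin(re[keep] / s[keep], 1)
  out
}

make_gene_panels <- function(cfg, sp_names) {
  ng <- cfg$n_genes_per_species
  gene <- c(sprintf("%s_g%03d", sp_names[1], seq_len(ng)),
            sprintf("%s_g%03d", sp_names[2], seq_len(ng)))
  species <- rep(sp_names, each = ng)
  module <- logical(2L * ng)
  module[seq_len(min(cfg$module_size, ng))] <- TRUE
  data.frame(gene = gene, species = species, module = module,
             tag = random_dna(2L * ng, 20L, unique_seqs = TRUE))
}

# multinomial transcript counts per cell; module genes' weights scale with
# relative cell area
draw_cell_counts <- function(cells, gene_ref, base_w, cfg) {
  names(base_w) <- gene_ref$gene
  totals <- cells$total_umis
  mean_area <- mean(cells$area_px[cells$area_px > 0])
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (is.na(cells$sequencing_barcode[i]) || totals[i] == 0L) next
    panel <- gene_ref$species == cells$species[i]
    w <- base_w[panel]
    mod <- gene_ref$module[panel]
    if (any(mod) && cfg$module_strength != 0 && cells$area_px[i] > 0) {
      w[mod] <- w[mod] * (cells$area_px[i] / mean_area)^cfg$module_strength
    }
    cnt <- as.integer(stats::rmultinom(1, totals[i], w))
    nz <- cnt > 0L
    rows[[i]] <- data.frame(sequencing_barcode = cells$sequencing_barcode[i],
                            gene = gene_ref$gene[panel][nz], n = cnt[nz])
  }
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(sequencing_barcode = character(0),
                                  gene = character(0), n = integer(0)))
  }
  dt[, list(n = sum(n)), by = c("sequencing_barcode", "gene")]
}

# ambient (cell-free) capture: every bead draws Poisson UMIs from the
# species-weighted pooled gene distribution
ambient_counts <- function(barcodes, gene_ref, base_w, cfg) {
  if (cfg$ambient_umis_per_bead <= 0) {
    return(data.table::data.table(sequencing_barcode = character(0),
                                  gene = character(0), n = integer(0)))
  }
  frac <- cfg$species_fractions[match(gene_ref$species,
                                      names(cfg$species_fractions))]
  w <- base_w * as.numeric(frac)
  totals <- stats::rpois(length(barcodes), cfg$ambient_umis_per_bead)
  rows <- lapply(which(totals > 0L), function(i) {
    cnt <- as.integer(stats::rmultinom(1, totals[i], w))
    nz <- cnt > 0L
    data.frame(sequencing_barcode = barcodes[i],
               gene = gene_ref$gene[nz], n = cnt[nz])
  })
  data.table::rbindlist(rows)
}

apply_crosstalk <- function(counts_dt, all_barcodes, rate) {
  if (nrow(counts_dt) == 0L || rate <= 0) {
    return(list(counts = counts_dt, n_moved = 0L))
  }
  moved <- stats::rbinom(nrow(counts_dt), counts_dt$n, rate)
  n_moved <- sum(moved)
  counts_dt$n <- counts_dt$n - moved
  if (n_moved > 0L) {
    dest <- sample(all_barcodes, n_moved, replace = TRUE)
    extra <- data.table::data.table(
      sequencing_barcode = dest,
      gene = rep(counts_dt$gene, moved), n = 1L)
    counts_dt <- data.table::rbindlist(list(counts_dt, extra))
  }
  counts_dt <- counts_dt[counts_dt$n > 0L, ]
  out <- counts_dt[, list(n = sum(n)), by = c("sequencing_barcode", "gene")]
  list(counts = out, n_moved = n_moved)
}

counts_to_matrix <- function(counts_dt, genes, barcodes) {
  m <- Matrix::sparseMatrix(
    i = match(counts_dt$gene, genes),
    j = match(counts_dt$sequencing_barcode, barcodes),
    x = counts_dt$n,
    dims = c(length(genes), length(barcodes)),
    dimnames = list(genes, barcodes))
  methods::as(m, "CsparseMatrix")
}

#' Expand expression counts into barcoded scRNA-Seq reads
#'
#' Each UMI becomes `1 + Poisson(reads_per_umi - 1)` reads of structure
#' `sequencing_barcode | UMI | 20-nt gene tag`, with per-base substitution
#' errors at `seq_error_rate`. Reads are grouped by the array piece of the
#' barcode's bead (pieces are library-prepped and indexed separately).
#'
#' @param sim A `cell_sim` from [simulate_cells_and_expression()].
#' @param beads The matching `bead_set`.
#' @param cfg A [scope_config()].
#' @param dir Optional directory; writes one `piece_XX.fastq` per piece.
#' @return Invisibly, a named list (`piece_01`, ...) of data.frames with
#'   columns `header`, `seq`.
#' @export
simulate_expression_reads <- function(sim, beads, cfg, dir = NULL) {
  stopifnot(inherits(sim, "cell_sim"))
  use_substream(cfg$rng_seed, "screads")
  counts <- sim$counts
  dt <- data.table::as.data.table(Matrix::summary(counts))
  piece_of_bc <- beads$piece[match(colnames(counts), beads$sequencing_barcode)]
  tag_of_gene <- sim$gene_ref$tag[match(rownames(counts), sim$gene_ref$gene)]

  n_umi <- sum(dt$x)
  bc_idx <- rep(dt$j, dt$x)
  gene_idx <- rep(dt$i, dt$x)
  umis <- random_dna(n_umi, cfg$umi_length)
  nreads <- 1L + stats::rpois(n_umi, max(cfg$reads_per_umi - 1, 0))
  rix <- rep(seq_len(n_umi), nreads)
  seqs <- paste0(colnames(counts)[bc_idx][rix], umis[rix],
                 tag_of_gene[gene_idx][rix])
  seqs <- mutate_dna(seqs, cfg$seq_error_rate)
  piece <- piece_of_bc[bc_idx][rix]
  hdr <- sprintf("sc:%d piece=%02d", seq_along(rix), piece)

  out <- lapply(sort(unique(piece)), function(p) {
    sel <- piece == p
    data.frame(header = hdr[sel], seq = seqs[sel])
  })
  names(out) <- sprintf("piece_%02d", sort(unique(piece)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_fastq(out[[nm]]$header, out[[nm]]$seq,
                  file.path(dir, paste0(nm, ".fastq")))
    }
  }
  invisible(out)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running every generator stage off one seed:
#' beads, bead-free pools, hybridization stack, cells + live images +
#' expression counts.
#'
#' @param cfg A [scope_config()].
#' @param reads Also expand expression counts into reads? (FASTQ-level
#'   processing is the slow path; count-level consumers can skip it.)
#' @return A list of class `scope_sim` with elements `cfg`, `beads`,
#'   `beadfree`, `hyb`, `cells`, and optionally `screads`.
#' @export
simulate_experiment <- function(cfg, reads = TRUE) {
  beads <- simulate_beads(cfg)
  beadfree <- simulate_beadfree_reads(beads, cfg)
  hyb <- simulate_hybridization_stack(beads, cfg)
  cells <- simulate_cells_and_expression(beads, cfg)
  out <- list(cfg = cfg, beads = beads, beadfree = beadfree, hyb = hyb,
              cells = cells)
  if (reads) out$screads <- simulate_expression_reads(cells, beads, cfg)
  class(out) <- "scope_sim"
  out
}

#' @export
print.scope_sim <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d beads, %d cells, %d-frame stack, seed %d\n",
              nrow(x$beads), nrow(x$cells$cells), x$cfg$n_obos, x$cfg$rng_seed))
  invisible(x)
}
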