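#' Experiment configuration
#'
#' Bundles every parameter of a dual-barcoded microwell experiment: the
#' optical barcode design (how many optical barcode oligonucleotides, OBOs,
#' and how many split-pool ligation cycles distribute them), the device
#' geometry (number of microwells, grid layout, pixel geometry of the
#' rendered images), loading statistics for cells and beads, and all error
#' rates of the synthetic-data generator.
#'
#' Defaults reproduce the reference device design: 12 OBOs attached over 2
#' split-pool ligation cycles (6 OBOs per cycle, so the optical codespace is
#' 2^12 = 4096), a 30,500-microwell array cut into 10 pieces for separately
#' indexed library preparation.
#'
#' @param n_obos Number of optical barcode oligonucleotides (bits of the
#'   optical code).
#' @param n_split_cycles Number of split-pool ligation cycles. Each cycle
#'   owns `bits_per_cycle` dedicated OBOs and assigns each bead a uniformly
#'   random subset of them (the subset is the pool identity).
#' @param bits_per_cycle OBOs per cycle; must satisfy
#'   `n_obos == n_split_cycles * bits_per_cycle`. Default `n_obos / n_split_cycles`.
#' @param n_pieces Number of pieces the array is cut into before library
#'   prep; each piece gets its own sample index, multiplying the effective
#'   barcode capacity.
#' @param n_wells Number of microwells on the device.
#' @param sb_length Length (bases) of the cell-identifying sequencing barcode.
#' @param umi_length Length (bases) of the unique molecular identifier.
#' @param cell_loading_rate Mean cells per well (Poisson loading).
#' @param bead_loading_rate Mean beads per well, in `[0, 1]`; wells hold at
#'   most one bead (size exclusion), and `round(n_wells * bead_loading_rate)`
#'   beads are placed uniformly at random.
#' @param doublet_bias Multiplier on the probability that a well receives
#'   two or more cells (applied to the Poisson tail, renormalising the 0/1
#'   probabilities), so the planted multiplet rate is directly recoverable;
#'   see [planted_doublet_rate()].
#' @param species_fractions Named length-2 numeric, proportions of the two
#'   species in the cell suspension; must sum to 1.
#' @param crosstalk_rate Fraction of UMIs reassigned to a random other
#'   barcode (molecular cross-talk).
#' @param bit_flip_rate Per-bead, per-cycle probability that a hybridization
#'   bit is rendered inverted in the image stack.
#' @param seq_error_rate Per-base substitution probability in simulated reads.
#' @param rng_seed Integer seed; all generator randomness flows from it
#'   through named substreams (see [substream_seed()]).
#' @param beadfree_depth Mean reads per bead per ligation pool in the
#'   bead-free library (Poisson).
#' @param mean_transcripts_per_cell Mean unique transcripts (UMIs) captured
#'   per cell.
#' @param ambient_umis_per_bead Mean ambient (cell-free) UMIs captured by
#'   every bead, so each extracted bead's barcode is observed in its
#'   piece's library even when its well held no cell.
#' @param reads_per_umi Mean sequenced reads per UMI (Poisson, zero-truncated).
#' @param n_genes_per_species Genes in each species' expression panel.
#' @param module_size Number of genes in the planted size-correlated module
#'   (members of the first species' panel).
#' @param module_strength Coupling exponent between cell area and the
#'   module genes' expected expression (0 disables the planted signal).
#' @param well_pitch_px Centre-to-centre well spacing in rendered images
#'   (pixels).
#' @param well_radius_px Well radius (pixels).
#' @param bead_radius_px Rendered bead radius (pixels).
#' @param cell_radius_px Median cell semi-major axis (pixels).
#' @param cell_radius_sdlog Log-sd of cell size variation.
#' @param cell_aspect_sdlog Log-sd of the cell aspect ratio (median 1.25).
#' @param cell_irregularity Amplitude of the sinusoidal boundary
#'   perturbation of rendered cells (fraction of radius).
#' @param snr Signal-to-noise ratio of rendered images (peak signal over
#'   Gaussian noise sd).
#' @param jitter_px Maximum rigid per-frame translation (pixels) of
#'   hybridization frames relative to the reference frame.
#' @param grid_rows,grid_cols Well grid layout; defaults to a near-square
#'   grid holding `n_wells` wells.
#' @param dye_on_mean,dye_off_mean Mean per-pixel intensity of a cell's
#'   species-matched and species-mismatched live-stain channel.
#' @param dye_sdlog Log-sd of per-cell dye brightness variation.
#' @param size_factor_sdlog Log-sd of the per-cell library size factor.
#'
#' @return An object of class `scope_config` (a named list, validated).
#' @seealso [well_map()], [simulate_experiment()]
#' @export
scope_config <- function(n_obos = 12L,
                         n_split_cycles = 2L,
                         bits_per_cycle = NULL,
                         n_pieces = 10L,
                         n_wells = 30500L,
                         sb_length = 12L,
                         umi_length = 8L,
                         cell_loading_rate = 0.15,
                         bead_loading_rate = 0.6,
                         doublet_bias = 1,
                         species_fractions = c(human = 0.6, mouse = 0.4),
                         crosstalk_rate = 0.01,
                         bit_flip_rate = 0.005,
                         seq_error_rate = 0.005,
                         rng_seed = 1L,
                         beadfree_depth = 20,
                         mean_transcripts_per_cell = 3600,
                         ambient_umis_per_bead = 15,
                         reads_per_umi = 1.5,
                         n_genes_per_species = 150L,
                         module_size = 20L,
                         module_strength = 1,
                         well_pitch_px = 18L,
                         well_radius_px = 6,
                         bead_radius_px = 4,
                         cell_radius_px = 3.2,
                         cell_radius_sdlog = 0.18,
                         cell_aspect_sdlog = 0.18,
                         cell_irregularity = 0.08,
                         snr = 8,
                         jitter_px = 1L,
                         grid_rows = NULL,
                         grid_cols = NULL,
                         dye_on_mean = 1000,
                         dye_off_mean = 25,
                         dye_sdlog = 0.25,
                         size_factor_sdlog = 0.3) {
  if (is.null(bits_per_cycle)) {
    bits_per_cycle <- n_obos / n_split_cycles
  }
  cfg <- list(
    n_obos = as.integer(n_obos),
    n_split_cycles = as.integer(n_split_cycles),
    bits_per_cycle = as.integer(bits_per_cycle),
    n_pieces = as.integer(n_pieces),
    n_wells = as.integer(n_wells),
    sb_length = as.integer(sb_length),
    umi_length = as.integer(umi_length),
    cell_loading_rate = cell_loading_rate,
    bead_loading_rate = bead_loading_rate,
    doublet_bias = doublet_bias,
    species_fractions = species_fractions,
    crosstalk_rate = crosstalk_rate,
    bit_flip_rate = bit_flip_rate,
    seq_error_rate = seq_error_rate,
    rng_seed = as.integer(rng_seed),
    beadfree_depth = beadfree_depth,
    mean_transcripts_per_cell = mean_transcripts_per_cell,
    ambient_umis_per_bead = ambient_umis_per_bead,
    reads_per_umi = reads_per_umi,
    n_genes_per_species = as.integer(n_genes_per_species),
    module_size = as.integer(module_size),
    module_strength = module_strength,
    well_pitch_px = as.integer(well_pitch_px),
    well_radius_px = well_radius_px,
    bead_radius_px = bead_radius_px,
    cell_radius_px = cell_radius_px,
    cell_radius_sdlog = cell_radius_sdlog,
    cell_aspect_sdlog = cell_aspect_sdlog,
    cell_irregularity = cell_irregularity,
    snr = snr,
    jitter_px = as.integer(jitter_px),
    grid_rows = grid_rows,
    grid_cols = grid_cols,
    dye_on_mean = dye_on_mean,
    dye_off_mean = dye_off_mean,
    dye_sdlog = dye_sdlog,
    size_factor_sdlog = size_factor_sdlog
  )
  if (is.null(cfg$grid_rows)) {
    cfg$grid_rows <- max(1L, as.integer(floor(sqrt(cfg$n_wells))))
  }
  cfg$grid_rows <- as.integer(cfg$grid_rows)
  if (is.null(cfg$grid_cols)) {
    cfg$grid_cols <- as.integer(ceiling(cfg$n_wells / cfg$grid_rows))
  }
  cfg$grid_cols <- as.integer(cfg$grid_cols)
  class(cfg) <- "scope_config"
  validate_scope_config(cfg)
}

validate_scope_config <- function(cfg) {
  stopifnot(inherits(cfg, "scope_config"))
  if (cfg$n_obos != cfg$n_split_cycles * cfg$bits_per_cycle) {
    stop("n_obos must equal n_split_cycles * bits_per_cycle")
  }
  if (cfg$n_obos < 1L || cfg$n_obos > 30L) {
    stop("n_obos must be in [1, 30]")
  }
  if (abs(sum(cfg$species_fractions) - 1) > 1e-8) {
    stop("species_fractions must sum to 1")
  }
  if (length(cfg$species_fractions) != 2L) {
    stop("species_fractions must have length 2 (a two-species mixing design)")
  }
  rates <- c(crosstalk_rate = cfg$crosstalk_rate,
             bit_flip_rate = cfg$bit_flip_rate,
             seq_error_rate = cfg$seq_error_rate,
             bead_loading_rate = cfg$bead_loading_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ", paste(names(rates)[bad], collapse = ", "))
  }
  if (cfg$cell_loading_rate < 0) stop("cell_loading_rate must be >= 0")
  if (cfg$doublet_bias < 0) stop("doublet_bias must be >= 0")
  if (cfg$n_pieces < 1L) stop("n_pieces must be >= 1")
  if (cfg$grid_rows * cfg$grid_cols < cfg$n_wells) {
    stop("grid_rows * grid_cols must be >= n_wells")
  }
  if (is.null(names(cfg$species_fractions))) {
    names(cfg$species_fractions) <- c("speciesA", "speciesB")
  }
  cfg
}

#' @export
print.scope_config <- function(x, ...) {
  cat("Experiment configuration\n")
  cat(sprintf("  optical code : %d OBOs in %d split-pool cycles (%d per cycle); codespace 2^%d = %d\n",
              x$n_obos, x$n_split_cycles, x$bits_per_cycle, x$n_obos, 2^x$n_obos))
  cat(sprintf("  device       : %d wells (%d x %d grid), %d pieces; effective capacity %d\n",
              x$n_wells, x$grid_rows, x$grid_cols, x$n_pieces,
              effective_capacity(x$n_obos, x$n_pieces)))
  cat(sprintf("  loading      : %.3g cells/well (doublet bias %.3g), %.3g beads/well\n",
              x$cell_loading_rate, x$doublet_bias, x$bead_loading_rate))
  cat(sprintf("  species      : %s\n",
              paste(sprintf("%s=%.2f", names(x$species_fractions),
                            x$species_fractions), collapse = ", ")))
  cat(sprintf("  error rates  : bit flip %.3g, seq %.3g, crosstalk %.3g; SNR %.3g\n",
              x$bit_flip_rate, x$seq_error_rate, x$crosstalk_rate, x$snr))
  cat(sprintf("  seed         : %d\n", x$rng_seed))
  invisible(x)
}

#' Read / write a configuration as a flat YAML file
#'
#' @param path File path.
#' @return `read_scope_config()` returns a validated `scope_config`.
#' @export
read_scope_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$species_fractions)) {
    vals$species_fractions <- unlist(vals$species_fractions)
  }
  do.call(scope_config, vals)
}

#' @rdname read_scope_config
#' @param cfg A `scope_config`.
#' @export
write_scope_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scope_config"))
  vals <- unclass(cfg)
  vals$species_fractions <- as.list(vals$species_fractions)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Microwell grid map
#'
#' Lays out `n_wells` wells row-major on the configured grid and assigns
#' each well to an array piece by contiguous column blocks, mimicking
#' physically cutting the device into `n_pieces` strips.
#'
#' @param cfg A [scope_config()].
#' @return A data.frame with columns `well` (1-based index), `row`, `col`,
#'   `x`, `y` (pixel centre, origin top-left) and `piece`.
#' @export
well_map <- function(cfg) {
  w <- seq_len(cfg$n_wells)
  row <- ((w - 1L) %/% cfg$grid_cols) + 1L
  col <- ((w - 1L) %% cfg$grid_cols) + 1L
  data.frame(
    well = w,
    row = row,
    col = col,
    x = (col - 0.5) * cfg$well_pitch_px,
    y = (row - 0.5) * cfg$well_pitch_px,
    piece = pmin(cfg$n_pieces, 1L + as.integer((col - 1L) * cfg$n_pieces / cfg$grid_cols))
  )
}

#' Cell-count distribution with multiplet bias
#'
#' Per-well cell counts are Poisson(`cell_loading_rate`) with the
#' probability of two or more cells multiplied by `doublet_bias` and the
#' 0/1-cell probabilities renormalised proportionally. This leaves the
#' planted multiplet rate (probability of >= 2 cells given >= 1) in closed
#' form, so parameter-recovery checks have an exact target.
#'
#' @param cfg A [scope_config()].
#' @return `planted_doublet_rate()`: the probability that an occupied well
#'   holds two or more cells.
#' @export
planted_doublet_rate <- function(cfg) {
  pm <- cell_count_pmf(cfg$cell_loading_rate, cfg$doublet_bias)
  pm$p2plus / (1 - pm$p0)
}

# adjusted pmf pieces: p0, p1, p2plus after applying the bias
cell_count_pmf <- function(lambda, bias) {
  p0 <- dpois(0, lambda)
  p1 <- dpois(1, lambda)
  p2 <- 1 - p0 - p1
  p2b <- min(1, bias * p2)
  s <- if (p0 + p1 > 0) (1 - p2b) / (p0 + p1) else 0
  list(p0 = p0 * s, p1 = p1 * s, p2plus = p2b)
}

#' @rdname planted_doublet_rate
#' @param rate Target multiplet rate (probability of >= 2 cells among
#'   occupied wells).
#' @return `doublet_bias_for_rate()`: the `doublet_bias` value that plants
#'   `rate` at the configuration's `cell_loading_rate`.
#' @export
doublet_bias_for_rate <- function(cfg, rate) {
  f <- function(b) {
    pm <- cell_count_pmf(cfg$cell_loading_rate, b)
    pm$p2plus / (1 - pm$p0) - rate
  }
  uniroot(f, c(0, 1e4), tol = 1e-10)$root
}
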