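#' Simulate dual-barcoded beads
#'
#' Emulates split-pool ligation of optical barcode oligonucleotides (OBOs)
#' onto sequencing-barcoded mRNA capture beads. Each of the
#' `n_split_cycles` ligation cycles owns `bits_per_cycle` dedicated OBOs
#' (cycle 1 owns OBOs 1..b, cycle 2 owns b+1..2b, ...); in each cycle a
#' bead is routed through a uniformly random subset of that cycle's
#' ligation reactions, so the subset is the bead's pool identity for the
#' cycle and the final optical barcode is the union of subsets over
#' cycles. With 12 OBOs in 2 cycles this yields the full 2^12 = 4096
#' codespace, each code equally likely.
#'
#' Beads are placed in `round(n_wells * bead_loading_rate)` distinct wells
#' chosen uniformly (wells hold at most one bead); each bead inherits its
#' well's array-piece index. Sequencing barcodes are random DNA drawn
#' without replacement.
#'
#' @param cfg A [scope_config()].
#' @return A data.frame of class `bead_set` with columns `bead_id`,
#'   `sequencing_barcode`, `code` (integer optical code), `bits`
#'   (bitstring, OBO 1 leftmost), `well`, `piece`, and attribute
#'   `n_obos`.
#' @export
simulate_beads <- function(cfg) {
  stopifnot(inherits(cfg, "scope_config"))
  n_beads <- round(cfg$n_wells * cfg$bead_loading_rate)
  if (n_beads > 4^cfg$sb_length) {
    stop("bead count ", n_beads, " exceeds the 4^", cfg$sb_length,
         " sequencing-barcode space")
  }
  use_substream(cfg$rng_seed, "beads")
  wm <- well_map(cfg)
  wells <- sort(sample.int(cfg$n_wells, n_beads))
  # per cycle, a uniform subset of that cycle's OBOs = pool identity
  code <- integer(n_beads)
  for (cyc in seq_len(cfg$n_split_cycles)) {
    subset_id <- sample.int(2^cfg$bits_per_cycle, n_beads, replace = TRUE) - 1L
    code <- code + subset_id * 2^((cyc - 1L) * cfg$bits_per_cycle)
  }
  code <- as.integer(code)
  sb <- random_dna(n_beads, cfg$sb_length, unique_seqs = TRUE)
  beads <- data.frame(
    bead_id = seq_len(n_beads),
    sequencing_barcode = sb,
    code = code,
    bits = code_to_bits(code, cfg$n_obos),
    well = wells,
    piece = wm$piece[wells]
  )
  attr(beads, "n_obos") <- cfg$n_obos
  class(beads) <- c("bead_set", class(beads))
  beads
}

#' Simulate the pool-indexed bead-free sequencing library
#'
#' During split-pool ligation a small fraction of capture oligonucleotides
#' is sonicated off the beads and sequenced separately, one library per
#' ligation reaction. A bead whose optical code has bit k set passed
#' through ligation reaction k, so its sequencing barcode appears (at
#' Poisson depth, with per-base substitution errors) in pool k's reads.
#' Sequencing these pools is what makes the optical barcode of each
#' sequencing barcode recoverable without imaging the beads.
#'
#' @param beads A `bead_set` from [simulate_beads()].
#' @param cfg A [scope_config()].
#' @param dir Optional directory; when given, one FASTQ per pool is
#'   written as `pool_XX.fastq` with the pool index also in each read
#'   header (`pool=XX`).
#' @return Invisibly, a named list (one element per pool, `pool_01` ...)
#'   of data.frames with columns `header`, `seq`; the same object that
#'   [build_lookup()] accepts directly.
#' @export
simulate_beadfree_reads <- function(beads, cfg, dir = NULL) {
  stopifnot(inherits(beads, "bead_set"))
  use_substream(cfg$rng_seed, "beadfree")
  bits <- code_bit_matrix(beads$code, cfg$n_obos)
  pools <- vector("list", cfg$n_obos)
  names(pools) <- sprintf("pool_%02d", seq_len(cfg$n_obos))
  for (k in seq_len(cfg$n_obos)) {
    member <- which(bits[, k])
    depth <- stats::rpois(length(member), cfg$beadfree_depth)
    idx <- rep(member, depth)
    seqs <- mutate_dna(beads$sequencing_barcode[idx], cfg$seq_error_rate)
    hdr <- sprintf("bf:%d pool=%02d", seq_along(idx), k)
    pools[[k]] <- data.frame(header = hdr, seq = seqs)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(cfg$n_obos)) {
      write_fastq(pools[[k]]$header, pools[[k]]$seq,
                  file.path(dir, sprintf("pool_%02d.fastq", k)))
    }
  }
  invisible(pools)
}
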