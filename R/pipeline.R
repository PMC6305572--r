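#' Run the full pipeline on a simulated experiment
#'
#' Convenience driver chaining every stage: simulate (or accept) an
#' experiment, build the look-up table from the bead-free pools, demux
#' the hybridization stack, extract imaging records from the live-cell
#' images, count species-split UMIs, link optical calls to expression
#' barcodes piece by piece, and compute the validation report.
#'
#' @param cfg A [scope_config()].
#' @param sim Optional pre-simulated `scope_sim`; simulated from `cfg`
#'   when omitted.
#' @param from_reads Process expression at the read level through
#'   [count_umis()] (the full pipeline); when `FALSE`, the simulator's
#'   count matrix is used directly (fast path for count-level studies).
#' @param min_umis Minimum UMIs for a barcode to count as an expression
#'   profile in the validation report.
#' @param lookup_min_reads,lookup_mismatch Passed to [build_lookup()]
#'   (`min_reads_per_pool`, `max_barcode_mismatch`).
#' @param ... Passed to [validation_report()].
#' @return A list of class `scope_run`: `sim`, `lookup`, `calls`,
#'   `imaging`, `counts` (genes x barcodes UMI matrix), `species_counts`,
#'   `linked`, `report`.
#' @export
run_pipeline <- function(cfg, sim = NULL, from_reads = TRUE,
                         min_umis = 50L, lookup_min_reads = 2L,
                         lookup_mismatch = 1L, ...) {
  if (is.null(sim)) sim <- simulate_experiment(cfg, reads = from_reads)
  lookup <- build_lookup(sim$beadfree, n_obos = cfg$n_obos,
                         min_reads_per_pool = lookup_min_reads,
                         max_barcode_mismatch = lookup_mismatch)
  calls <- demux_stack(sim$hyb, cfg)
  imaging <- imaging_records(sim$cells$live, sim$hyb$wells, cfg)

  if (from_reads) {
    uc <- count_umis(sim$screads, lookup$sequencing_barcode,
                     sim$cells$gene_ref, cfg$sb_length, cfg$umi_length)
    counts <- uc$counts
    sc <- uc$species_counts
  } else {
    counts <- sim$cells$counts
    sc <- species_counts_from_matrix(counts, sim$cells$gene_ref)
    sc$piece <- sim$beads$piece[match(sc$sequencing_barcode,
                                      sim$beads$sequencing_barcode)]
  }
  expr_bc <- split(sc$sequencing_barcode[!is.na(sc$piece) & sc$total > 0],
                   sc$piece[!is.na(sc$piece) & sc$total > 0])
  # pieces with no optical calls need no library; pieces with calls must
  # have one, which link() enforces
  linked <- link(calls, lookup, expr_bc)
  report <- validation_report(linked, imaging, sc, min_umis = min_umis,
                              truth = sim$cells$wells_truth, ...)
  structure(list(sim = sim, lookup = lookup, calls = calls,
                 imaging = imaging, counts = counts, species_counts = sc,
                 linked = linked, report = report),
            class = "scope_run")
}

#' @export
print.scope_run <- function(x, ...) {
  print(x$sim)
  print(x$lookup)
  print(x$calls)
  print(x$linked)
  print(x$report)
  invisible(x)
}

#' Export a barnyard scatter table
#'
#' Per linked expression profile: UMIs of each species and the imaging
#' species label, the raw material of the classic two-species mixing
#' scatter plot.
#'
#' @param run A `scope_run` from [run_pipeline()].
#' @return data.frame `sequencing_barcode`, `well`, `umis_a`, `umis_b`,
#'   `purity`, `imaging_label`.
#' @export
barnyard_table <- function(run) {
  lc <- run$linked$cells
  lc <- lc[lc$link_status == "linked", ]
  sc <- run$species_counts[match(lc$sequencing_barcode,
                                 run$species_counts$sequencing_barcode), ]
  im <- run$imaging[match(lc$well, run$imaging$well), ]
  data.frame(sequencing_barcode = lc$sequencing_barcode, well = lc$well,
             umis_a = sc$umis_a, umis_b = sc$umis_b, purity = sc$purity,
             imaging_label = im$species_label, row.names = NULL)
}
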