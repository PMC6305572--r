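mk_pool <- function(seqs, pool) {
  data.frame(header = sprintf("r%d pool=%02d", seq_along(seqs), pool),
             seq = seqs)
}

test_that("lookup construction follows threshold and absorption semantics", {
  bc <- "ACGTACGTACGT"
  pools <- list(
    pool_01 = mk_pool(rep(bc, 5), 1),
    pool_02 = mk_pool(character(0), 2),
    pool_03 = mk_pool(bc, 3),            # single read: below threshold
    pool_04 = mk_pool(rep(bc, 5), 4)
  )
  expect_warning(lk <- build_lookup(pools, min_reads_per_pool = 2,
                                    n_obos = 4L),
                 "empty pool")
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$bits, "1001")          # bits 1 and 4 only
  # the below-threshold pool-3 read is inconsistent with the call
  expect_equal(lk$confidence, 10 / 11)

  dup <- pools
  names(dup)[2] <- "pool_01"
  expect_error(build_lookup(dup, n_obos = 4L), "duplicate pool")
})

test_that("near-miss barcodes are absorbed into their higher-count parent", {
  bc <- "AAAAAAAAAAAA"
  err <- "AAAAAAAAAAAT"                  # Hamming distance 1
  pools <- list(pool_01 = mk_pool(c(rep(bc, 4), err), 1),
                pool_02 = mk_pool(rep(bc, 4), 2))
  lk <- build_lookup(pools, n_obos = 2L, max_barcode_mismatch = 1L)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$sequencing_barcode, bc)
  expect_equal(lk$pool_01, 5L)
  # with absorption disabled the error read founds its own row
  lk0 <- build_lookup(pools, n_obos = 2L, max_barcode_mismatch = 0L)
  expect_equal(nrow(lk0), 2L)
})

test_that("lookup reproduces truth codes on simulated libraries", {
  cfg <- scope_config(n_wells = 600L, grid_rows = 20L, grid_cols = 30L,
                      n_pieces = 1L, bead_loading_rate = 0.5,
                      seq_error_rate = 0.005, beadfree_depth = 20,
                      rng_seed = 21L)
  beads <- simulate_beads(cfg)
  lk <- build_lookup(simulate_beadfree_reads(beads, cfg))
  m <- match(beads$sequencing_barcode, lk$sequencing_barcode)
  ok <- !is.na(m) & lk$code[m] == beads$code
  expect_gte(mean(ok), 0.99)
})

test_that("lookup confidence is 1 without errors and decays with error rate", {
  cfg0 <- scope_config(n_wells = 600L, grid_rows = 20L, grid_cols = 30L,
                       n_pieces = 1L, bead_loading_rate = 0.5,
                       beadfree_depth = 15, rng_seed = 23L)
  conf <- vapply(c(0, 0.01, 0.05), function(e) {
    cfg <- cfg_with(cfg0, seq_error_rate = e)
    beads <- simulate_beads(cfg)
    lk <- build_lookup(simulate_beadfree_reads(beads, cfg))
    m <- match(beads$sequencing_barcode, lk$sequencing_barcode)
    mean(lk$confidence[m], na.rm = TRUE)
  }, numeric(1))
  expect_equal(conf[1], 1)
  expect_true(all(diff(conf) < 0))
})

mk_reads <- function(bc, umi, tag) {
  data.frame(header = sprintf("sc:%d piece=01", seq_along(bc)),
             seq = paste0(bc, umi, tag))
}

test_that("UMI counting splits species and computes purity", {
  gene_ref <- data.frame(gene = c("gH", "gM"),
                         species = c("human", "mouse"),
                         tag = c(strrep("A", 20), strrep("C", 20)))
  bc <- strrep("G", 12)
  umis <- random_dna(100, 8, unique_seqs = TRUE)
  reads <- mk_reads(rep(bc, 100), umis,
                    c(rep(gene_ref$tag[1], 90), rep(gene_ref$tag[2], 10)))
  # exact-UMI dedup: the 100 distinct UMIs are 100 molecules
  uc <- count_umis(reads, bc, gene_ref, sb_length = 12L, umi_length = 8L,
                   umi_collapse_distance = 0L)
  sc <- uc$species_counts
  expect_equal(sc$umis_a, 90L)
  expect_equal(sc$umis_b, 10L)
  expect_equal(sc$purity, 0.9)
  expect_equal(sc$piece, 1L)
})

test_that("UMI dedup collapses duplicates and near-misses, and is idempotent", {
  gene_ref <- data.frame(gene = c("g1", "g2"), species = c("human", "mouse"),
                         tag = c(strrep("A", 20), strrep("C", 20)))
  bc <- strrep("G", 12)
  # two identical reads + one UMI at Hamming distance 1 -> one molecule
  reads <- mk_reads(rep(bc, 3), c("TTTTTTTT", "TTTTTTTT", "TTTTTTTA"),
                    rep(gene_ref$tag[1], 3))
  uc <- count_umis(reads, bc, gene_ref, 12L, 8L, umi_collapse_distance = 1L)
  expect_equal(sum(uc$counts), 1)
  uc0 <- count_umis(reads, bc, gene_ref, 12L, 8L, umi_collapse_distance = 0L)
  expect_equal(sum(uc0$counts), 2)
  # totals can never exceed read count
  expect_lte(sum(uc$counts), nrow(reads))
})

test_that("reads with unknown barcodes are dropped and logged", {
  gene_ref <- data.frame(gene = c("g1", "g2"), species = c("human", "mouse"),
                         tag = c(strrep("A", 20), strrep("C", 20)))
  reads <- mk_reads(c(strrep("G", 12), strrep("T", 12)),
                    c("AAAAAAAA", "CCCCCCCC"), rep(gene_ref$tag[1], 2))
  expect_message(
    uc <- count_umis(reads, strrep("G", 12), gene_ref, 12L, 8L),
    "not in whitelist")
  expect_equal(uc$log$n_dropped_barcode, 1L)
  expect_equal(sum(uc$counts), 1)
})

test_that("singlet purity stays high and degrades with cross-talk", {
  cfg0 <- scope_config(n_wells = 900L, grid_rows = 30L, grid_cols = 30L,
                       n_pieces = 1L, cell_loading_rate = 0.3,
                       mean_transcripts_per_cell = 300,
                       n_genes_per_species = 40L, rng_seed = 13L)
  purity_at <- function(ct) {
    cfg <- cfg_with(cfg0, crosstalk_rate = ct)
    beads <- simulate_beads(cfg)
    sim <- simulate_cells_and_expression(beads, cfg)
    sc <- species_counts_from_matrix(sim$counts, sim$gene_ref)
    singles <- sim$wells_truth[sim$wells_truth$n_cells == 1L &
                                 !is.na(sim$wells_truth$bead_id), ]
    bcs <- beads$sequencing_barcode[singles$bead_id]
    mean(sc$purity[match(bcs, sc$sequencing_barcode)], na.rm = TRUE)
  }
  p0 <- purity_at(0)
  p5 <- purity_at(0.05)
  expect_gt(p0, 0.93)    # ambient capture alone costs a little purity
  expect_gt(p0, p5)      # cross-talk strictly lowers mean singlet purity
})
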