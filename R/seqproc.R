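#' Build the optical/sequencing barcode look-up table
#'
#' Consumes the pool-indexed bead-free libraries (one read set per
#' ligation reaction) and reconstructs, for every sequencing barcode, the
#' set of ligation pools it visited -- which is exactly its optical
#' barcode. Barcodes are counted per pool by exact match; a barcode within
#' Hamming distance `max_barcode_mismatch` of a higher-count barcode is
#' absorbed into it (ties in count broken lexicographically, the smaller
#' string absorbing). Bit k is called present when the absorbed read count
#' in pool k reaches `min_reads_per_pool`. The row confidence is the
#' fraction of the barcode's reads fully consistent with the final call
#' (exact barcode match, in a called-present pool); it is 1.0 on
#' error-free input and decays as the sequencing error rate rises.
#'
#' @param pools The bead-free read set: a directory containing
#'   `pool_XX.fastq` files, a character vector of such files, or the
#'   in-memory list returned by [simulate_beadfree_reads()].
#' @param min_reads_per_pool Evidence threshold per pool (default 2).
#' @param max_barcode_mismatch Hamming absorption radius (default 1,
#'   Drop-seq convention).
#' @param n_obos Number of pools/bits; inferred from the input when
#'   omitted (the largest pool index seen).
#' @return A data.frame of class `lookup_table`: `sequencing_barcode`,
#'   `code`, `bits`, per-pool read-count columns `pool_XX`, `total_reads`,
#'   `confidence`.
#' @export
build_lookup <- function(pools, min_reads_per_pool = 2L,
                         max_barcode_mismatch = 1L, n_obos = NULL) {
  pools <- load_pool_reads(pools)
  if (anyDuplicated(names(pools))) {
    stop("duplicate pool labels: ",
         paste(unique(names(pools)[duplicated(names(pools))]), collapse = ", "))
  }
  pool_idx <- as.integer(sub("^pool_", "", names(pools)))
  if (is.null(n_obos)) n_obos <- max(pool_idx)
  empty <- vapply(pools, function(p) nrow(p) == 0L, logical(1))
  if (any(empty)) {
    warning("empty pool file(s): ", paste(names(pools)[empty], collapse = ", "),
            "; their bits are called absent")
  }

  dt <- data.table::rbindlist(lapply(seq_along(pools), function(i) {
    if (nrow(pools[[i]]) == 0L) return(NULL)
    data.table::data.table(seq = pools[[i]]$seq, pool = pool_idx[i])
  }))
  if (is.null(dt) || nrow(dt) == 0L) stop("no bead-free reads supplied")
  cnt <- dt[, list(n = .N), by = c("seq", "pool")]
  tot <- cnt[, list(total = sum(n)), by = "seq"]
  data.table::setorder(tot, -total, seq)

  canon <- absorb_barcodes(tot$seq, max_barcode_mismatch)
  cnt$canon <- canon[cnt$seq]
  absorbed <- cnt[, list(n = sum(n), n_exact = sum(n[seq == canon])),
                  by = c("canon", "pool")]

  barcodes <- unique(canon)
  pool_counts <- matrix(0L, nrow = length(barcodes), ncol = n_obos,
                        dimnames = list(barcodes, sprintf("pool_%02d", seq_len(n_obos))))
  exact_counts <- pool_counts
  ij <- cbind(match(absorbed$canon, barcodes), absorbed$pool)
  pool_counts[ij] <- absorbed$n
  exact_counts[ij] <- absorbed$n_exact

  on <- pool_counts >= min_reads_per_pool
  code <- as.integer(on %*% 2^(seq_len(n_obos) - 1L))
  # a read is consistent with the call when it matches the barcode
  # exactly and sits in a pool whose bit was called present
  consistent <- rowSums(exact_counts * on)
  total <- rowSums(pool_counts)
  out <- data.frame(
    sequencing_barcode = barcodes,
    code = code,
    bits = code_to_bits(code, n_obos),
    pool_counts,
    total_reads = as.integer(total),
    confidence = ifelse(total > 0, consistent / total, NA_real_),
    row.names = NULL
  )
  attr(out, "n_obos") <- n_obos
  class(out) <- c("lookup_table", class(out))
  out
}

# greedy Hamming absorption: process barcodes in decreasing-count order
# (ties lexicographic); each barcode joins the nearest earlier canonical
# within `radius`, else founds its own. Returns named map seq -> canonical.
absorb_barcodes <- function(seqs_ordered, radius) {
  n <- length(seqs_ordered)
  canon <- seqs_ordered
  if (radius > 0L && n > 1L) {
    len <- nchar(seqs_ordered[1])
    bank <- matrix(NA_character_, nrow = len, ncol = n)
    bank_seq <- character(n)
    nb <- 0L
    for (i in seq_len(n)) {
      v <- strsplit(seqs_ordered[i], "", fixed = TRUE)[[1]]
      if (nb > 0L) {
        d <- colSums(bank[, seq_len(nb), drop = FALSE] != v)
        j <- which(d <= radius)
        if (length(j)) {
          canon[i] <- bank_seq[j[which.min(d[j])]]
          next
        }
      }
      nb <- nb + 1L
      bank[, nb] <- v
      bank_seq[nb] <- seqs_ordered[i]
    }
  }
  names(canon) <- seqs_ordered
  canon
}

load_pool_reads <- function(pools) {
  if (is.character(pools) && length(pools) == 1L && dir.exists(pools)) {
    pools <- list.files(pools, pattern = "^pool_\\d+\\.fastq$", full.names = TRUE)
  }
  if (is.character(pools)) {
    nm <- sub("\\.fastq$", "", basename(pools))
    out <- lapply(pools, read_fastq)
    names(out) <- nm
    return(out)
  }
  stopifnot(is.list(pools), !is.null(names(pools)))
  pools
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Look-up table: %d sequencing barcodes, %d-bit optical codes, mean confidence %.3f\n",
              nrow(x), attr(x, "n_obos"), mean(x$confidence, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a look-up table as TSV
#' @param x A `lookup_table`.
#' @param path File path.
#' @export
write_lookup <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  out <- read_tsv(path)
  n_obos <- sum(grepl("^pool_", names(out)))
  out$bits <- code_to_bits(out$code, n_obos)  # TSV readers strip leading 0s
  attr(out, "n_obos") <- n_obos
  class(out) <- c("lookup_table", class(out))
  out
}

#' Count species-split UMIs per sequencing barcode
#'
#' Processes barcoded expression reads (`barcode | UMI | gene tag`) into
#' deduplicated transcript counts. Cell barcodes are matched exactly
#' against the whitelist (reads failing are dropped and tallied); the
#' 20-nt gene tag is matched exactly against the simulator's gene
#' reference -- the seam where a real experiment would align reads to a
#' joint two-species transcriptome. UMIs are deduplicated per
#' (barcode, gene) by Hamming collapse within `umi_collapse_distance`
#' (an absorbed UMI joins the higher-read-count UMI; ties lexicographic).
#'
#' @param reads A directory of `piece_XX.fastq` files, a character vector
#'   of FASTQ paths, a single data.frame with columns `header`/`seq`, or
#'   the per-piece list from [simulate_expression_reads()].
#' @param whitelist Character vector of valid sequencing barcodes
#'   (typically `lookup$sequencing_barcode`).
#' @param gene_ref Gene reference data.frame with columns `gene`,
#'   `species`, `tag` (see [simulate_cells_and_expression()]).
#' @param sb_length,umi_length Read structure (bases).
#' @param umi_collapse_distance Hamming radius for UMI dedup (default 1).
#' @return A list of class `umi_counts`: `counts` (sparse genes x
#'   barcodes UMI matrix), `species_counts` (data.frame of class
#'   `species_counts`: barcode, per-species UMI totals, `total`, `purity`,
#'   `piece`), and `log` (reads seen / dropped).
#' @export
count_umis <- function(reads, whitelist, gene_ref, sb_length, umi_length,
                       umi_collapse_distance = 1L) {
  reads <- load_expression_reads(reads)
  n_in <- nrow(reads)
  if (n_in == 0L) stop("no expression reads supplied")
  sb <- substr(reads$seq, 1L, sb_length)
  umi <- substr(reads$seq, sb_length + 1L, sb_length + umi_length)
  tag <- substr(reads$seq, sb_length + umi_length + 1L, nchar(reads$seq))

  keep_bc <- sb %in% whitelist
  n_bad_bc <- sum(!keep_bc)
  gene <- gene_ref$gene[match(tag, gene_ref$tag)]
  keep_tag <- !is.na(gene)
  n_bad_tag <- sum(keep_bc & !keep_tag)
  keep <- keep_bc & keep_tag
  if (n_bad_bc > 0L) {
    message(n_bad_bc, " reads dropped: barcode not in whitelist")
  }

  dt <- data.table::data.table(sb = sb[keep], gene = gene[keep],
                               umi = umi[keep], piece = reads$piece[keep])
  ur <- dt[, list(reads = .N), by = c("sb", "gene", "umi")]
  data.table::setorder(ur, sb, gene, -reads, umi)
  ded <- ur[, list(n = n_distinct_umis(umi, umi_collapse_distance)),
            by = c("sb", "gene")]

  counts <- Matrix::sparseMatrix(
    i = match(ded$gene, gene_ref$gene),
    j = match(ded$sb, unique(ded$sb)),
    x = ded$n,
    dims = c(nrow(gene_ref), length(unique(ded$sb))),
    dimnames = list(gene_ref$gene, unique(ded$sb)))
  counts <- methods::as(counts, "CsparseMatrix")

  piece_of_sb <- dt[, list(piece = piece[1]), by = "sb"]
  sc <- species_counts_from_matrix(counts, gene_ref)
  sc$piece <- piece_of_sb$piece[match(sc$sequencing_barcode, piece_of_sb$sb)]

  structure(list(counts = counts, species_counts = sc,
                 log = list(n_reads = n_in, n_dropped_barcode = n_bad_bc,
                            n_dropped_tag = n_bad_tag)),
            class = "umi_counts")
}

# number of distinct UMIs after greedy Hamming absorption; input must be
# ordered by decreasing read support (ties lexicographic)
n_distinct_umis <- function(umis, radius) {
  n <- length(umis)
  if (n == 1L || radius == 0L) return(n)
  m <- matrix(unlist(strsplit(umis, "", fixed = TRUE), use.names = FALSE),
              ncol = n)
  keep <- rep(TRUE, n)
  for (i in 2:n) {
    prev <- which(keep[seq_len(i - 1L)])
    d <- colSums(m[, prev, drop = FALSE] != m[, i])
    if (any(d <= radius)) keep[i] <- FALSE
  }
  sum(keep)
}

#' Species-split totals and purity from a count matrix
#'
#' @param counts Genes x barcodes matrix.
#' @param gene_ref Gene reference with `gene` and `species` columns.
#' @return A data.frame of class `species_counts` with one row per
#'   barcode: per-species UMI totals, `total`, and `purity` (majority
#'   species fraction; `NA` when the barcode has no UMIs).
#' @export
species_counts_from_matrix <- function(counts, gene_ref) {
  sp <- unique(gene_ref$species)
  stopifnot(length(sp) == 2L)
  spec <- gene_ref$species[match(rownames(counts), gene_ref$gene)]
  a <- Matrix::colSums(counts[spec == sp[1], , drop = FALSE])
  b <- Matrix::colSums(counts[spec == sp[2], , drop = FALSE])
  tot <- a + b
  out <- data.frame(sequencing_barcode = colnames(counts),
                    umis_a = as.integer(a), umis_b = as.integer(b),
                    total = as.integer(tot),
                    purity = ifelse(tot > 0, pmax(a, b) / tot, NA_real_),
                    row.names = NULL)
  attr(out, "species") <- sp
  class(out) <- c("species_counts", class(out))
  out
}

load_expression_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && dir.exists(reads)) {
    reads <- list.files(reads, pattern = "\\.fastq$", full.names = TRUE)
  }
  if (is.character(reads)) {
    lst <- lapply(reads, read_fastq)
    names(lst) <- sub("\\.fastq$", "", basename(reads))
    reads <- lst
  }
  if (is.data.frame(reads)) reads <- list(reads)
  dt <- data.table::rbindlist(lapply(reads, function(r) {
    r$piece <- parse_piece(r$header)
    r
  }), use.names = TRUE)
  as.data.frame(dt)
}

parse_piece <- function(headers) {
  m <- regmatches(headers, regexpr("piece=\\d+", headers))
  out <- rep(NA_integer_, length(headers))
  hit <- grepl("piece=\\d+", headers)
  out[hit] <- as.integer(sub("piece=", "", m))
  out
}
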