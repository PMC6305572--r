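#' FASTQ read/write
#'
#' Thin wrappers over Biostrings giving the 4-line Phred+33 FASTQ format
#' used for all simulated read sets. Read identifiers are free-form; the
#' pipeline encodes machine-readable key=value fields in them (e.g. the
#' ligation-pool index of a bead-free read).
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: data.frame with columns `header` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(header = names(x), seq = as.character(x), row.names = NULL)
}

#' @rdname read_fastq
#' @param headers Character vector of read identifiers (no leading `@`).
#' @param seqs Character vector of read sequences.
#' @export
write_fastq <- function(headers, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Multi-frame 16-bit TIFF stacks
#'
#' Image stacks are held in memory as numeric arrays `[rows, cols, frames]`
#' in arbitrary intensity units and written as 16-bit grayscale TIFF with a
#' fixed full-scale of `2^16 - 1` counts.
#'
#' @param stack Numeric matrix or 3-d array (`rows x cols x frames`).
#' @param path TIFF file path.
#' @export
write_stack <- function(stack, path) {
  if (length(dim(stack)) == 2L) stack <- array(stack, dim = c(dim(stack), 1L))
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k]
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @return `read_stack()`: numeric array `rows x cols x frames` on the
#'   original count scale.
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate greyscale-as-RGB
    m * 65535
  })
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Tab-separated tables
#'
#' All tabular pipeline artifacts (well maps, look-up tables, optical
#' calls, imaging records, linked cells, ground truth) are exchanged as
#' plain TSV with a header line.
#'
#' @param df A data.frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a sparse count matrix as MatrixMarket + row/col annotation
#'
#' @param counts A genes-by-cells matrix (coerced to sparse `dgCMatrix`).
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @return `read_counts_mtx()`: a `dgCMatrix` with dimnames restored.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
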