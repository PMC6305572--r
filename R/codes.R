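#' Optical barcode encodings
#'
#' An optical barcode is a fixed-length presence/absence vector over the
#' OBO set; bit k records whether OBO k was ligated onto the bead. Codes
#' are carried as non-negative integers in `[0, 2^n_obos)` and rendered as
#' bitstrings with OBO 1 leftmost.
#'
#' @param code Integer vector of code values.
#' @param n_obos Number of bits.
#' @return `code_to_bits()`: character vector of `n_obos`-character
#'   bitstrings. `bits_to_code()`: integer vector. `code_bit()`: logical
#'   vector, whether bit `k` is set.
#' @examples
#' code_to_bits(bits_to_code(c("1010", "0001")), 4)
#' @export
code_to_bits <- function(code, n_obos) {
  vapply(code, function(cd) {
    paste(ifelse(bitwAnd(cd, bitwShiftL(1L, seq_len(n_obos) - 1L)) > 0L, "1", "0"),
          collapse = "")
  }, character(1))
}

#' @rdname code_to_bits
#' @param bits Character vector of bitstrings (OBO 1 leftmost).
#' @export
bits_to_code <- function(bits) {
  vapply(bits, function(b) {
    v <- as.integer(strsplit(b, "", fixed = TRUE)[[1]])
    as.integer(sum(v * 2^(seq_along(v) - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname code_to_bits
#' @param k Bit index (1-based).
#' @export
code_bit <- function(code, k) {
  bitwAnd(code, bitwShiftL(1L, k - 1L)) > 0L
}

# logical matrix (n x n_obos) of code bits
code_bit_matrix <- function(code, n_obos) {
  m <- vapply(seq_len(n_obos), function(k) code_bit(code, k), logical(length(code)))
  if (length(code) == 1L) m <- matrix(m, nrow = 1L)
  m
}

#' Random DNA barcodes
#'
#' @param n Number of sequences.
#' @param len Sequence length.
#' @param unique_seqs Draw without replacement (re-sampling duplicates)?
#' @return Character vector of DNA strings.
#' @export
random_dna <- function(n, len, unique_seqs = FALSE) {
  if (unique_seqs && n > 4^len) {
    stop("cannot draw ", n, " unique sequences of length ", len)
  }
  draw <- function(m) {
    mat <- matrix(sample(c("A", "C", "G", "T"), m * len, replace = TRUE),
                  nrow = m)
    apply(mat, 1L, paste, collapse = "")
  }
  out <- draw(n)
  if (unique_seqs) {
    while (anyDuplicated(out)) {
      dup <- which(duplicated(out))
      out[dup] <- draw(length(dup))
    }
  }
  out
}

# per-base substitution noise on equal-length DNA strings
mutate_dna <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs[1])
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"), nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- alt[cbind(match(chars[hit], rownames(alt)), pick)]
  }
  mat <- matrix(chars, ncol = len, byrow = TRUE)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# pairwise Hamming distance of one string against a character-matrix bank
hamming_to_bank <- function(s, bank_mat) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  colSums(bank_mat != v)
}

# character matrix (len x n) from equal-length strings
dna_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = nchar(seqs[1]))
}
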