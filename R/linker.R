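#' Effective barcode capacity
#'
#' The optical codespace is `2^n_obos`; cutting the array into
#' `n_pieces` separately indexed pieces multiplies it, because the same
#' optical code can be reused in different pieces. With 12 OBOs and 10
#' pieces the effective barcode library size is 40,960.
#'
#' @param n_obos Number of optical barcode oligonucleotides (>= 1).
#' @param n_pieces Number of array pieces (>= 1).
#' @return Integer: `2^n_obos * n_pieces`.
#' @examples
#' effective_capacity(12, 10)  # 40960
#' @export
effective_capacity <- function(n_obos, n_pieces) {
  if (n_obos < 1 || n_pieces < 1) stop("n_obos and n_pieces must be positive")
  as.integer(round(2^n_obos * n_pieces))
}

#' Link optical calls to sequencing barcodes
#'
#' For every pass-flag optical call in piece p, the candidate set is the
#' look-up rows whose optical code equals the called code AND whose
#' sequencing barcode was observed in piece p's expression library.
#' Exactly one candidate links the well to that barcode; two or more is
#' an unresolvable code collision (never force-resolved -- a demux error
#' should fail to link, not link wrongly); zero means the code never
#' made it into the look-up (bead-free library dropout). Non-pass calls
#' are recorded as demux failures.
#'
#' @param calls An `optical_calls` data.frame with a `piece` column.
#' @param lookup A `lookup_table`.
#' @param expr_barcodes Observed expression barcodes per piece: a named
#'   list (names = piece indices) of character vectors, or a data.frame
#'   with columns `piece`, `sequencing_barcode`.
#' @return A list of class `linked_cells`: `cells` (per optical call:
#'   `well`, `piece`, `code`, `bits`, `link_status` in
#'   linked / ambiguous-code-collision / code-not-in-lookup / demux-fail,
#'   `sequencing_barcode` for linked rows) and `summary` (counts per
#'   status, `yield` = linked / total calls).
#' @export
link <- function(calls, lookup, expr_barcodes) {
  stopifnot(inherits(lookup, "lookup_table"))
  if (is.data.frame(expr_barcodes)) {
    expr_barcodes <- split(expr_barcodes$sequencing_barcode, expr_barcodes$piece)
  }
  if (is.null(calls$piece)) stop("optical calls carry no piece labels")
  pieces <- sort(unique(calls$piece))
  missing_p <- setdiff(as.character(pieces), names(expr_barcodes))
  if (length(missing_p)) {
    stop("piece label mismatch: no expression library for piece(s) ",
         paste(missing_p, collapse = ", "))
  }

  out <- calls[, c("well", "piece", "code", "bits")]
  out$link_status <- "demux-fail"
  out$sequencing_barcode <- NA_character_
  for (p in pieces) {
    bc <- expr_barcodes[[as.character(p)]]
    lk <- lookup[lookup$sequencing_barcode %in% bc, c("sequencing_barcode", "code")]
    sel <- which(calls$piece == p & calls$flag == "pass")
    if (length(sel) == 0L) next
    tb <- table(lk$code)
    cand_n <- as.integer(tb[as.character(calls$code[sel])])
    cand_n[is.na(cand_n)] <- 0L
    out$link_status[sel] <- ifelse(cand_n == 0L, "code-not-in-lookup",
                                   ifelse(cand_n == 1L, "linked",
                                          "ambiguous-code-collision"))
    lnk <- sel[cand_n == 1L]
    uniq <- lk[lk$code %in% names(tb)[tb == 1L], ]
    out$sequencing_barcode[lnk] <-
      uniq$sequencing_barcode[match(calls$code[lnk], uniq$code)]
  }
  status_levels <- c("linked", "ambiguous-code-collision",
                     "code-not-in-lookup", "demux-fail")
  counts <- table(factor(out$link_status, levels = status_levels))
  summ <- c(as.list(counts),
            list(total_calls = nrow(out),
                 yield = if (nrow(out) > 0)
                   unname(counts["linked"]) / nrow(out) else NA_real_))
  structure(list(cells = out, summary = summ), class = "linked_cells")
}

#' @export
print.linked_cells <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Linked cells: %d/%d optical calls linked (yield %.1f%%)\n",
              s$linked, s$total_calls, 100 * s$yield))
  cat(sprintf("  collisions %d, not-in-lookup %d, demux-fail %d\n",
              s$`ambiguous-code-collision`, s$`code-not-in-lookup`,
              s$`demux-fail`))
  invisible(x)
}

#' Closed-form expected link fraction under code collisions
#'
#' With k beads per piece assigned codes uniformly over `2^n_obos`
#' possibilities, a bead links iff no other bead in its piece shares its
#' code, so the expected linked fraction is `(1 - 2^-n_obos)^(k-1)`.
#'
#' @param k Beads per piece.
#' @param n_obos Bits in the optical code.
#' @return Expected fraction of beads linked.
#' @export
expected_link_fraction <- function(k, n_obos) {
  (1 - 2^(-n_obos))^(k - 1)
}
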