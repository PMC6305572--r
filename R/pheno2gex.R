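#' PCA of the imaging feature matrix
#'
#' Features are z-scored per feature (constant features dropped with a
#' warning) and decomposed with standard PCA. A deterministic sign
#' convention is applied: within each component, the largest-magnitude
#' loading is made positive, so repeated runs and duplicated data give
#' identical components.
#'
#' @param features Numeric matrix or data.frame, cells x features
#'   (typically the 19 imaging features of singlet wells).
#' @return A list of class `phenotype_pcs`: `scores` (cells x K),
#'   `loadings` (features x K, orthonormal), `var_explained`,
#'   `center`, `scale`, `dropped` (names of constant features).
#' @export
feature_pca <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 cells for PCA")
  sds <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, "*")
  pc$x <- sweep(pc$x, 2L, flip, "*")
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, scale = pc$scale, dropped = dropped),
            class = "phenotype_pcs")
}

#' @export
print.phenotype_pcs <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("Phenotype PCA: %d cells x %d features; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), 100 * ve[1],
              if (length(ve) > 1) 100 * ve[2] else NA))
  invisible(x)
}

#' Normalise a count matrix for correlation analysis
#'
#' Counts are scaled per cell to a common total (the median cell total)
#' and log1p-transformed.
#'
#' @param counts Genes x cells matrix.
#' @return Dense numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  tot <- Matrix::colSums(counts)
  target <- stats::median(tot[tot > 0])
  sf <- ifelse(tot > 0, target / tot, 0)
  log1p(as.matrix(counts) %*% Matrix::Diagonal(x = sf))
}

#' Rank genes by correlation with a phenotype PC
#'
#' Pearson correlation of each gene's normalised expression with the
#' chosen component's cell scores; genes are ranked in descending
#' correlation (rank 1 = most positively correlated), ties broken by
#' gene identifier. Zero-variance genes get correlation 0 by convention.
#'
#' @param counts Genes x cells count matrix (cells aligned with
#'   `pcs$scores` rows).
#' @param pcs A `phenotype_pcs`, or directly a numeric score vector.
#' @param component Which PC to use (default 1).
#' @return A data.frame of class `gene_ranking`: `gene`, `correlation`,
#'   `rank`, sorted by rank.
#' @export
rank_genes_by_pc <- function(counts, pcs, component = 1L) {
  scores <- if (inherits(pcs, "phenotype_pcs")) {
    pcs$scores[, component]
  } else as.numeric(pcs)
  if (length(scores) != ncol(counts)) {
    stop("cells in counts (", ncol(counts), ") and PC scores (",
         length(scores), ") are not aligned")
  }
  xn <- normalize_counts(counts)
  r <- suppressWarnings(as.numeric(stats::cor(t(as.matrix(xn)), scores)))
  zv <- !is.finite(r)
  if (any(zv)) {
    message(sum(zv), " zero-variance gene(s) assigned correlation 0")
    r[zv] <- 0
  }
  ord <- order(-r, rownames(counts))
  out <- data.frame(gene = rownames(counts)[ord], correlation = r[ord],
                    rank = seq_along(r), row.names = NULL)
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Permutation-normalised gene set enrichment score
#'
#' Weighted Kolmogorov-Smirnov-style running-sum statistic over the
#' correlation-ranked gene list (weight = |correlation|, the standard
#' exponent-1 scheme): walking down the ranking, in-set genes add their
#' normalised weight, out-of-set genes subtract 1/(N - |S|); the
#' enrichment score ES is the maximum deviation from zero. The null is
#' generated by permuting set membership (`n_permutations` random sets
#' of the same size); the normalised score is ES divided by the mean
#' |ES| of the null, and the p-value is the two-sided null exceedance
#' fraction with the +1 correction.
#'
#' @param ranking A `gene_ranking` from [rank_genes_by_pc()].
#' @param gene_set Character vector of gene identifiers (must all be in
#'   the ranking).
#' @param n_permutations Number of membership permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @return A list of class `enrichment_result`: `es`, `nes`, `p_value`,
#'   `set_size`, `n_permutations`.
#' @export
enrichment_score <- function(ranking, gene_set, n_permutations = 1000L,
                             seed = 1L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (length(gene_set) == 0L) stop("empty gene set")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  missing_g <- setdiff(gene_set, ranking$gene)
  if (length(missing_g)) {
    stop("gene set members absent from ranking: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  inset <- ranking$gene %in% gene_set
  es <- running_es(ranking$correlation, inset)
  set.seed(seed)
  m <- sum(inset)
  n <- nrow(ranking)
  null_es <- vapply(seq_len(n_permutations), function(i) {
    idx <- logical(n)
    idx[sample.int(n, m)] <- TRUE
    running_es(ranking$correlation, idx)
  }, numeric(1))
  nes <- es / mean(abs(null_es))
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_permutations + 1)
  structure(list(es = es, nes = nes, p_value = p, set_size = m,
                 n_permutations = n_permutations),
            class = "enrichment_result")
}

# max-deviation weighted running sum; stats must be in ranking order
running_es <- function(stats_ranked, inset) {
  n <- length(stats_ranked)
  w <- abs(stats_ranked)
  win <- sum(w[inset])
  step <- numeric(n)
  # all-zero in-set weights degenerate to uniform steps
  step[inset] <- if (win > 0) w[inset] / win else 1 / sum(inset)
  step[!inset] <- -1 / (n - sum(inset))
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: ES %.3f, NES %.3f, p = %.4g (set size %d, %d permutations)\n",
              x$es, x$nes, x$p_value, x$set_size, x$n_permutations))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}
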