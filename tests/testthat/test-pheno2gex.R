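synth_features <- function(n = 120, seed = 6) {
  set.seed(seed)
  size <- rnorm(n)
  shape <- rnorm(n)
  f <- matrix(rnorm(n * 19, sd = 0.1), n, 19,
              dimnames = list(NULL, imaging_feature_names()))
  size_block <- c("area", "perimeter", "equiv_diameter", "major_axis",
                  "minor_axis", "convex_area", "int_total")
  shape_block <- c("aspect_ratio", "eccentricity", "circularity")
  f[, size_block] <- f[, size_block] + size * 2
  f[, shape_block] <- f[, shape_block] + shape
  list(f = f, size = size)
}

test_that("PCA recovers a planted size axis with deterministic sign", {
  sf <- synth_features()
  pcs <- feature_pca(sf$f)
  expect_equal(dim(pcs$loadings)[1], 19L)
  # orthonormal loadings, non-increasing variance profile
  expect_equal(crossprod(pcs$loadings), diag(19), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pcs$var_explained) <= 1e-12))
  # PC1 is the size axis
  size_block <- c("area", "perimeter", "equiv_diameter", "major_axis",
                  "minor_axis", "convex_area", "int_total")
  l1 <- abs(pcs$loadings[, 1])
  expect_gt(mean(l1[size_block]), 2 * mean(l1[setdiff(rownames(pcs$loadings),
                                                      size_block)]))
  expect_gt(abs(cor(pcs$scores[, 1], sf$size)), 0.95)
  # duplicated data gives identical components
  pcs2 <- feature_pca(sf$f)
  expect_identical(pcs$loadings, pcs2$loadings)
})

test_that("PCA reconstruction, rank limits, and constant-feature handling", {
  sf <- synth_features(n = 40, seed = 7)
  pcs <- feature_pca(sf$f)
  z <- scale(sf$f)
  recon <- pcs$scores %*% t(pcs$loadings)
  expect_equal(unname(recon), unname(z[, rownames(pcs$loadings)]),
               tolerance = 1e-8)
  # two cells admit exactly one nontrivial component
  pcs2 <- feature_pca(sf$f[1:2, ])
  expect_equal(pcs2$var_explained[1], 1, tolerance = 1e-8)
  # constant features are dropped with a warning
  f3 <- sf$f
  f3[, "solidity"] <- 1
  expect_warning(pcs3 <- feature_pca(f3), "solidity")
  expect_false("solidity" %in% rownames(pcs3$loadings))
})

test_that("gene ranking is exact for planted extremes", {
  set.seed(12)
  n_cells <- 80
  scores <- rnorm(n_cells)
  counts <- matrix(rpois(50 * n_cells, 20), 50, n_cells,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  # plant a gene tracking the scores exactly on the normalised scale
  counts["g01", ] <- round(50 * exp(scores))
  rk <- rank_genes_by_pc(counts, scores)
  expect_equal(rk$gene[1], "g01")
  expect_true(all(sort(rk$rank) == 1:50))
  expect_true(all(rk$correlation >= -1 & rk$correlation <= 1))
  expect_true(all(diff(rk$correlation) <= 1e-12))
  # independent noise genes stay near zero
  expect_lt(max(abs(rk$correlation[rk$gene != "g01"])), 0.5)
  # zero-variance gene gets correlation 0 by convention
  counts["g02", ] <- 0
  expect_message(rk2 <- rank_genes_by_pc(counts, scores), "zero-variance")
  expect_equal(rk2$correlation[rk2$gene == "g02"], 0)
})

test_that("enrichment statistic matches the independent fgsea oracle", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  n <- 200
  rk <- data.frame(gene = sprintf("g%03d", 1:n),
                   correlation = sort(rnorm(n), decreasing = TRUE),
                   rank = 1:n)
  class(rk) <- c("gene_ranking", class(rk))
  for (set_idx in list(1:15, seq(5, 150, by = 7), 180:195)) {
    es <- scopelink:::running_es(rk$correlation,
                                 seq_len(n) %in% set_idx)
    stats <- stats::setNames(rk$correlation, rk$gene)
    es_fgsea <- fgsea::calcGseaStat(stats, selectedStats = set_idx,
                                    gseaParam = 1)
    expect_equal(es, es_fgsea, tolerance = 1e-9)
  }
})

test_that("enrichment score behaves at the extremes and is deterministic", {
  set.seed(15)
  n <- 300
  rk <- data.frame(gene = sprintf("g%03d", 1:n),
                   correlation = sort(rnorm(n), decreasing = TRUE),
                   rank = 1:n)
  class(rk) <- c("gene_ranking", class(rk))
  top <- enrichment_score(rk, rk$gene[1:10], n_permutations = 200, seed = 2)
  expect_gt(top$es, 0)
  expect_lte(top$p_value, 1 / 200 + 1e-9)
  again <- enrichment_score(rk, rk$gene[1:10], n_permutations = 200, seed = 2)
  expect_identical(top, again)
  expect_error(enrichment_score(rk, character(0)), "empty gene set")
  expect_error(enrichment_score(rk, "not-a-gene"), "absent from ranking")
  # random sets: |NES| centred near 1 across replicates
  set.seed(99)
  nes <- replicate(20, {
    s <- sample(rk$gene, 15)
    abs(enrichment_score(rk, s, n_permutations = 150, seed = 7)$nes)
  })
  expect_gt(mean(nes), 0.6)
  expect_lt(mean(nes), 1.6)
})

test_that("GMT round trip preserves set membership", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})
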