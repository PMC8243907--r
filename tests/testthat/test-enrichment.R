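# independent brute-force running sum used as the oracle for ES values
brute_es <- function(scores, set, p = 1) {
  hits <- names(scores) %in% set
  w <- abs(scores)^p
  run <- numeric(length(scores)); acc <- 0
  for (i in seq_along(scores)) {
    acc <- if (hits[i]) acc + w[i] / sum(w[hits]) else
      acc - 1 / sum(!hits)
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

test_that("gene ranking orders by signed score with symbol tie-break", {
  dmp <- data.frame(probe_id = paste0("p", 1:6), comparison = "C1_vs_C2",
                    delta_beta = c(0.3, -0.2, 0.1, 0.1, -0.2, 0.5),
                    statistic = 1, p_value = 0.5, q_value = 0.5,
                    direction = "hyper", significant = TRUE)
  ann <- data.frame(probe_id = paste0("p", 1:6), chrom = "chr1", pos = 1:6,
                    gene = c("gB", "gC", "gA", "gD", "gE", ""),
                    region_class = c("gene_body", "promoter", "utr",
                                     "upstream", "gene_body", "intergenic"))
  r <- rank_genes(dmp, ann)
  expect_equal(names(r), c("gB", "gA", "gD", "gC", "gE"))  # ties: gA < gD
  expect_equal(unname(r), c(0.3, 0.1, 0.1, -0.2, -0.2))
  # reversing the scores reverses the order (ties still by symbol)
  dmp2 <- transform(dmp, delta_beta = -delta_beta)
  r2 <- rank_genes(dmp2, ann)
  expect_equal(names(r2), c("gC", "gE", "gA", "gD", "gB"))
})

test_that("the running-sum ES matches brute force on a 10-gene list", {
  scores <- setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5),
                     paste0("g", 1:10))
  set <- c("g1", "g2", "g5")
  got <- enrichment_score(scores, set)
  expect_equal(got$es, brute_es(scores, set))
  expect_equal(got$size, 3L)
  # leading edge: members at or before the positive extremum
  expect_equal(got$leading_edge, c("g1", "g2"))
  # a bottom-loaded set scores negative
  bot <- enrichment_score(scores, c("g9", "g10"))
  expect_lt(bot$es, 0)
  expect_equal(bot$es, brute_es(scores, c("g9", "g10")))
  expect_error(enrichment_score(scores, c("zz")), "empty intersection")
})

test_that("unweighted ES equals the classic KS statistic for a top block", {
  scores <- setNames(seq(10, 1), paste0("g", 1:10))
  set <- paste0("g", 1:3)   # exactly the top block
  got <- enrichment_score(scores, set, p = 0)
  N <- 10; Nh <- 3
  ks <- max(vapply(1:N, function(i) {
    hits <- sum(paste0("g", 1:i) %in% set)
    hits / Nh - (i - hits) / (N - Nh)
  }, numeric(1)))
  expect_equal(got$es, ks)
  # p = 0 is invariant under monotone rescaling of the scores
  resc <- setNames(exp(seq(10, 1)), paste0("g", 1:10))
  expect_equal(enrichment_score(resc, set, p = 0)$es, got$es)
})

test_that("the whole-list set degenerates to ES 0", {
  scores <- setNames(5:1, paste0("g", 1:5))
  expect_equal(enrichment_score(scores, paste0("g", 1:5))$es, 0)
})

test_that("reversing the ranked list negates the ES", {
  set.seed(77)
  scores <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("g", 1:40))
  set <- sample(names(scores), 8)
  fwd <- enrichment_score(scores, set)$es
  rev_scores <- rev(scores)
  bwd <- enrichment_score(rev_scores, set)$es
  expect_equal(bwd, -fwd, tolerance = 1e-12)
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  scores <- setNames(sort(rnorm(60), decreasing = TRUE), paste0("g", 1:60))
  for (i in 1:5) {
    set <- sample(names(scores), 10)
    mine <- enrichment_score(scores, set, p = 1)$es
    ref <- fgsea::calcGseaStat(scores, which(names(scores) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("permutation p-values are seeded, bounded and extreme for planted sets", {
  scores <- setNames(sort(rnorm(100), decreasing = TRUE), paste0("g", 1:100))
  sets <- list(planted = names(scores)[1:10],
               random = sample(names(scores), 10))
  res <- gsea_preranked(scores, sets, n_perm = 200, seed = 5)
  expect_equal(res$p_value[res$gene_set == "planted"], 1 / 201)
  expect_true(all(res$p_value >= 1 / 201 & res$p_value <= 1))
  res2 <- gsea_preranked(scores, sets, n_perm = 200, seed = 5)
  expect_identical(res$es, res2$es)
  expect_identical(res$p_value, res2$p_value)
  expect_error(gsea_preranked(scores, sets, n_perm = 50), "100")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(55)
  scores <- setNames(sort(rnorm(500), decreasing = TRUE), paste0("g", 1:500))
  sets <- lapply(1:100, function(i) sample(names(scores), 15))
  names(sets) <- paste0("null", 1:100)
  res <- gsea_preranked(scores, sets, n_perm = 200, seed = 6)
  frac <- mean(res$p_value < 0.05)
  # binomial noise around 0.05 with 100 sets: allow +/- 3 SD
  expect_gte(frac, 0.0)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
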