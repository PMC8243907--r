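test_that("Welch t and BH q match independent computation on a toy", {
  beta <- toy_beta(20, 6, seed = 7)
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), colnames(beta))
  res <- pairwise_dmp(beta, labels, pair = c(1, 2), space = "beta")
  # oracle: stats::t.test per probe + step-up BH from its definition
  for (i in c(1, 7, 20)) {
    tt <- t.test(beta[i, 1:3], beta[i, 4:6])
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$delta_beta[i], mean(beta[i, 1:3]) - mean(beta[i, 4:6]))
  }
  m <- nrow(beta)
  ord <- order(res$p_value)
  brute_q <- numeric(m)
  brute_q[ord] <- rev(cummin(rev(res$p_value[ord] * m / seq_len(m))))
  brute_q <- pmin(brute_q, 1)
  expect_equal(res$q_value, brute_q, tolerance = 1e-12)
})

test_that("BH step-up equals its brute-force definition on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(10:1000, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- stats::p.adjust(p, "BH")   # the path pairwise_dmp uses
    ord <- order(p)
    brute <- numeric(m)
    brute[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
    brute <- pmin(brute, 1)
    expect_equal(q, brute, tolerance = 1e-12)
    # step-up property: significant iff p <= largest passing threshold
    for (alpha in c(0.01, 0.05)) {
      k <- max(c(0L, which(p[ord] <= seq_len(m) * alpha / m)))
      sig_brute <- if (k > 0) ord[seq_len(k)] else integer(0)
      expect_setequal(which(q <= alpha), sig_brute)
    }
  }
})

test_that("identical clusters produce a clean null", {
  base <- toy_beta(200, 3, seed = 3)
  beta <- cbind(base, base)
  colnames(beta) <- paste0("s", 1:6)
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), colnames(beta))
  res <- pairwise_dmp(beta, labels, pair = c(1, 2))
  expect_true(all(res$delta_beta == 0))
  expect_false(any(res$significant))
})

test_that("flipping the comparison flips direction but not q-values", {
  beta <- toy_beta(50, 6, seed = 11)
  labels <- setNames(rep(1:2, each = 3), colnames(beta))
  ab <- pairwise_dmp(beta, labels, pair = c(1, 2))
  ba <- pairwise_dmp(beta, labels, pair = c(2, 1))
  expect_equal(ab$q_value, ba$q_value, tolerance = 1e-12)
  expect_equal(ab$delta_beta, -ba$delta_beta)
  flip <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(unname(flip[ab$direction]), ba$direction)
})

test_that("a singleton cluster is scored with a floored z-statistic", {
  beta <- toy_beta(30, 5, seed = 13)
  labels <- setNames(c(1L, 2L, 2L, 2L, 2L), colnames(beta))
  res <- pairwise_dmp(beta, labels, pair = c(1, 2), space = "beta",
                      sd_floor = 0.05)
  expect_equal(attr(res, "test"), "z_vs_cluster")
  x1 <- beta[, 1]
  mb <- rowMeans(beta[, 2:5]); sb <- apply(beta[, 2:5], 1, sd)
  z <- (x1 - mb) / pmax(sb, 0.05)
  expect_equal(res$statistic, unname(z), tolerance = 1e-12)
  expect_equal(res$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
  expect_error(pairwise_dmp(beta[, 1:2], setNames(1:2, colnames(beta)[1:2]),
                            pair = c(1, 2)), "2 or more")
})

test_that("planted drift probes are detected with controlled false discoveries", {
  recalls <- fdps <- numeric(8)
  for (s in seq_along(recalls)) {
    co <- simulate_cohort(two_clone_config(seed = 100 + s, n_probes = 3000L,
                                           fraction_drift_probes = 1 / 6,
                                           edge_length = 25))
    labels <- setNames(rep(1:2, each = 3), colnames(co$beta))
    res <- pairwise_dmp(co$beta, labels, pair = c(1, 2))
    sig <- res$probe_id[res$significant]
    truth <- co$truth$drift_probes   # 500 planted probes
    recalls[s] <- mean(truth %in% sig)
    fdps[s] <- if (length(sig)) mean(!sig %in% truth) else 0
  }
  # drift shifts are centred at zero, so probes drawn near zero shift are
  # inherently undetectable; with shift SD 4 M units and noise SD 0.3 the
  # detectable fraction is about two thirds
  expect_gt(mean(recalls), 0.55)
  expect_lt(mean(fdps), 0.02)
})

test_that("under the global null almost no probe passes the FDR gate", {
  fracs <- vapply(1:20, function(s) {
    co <- simulate_cohort(two_clone_config(seed = 200 + s, n_probes = 1000L,
                                           fraction_drift_probes = 0,
                                           sigma_noise = 0.3))
    labels <- setNames(rep(1:2, each = 3), colnames(co$beta))
    mean(pairwise_dmp(co$beta, labels, pair = c(1, 2))$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.01)
})

test_that("gene summaries score, rank and truncate correctly", {
  # 3-gene toy with hand-computed means
  dmp <- data.frame(
    probe_id = paste0("p", 1:7), comparison = "C1_vs_C2",
    delta_beta = c(0.2, 0.4, -0.1, -0.3, 0.25, 0.6, 0.5),
    statistic = 5, p_value = 1e-6, q_value = 1e-5,
    direction = "hyper", significant = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                         FALSE, TRUE))
  ann <- data.frame(
    probe_id = paste0("p", 1:7), chrom = "chr1", pos = 1:7,
    gene = c("gA", "gA", "gB", "gB", "gC", "gC", ""),
    region_class = c("promoter", "gene_body", "utr", "upstream",
                     "gene_body", "gene_body", "intergenic"))
  out <- summarize_genes(dmp, ann, top_n = 50)
  # gA = mean(0.2, 0.4) = 0.3; gC = 0.25 (p6 not significant, p7 intergenic)
  expect_equal(out$hyper$gene, c("gA", "gC"))
  expect_equal(out$hyper$score, c(0.3, 0.25))
  expect_equal(out$hyper$n_probes, c(2L, 1L))
  # gB = mean(-0.1, -0.3) = -0.2
  expect_equal(out$hypo$gene, "gB")
  expect_equal(out$hypo$score, -0.2)
  expect_equal(out$hyper$rank, 1:2)
  # truncation floor: fewer qualifying genes than top_n
  out2 <- summarize_genes(dmp, ann, top_n = 1)
  expect_equal(out2$hyper$gene, "gA")
})

test_that("venn regions enumerate exactly and sum to the union", {
  same <- list(A = c("x", "y"), B = c("x", "y"), C = c("y", "x"))
  v <- venn_overlap(same)
  expect_equal(unname(v[["all"]]), 2L)
  expect_equal(sum(v), 2L)

  disj <- list(A = "a", B = "b", C = "c")
  v2 <- venn_overlap(disj)
  expect_equal(unname(v2[c("only_A", "only_B", "only_C")]), rep(1L, 3))
  expect_equal(sum(v2), 3L)

  v3 <- venn_overlap(list(A = c("a", "b"), B = c("b", "c"), C = c("c", "d")))
  expect_equal(unname(v3[["A&B"]]), 1L)   # b
  expect_equal(unname(v3[["B&C"]]), 1L)   # c
  expect_equal(unname(v3[["A&C"]]), 0L)
  expect_equal(unname(v3[["all"]]), 0L)
  expect_equal(unname(v3[["only_A"]]), 1L)
  expect_equal(unname(v3[["only_C"]]), 1L)
  expect_equal(sum(v3), 4L)
})
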