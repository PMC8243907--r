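make_signature <- function(n_probes = 60, types = c("tumor", "endo", "fibro"),
                           seed = 31) {
  set.seed(seed)
  S <- matrix(runif(n_probes * length(types), 0.05, 0.95), n_probes,
              dimnames = list(sprintf("sig%03d", seq_len(n_probes)), types))
  S
}

test_that("a pure signature column deconvolves to a unit fraction", {
  S <- make_signature()
  beta <- matrix(S[, "fibro"], nrow(S), 1,
                 dimnames = list(rownames(S), "sampleX"))
  fit <- estimate_fractions(beta, S)
  expect_equal(unname(fit$fractions["sampleX", ]), c(0, 0, 1),
               tolerance = 1e-9)
  expect_lt(fit$residual[["sampleX"]], 1e-9)
})

test_that("noiseless mixtures invert exactly", {
  S <- make_signature()
  w <- c(0.5, 0.3, 0.2)
  beta <- matrix(S %*% w, nrow(S), 1, dimnames = list(rownames(S), "mix"))
  fit <- estimate_fractions(beta, S)
  expect_equal(unname(fit$fractions["mix", ]), w, tolerance = 1e-6)
  expect_lt(fit$residual[["mix"]], 1e-9)
  # exact-mixture residual stays ~0 for arbitrary simplex weights
  set.seed(8)
  for (i in 1:5) {
    w2 <- rexp(3); w2 <- w2 / sum(w2)
    b2 <- matrix(S %*% w2, nrow(S), 1, dimnames = list(rownames(S), "m2"))
    f2 <- estimate_fractions(b2, S)
    expect_equal(unname(f2$fractions["m2", ]), w2, tolerance = 1e-6)
    expect_lt(f2$residual[["m2"]], 1e-9)
  }
})

test_that("fractions are non-negative, sum to one, and are permutation-equivariant", {
  S <- make_signature(40)
  set.seed(9)
  beta <- matrix(runif(40 * 3), 40, 3,
                 dimnames = list(rownames(S), paste0("s", 1:3)))
  fit <- estimate_fractions(beta, S)
  expect_true(all(fit$fractions >= 0))
  expect_equal(unname(rowSums(fit$fractions)), rep(1, 3), tolerance = 1e-6)
  perm <- c(3, 1, 2)
  fit2 <- estimate_fractions(beta, S[, perm])
  expect_equal(fit2$fractions, fit$fractions[, perm], tolerance = 1e-9)
})

test_that("a rank-deficient signature warns but still solves", {
  S <- make_signature(40, types = c("a", "b"))
  S <- cbind(S, c = S[, "b"])
  beta <- matrix(S[, "a"], 40, 1, dimnames = list(rownames(S), "s"))
  expect_warning(fit <- estimate_fractions(beta, S), "rank-deficient")
  expect_equal(unname(fit$fractions[1, "a"]), 1, tolerance = 1e-6)
})

test_that("simulated cohort fractions are recovered within 0.05 per type", {
  co <- small_cohort(seed = 14)
  fit <- estimate_fractions(co$beta, co$signature)
  err <- abs(fit$fractions - co$truth$cell_fractions[rownames(fit$fractions),
                                                     colnames(fit$fractions)])
  expect_true(all(colMeans(err) <= 0.05))
})

test_that("MGMT calls apply the mean-beta threshold rule", {
  beta <- matrix(c(1, 1, 0.4, 0.3, 0.35, 0.35, 0.1, 0.2), 2, 4,
                 dimnames = list(c("m1", "m2"), paste0("s", 1:4)))
  calls <- call_mgmt(beta, c("m1", "m2"), threshold = 0.35)
  expect_equal(calls$status, c("methylated", "methylated", "methylated",
                               "unmethylated"))
  expect_equal(calls$mean_beta, c(1, 0.35, 0.35, 0.15))
  # boundary: a mean exactly at threshold is methylated
  expect_equal(calls$status[calls$mean_beta == 0.35],
               c("methylated", "methylated"))
  # monotone in the threshold: raising it never flips unmethylated->methylated
  for (th in seq(0.1, 0.9, by = 0.1)) {
    lo <- call_mgmt(beta, c("m1", "m2"), threshold = th)$status
    hi <- call_mgmt(beta, c("m1", "m2"), threshold = th + 0.05)$status
    expect_true(all(!(lo == "unmethylated" & hi == "methylated")))
  }
  expect_message(call_mgmt(beta, c("m1", "m2", "mX")), "absent")
  expect_error(call_mgmt(beta, c("zz")), "none of the listed")
})

test_that("simulated MGMT promoter states are recovered per clone", {
  co <- small_cohort(seed = 15)
  probes <- co$annotation$probe_id[co$annotation$gene == "MGMT" &
                                     co$annotation$region_class == "promoter"]
  calls <- call_mgmt(co$beta, probes)
  got <- setNames(calls$status, calls$sample_id)
  expect_equal(got, co$truth$mgmt_state[names(got)])
})

test_that("two-cluster fraction comparison matches exhaustive Mann-Whitney", {
  v <- c(0.10, 0.30, 0.25, 0.70, 0.55, 0.80)
  F <- cbind(ct = v)
  rownames(F) <- paste0("s", 1:6)
  labels <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(F))
  res <- compare_fractions(F, labels)
  # brute force: U statistic and exact p by enumerating all 20 assignments
  u_obs <- sum(outer(v[1:3], v[4:6], ">")) # U for group 1
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(idx)
    sum(outer(v[idx], v[-idx], ">")))
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(res$statistic, u_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("constant fractions and planted enrichment behave as expected", {
  co <- small_cohort(seed = 16)
  labels <- setNames(as.integer(factor(co$truth$clone_of)),
                     names(co$truth$clone_of))
  res <- compare_fractions(co$truth$cell_fractions, labels)
  # purity is constant by design: the tumor fraction is untestable (p = 1)
  expect_equal(res$p_value[res$cell_type == "tumor"], 1)
  # planted fibroblast signal, judged on the two multi-sample clusters with
  # the exact Mann-Whitney test: no other type is more significant
  # (compositional closure lets perfectly separated types tie it)
  keep <- names(labels)[co$truth$clone_of %in% c("C2", "C3")]
  res23 <- compare_fractions(co$truth$cell_fractions[keep, ], labels[keep])
  p_fib <- res23$p_value[res23$cell_type == "fibroblast"]
  expect_true(all(p_fib <= res23$p_value[res23$cell_type != "tumor"]))
  expect_lt(p_fib, 0.05)
  # BH option adds q-values
  res_bh <- compare_fractions(co$truth$cell_fractions, labels, adjust = "BH")
  expect_true("q_value" %in% colnames(res_bh))
})
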