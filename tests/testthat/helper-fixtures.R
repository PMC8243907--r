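# Small cohort configurations used across tests. 5000 probes keeps every
# stage fast while retaining all probe roles (drift, MGMT, signature).
small_config <- function(seed = 1L, ...) {
  default_cohort_config(seed = seed, n_probes = 5000L, ...)
}

small_cohort <- function(seed = 1L, ...) simulate_cohort(small_config(seed, ...))

# Two-clone configuration (3 + 3 samples) for differential-methylation tests.
two_clone_config <- function(seed = 1L, n_probes = 5000L,
                             fraction_drift_probes = 0.1,
                             sigma_drift = 2, sigma_noise = 0.3,
                             edge_length = 4, purity = 1, ...) {
  samples <- data.frame(
    sample_id = paste0("t", 1:6),
    site = paste("site", 1:6), x = 1:6, y = 0, z = 0,
    collection = c("primary", rep("autopsy", 5)),
    stringsAsFactors = FALSE)
  cohort_config(
    n_probes = n_probes, samples = samples,
    clones = list(A = paste0("t", 1:3), B = paste0("t", 4:6)),
    tree = data.frame(parent = "A", child = "B", length = edge_length),
    root_clone = "A",
    fraction_drift_probes = fraction_drift_probes,
    sigma_drift = sigma_drift, sigma_noise = sigma_noise,
    purity = purity,
    cnv = data.frame(clone = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0), log2 = numeric(0)),
    mgmt = list(n_probes = 0L,
                states = c(A = "methylated", B = "methylated"),
                beta_meth = c(8, 2), beta_unmeth = c(2, 8)),
    celltypes = list(types = c("tumor", "endothelial", "fibroblast"),
                     n_sig_probes = 0L, beta_high = 0.85, beta_low = 0.1,
                     stroma_weights = c(endothelial = 0.5, fibroblast = 0.5),
                     stroma_jitter_sd = 0.1,
                     fibroblast_boost_clone = "B", fibroblast_boost = 1),
    seed = seed, ...)
}

# deterministic toy beta matrix
toy_beta <- function(n_probes, n_samples, seed = 42L) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

write_tsv_fixture <- function(df, header) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(header, apply(df, 1L, paste, collapse = "\t")), path)
  path
}

# adjusted Rand index between two labelings (independent of any package)
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  if (si * sj / n == (si + sj) / 2) return(1)
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}
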