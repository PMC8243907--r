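#' Configuration for the clonal methylation-cohort simulator
#'
#' Builds a validated configuration describing a multi-region tumor cohort:
#' a clone tree with drift lengths, a clone-to-sample map, a bimodal
#' baseline beta distribution, a fixed subset of clone-defining ("drift")
#' probes that drift in M space along tree edges, per-sample technical
#' noise, stromal admixture against a cell-type signature, clone-specific
#' copy-number segments on the intensity channel, and per-clone MGMT
#' promoter states.
#'
#' The defaults emulate a nine-sample multi-region glioblastoma cohort:
#' one primary-resection sample (clone C1), four recurrences adjacent to
#' the resection cavity plus the midbrain (clone C2: samples 2, 3, 4, 9),
#' and four contralateral recurrences (clone C3: samples 5-8), with MGMT
#' promoter methylation present in C1/C2 and lost in C3.
#'
#' @param n_probes total number of CpG probes (default 50000).
#' @param samples data.frame with \code{sample_id}, \code{site}, \code{x},
#'   \code{y}, \code{z} (mm) and \code{collection}.
#' @param clones named list mapping clone label to sample ids.
#' @param tree data.frame of clone-tree edges: \code{parent}, \code{child},
#'   \code{length} (drift-length units, >= 0).
#' @param root_clone label of the root clone.
#' @param fraction_drift_probes fraction of probes that drift along edges.
#' @param sigma_drift drift scale: M-unit SD per unit edge length.
#' @param sigma_noise per-sample technical noise SD in M units.
#' @param baseline bimodal mixture for baseline betas: list with
#'   \code{weights}, \code{shape1}, \code{shape2}.
#' @param purity per-sample tumor purity in [0,1] (recycled).
#' @param cnv data.frame of clone CNV segments: \code{clone}, \code{chrom},
#'   \code{start}, \code{end} (bp, 1-based closed), \code{log2}.
#' @param mgmt list: \code{n_probes}, \code{states} (named per-clone,
#'   \code{"methylated"}/\code{"unmethylated"}), \code{beta_meth} and
#'   \code{beta_unmeth} Beta shape pairs.
#' @param celltypes list: \code{types} (first entry is the tumor
#'   component), \code{n_sig_probes}, \code{beta_high}, \code{beta_low},
#'   \code{stroma_weights} (named, non-tumor), \code{stroma_jitter_sd}
#'   (log-normal SD on stromal weights), \code{fibroblast_boost_clone}
#'   and \code{fibroblast_boost} (stromal enrichment planted in one clone).
#' @param n_chrom number of chromosomes probes are spread over.
#' @param probe_spacing_bp spacing between consecutive probes (bp).
#' @param seed mandatory integer seed.
#' @return a validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_probes = 50000L,
                          samples = default_sample_sheet(),
                          clones = list(C1 = "s1",
                                        C2 = c("s2", "s3", "s4", "s9"),
                                        C3 = c("s5", "s6", "s7", "s8")),
                          tree = data.frame(parent = c("C1", "C1"),
                                            child  = c("C2", "C3"),
                                            length = c(24, 24)),
                          root_clone = "C1",
                          fraction_drift_probes = 0.05,
                          sigma_drift = 2.0,
                          sigma_noise = 0.3,
                          baseline = list(weights = c(0.55, 0.45),
                                          shape1 = c(1.5, 8),
                                          shape2 = c(8, 1.5)),
                          purity = 0.7,
                          cnv = default_cnv_spec(),
                          mgmt = list(n_probes = 10L,
                                      states = c(C1 = "methylated",
                                                 C2 = "methylated",
                                                 C3 = "unmethylated"),
                                      beta_meth = c(8, 2),
                                      beta_unmeth = c(2, 8)),
                          celltypes = list(
                            types = c("tumor", "endothelial", "fibroblast",
                                      "tcell", "neutrophil"),
                            n_sig_probes = 1000L,
                            beta_high = 0.85, beta_low = 0.10,
                            stroma_weights = c(endothelial = 0.30,
                                               fibroblast = 0.30,
                                               tcell = 0.25,
                                               neutrophil = 0.15),
                            stroma_jitter_sd = 0.10,
                            fibroblast_boost_clone = "C3",
                            fibroblast_boost = 2.0),
                          n_chrom = 10L,
                          probe_spacing_bp = 1000L,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  cfg <- list(n_probes = as.integer(n_probes), samples = samples,
              clones = clones, tree = tree, root_clone = root_clone,
              fraction_drift_probes = fraction_drift_probes,
              sigma_drift = sigma_drift, sigma_noise = sigma_noise,
              baseline = baseline,
              purity = stats::setNames(rep_len(purity, nrow(samples)),
                                       samples$sample_id),
              cnv = cnv, mgmt = mgmt, celltypes = celltypes,
              n_chrom = as.integer(n_chrom),
              probe_spacing_bp = as.integer(probe_spacing_bp),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' Default paper-scale cohort configuration
#'
#' Nine anatomically annotated samples, three clones with partition
#' \{s1\}, \{s2,s3,s4,s9\}, \{s5,s6,s7,s8\}, 50,000 probes, drift SD 2.0,
#' noise SD 0.3, purity 0.7, MGMT methylation lost in the C3 clone.
#'
#' @param seed integer seed (default 1).
#' @param ... overrides passed to [cohort_config()].
#' @return a \code{"cohort_config"}.
#' @export
default_cohort_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

# Anatomical sites of the nine-region sampling scheme, with approximate
# scanner-space coordinates in mm (x: left- to right+).
default_sample_sheet <- function() {
  data.frame(
    sample_id = paste0("s", 1:9),
    site = c("right temporal lobe (resection)",
             "resection cavity wall, right temporal lobe",
             "right parietal lobe", "right occipital lobe",
             "right frontal lobe / corpus callosum",
             "left frontal lobe / corpus callosum",
             "left superior frontal lobe", "left lateral frontal lobe",
             "midbrain"),
    x = c(45, 48, 35, 25, 15, -15, -20, -40, 0),
    y = c(-25, -30, -55, -80, 25, 25, 30, 30, -25),
    z = c(-15, -10, 40, 10, 25, 25, 50, 20, -10),
    collection = c("primary", rep("autopsy", 8)),
    stringsAsFactors = FALSE)
}

# Clone-specific copy-number segments (bp, 1-based closed; log2 shift).
# C2 inherits the C1 alterations and adds a focal amplification; C3 carries
# its own distinct gains/losses, mirroring divergent recurrent disease.
default_cnv_spec <- function() {
  data.frame(
    clone = c("C1", "C1", "C2", "C2", "C2", "C3", "C3"),
    chrom = c("chr8", "chr10", "chr8", "chr10", "chr1", "chr1", "chr6"),
    start = c(1000001, 2000001, 1000001, 2000001, 500001, 1, 1500001),
    end   = c(2000000, 3000000, 2000000, 3000000, 1250000, 1000000, 2500000),
    log2  = c(0.25, -0.40, 0.25, -0.40, 0.70, 0.20, -0.35),
    stringsAsFactors = FALSE)
}

validate_cohort_config <- function(cfg) {
  samp <- cfg$samples$sample_id
  if (anyDuplicated(samp)) stop("duplicate sample ids")
  assigned <- unlist(cfg$clones, use.names = FALSE)
  unknown <- setdiff(assigned, samp)
  if (length(unknown))
    stop("clone map references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(assigned) || !setequal(assigned, samp))
    stop("every sample must belong to exactly one clone")
  cl <- names(cfg$clones)
  if (!cfg$root_clone %in% cl) stop("root clone not in clone set")
  if (!all(cfg$tree$parent %in% cl) || !all(cfg$tree$child %in% cl))
    stop("tree edge references unknown clone")
  if (any(cfg$tree$length < 0)) stop("edge lengths must be >= 0")
  if (any(cfg$tree$child == cfg$root_clone)) stop("root clone cannot be a child")
  if (anyDuplicated(cfg$tree$child)) stop("clone tree must be a tree (one parent each)")
  if (cfg$fraction_drift_probes < 0 || cfg$fraction_drift_probes > 1)
    stop("fraction_drift_probes must be in [0,1]")
  if (cfg$sigma_drift < 0 || cfg$sigma_noise < 0) stop("sigmas must be >= 0")
  if (any(cfg$purity < 0 | cfg$purity > 1)) stop("purity must be in [0,1]")
  # overlapping CNV segments within one clone are ambiguous
  if (nrow(cfg$cnv)) {
    by_cc <- split(cfg$cnv, paste(cfg$cnv$clone, cfg$cnv$chrom))
    for (seg in by_cc) {
      if (nrow(seg) < 2L) next
      seg <- seg[order(seg$start), ]
      if (any(seg$start[-1L] <= seg$end[-nrow(seg)]))
        stop("overlapping CNV segments within clone ", seg$clone[1L])
    }
  }
  if (!all(cfg$mgmt$states %in% c("methylated", "unmethylated")))
    stop("mgmt states must be methylated/unmethylated")
  cfg
}

# cumulative drift path length between root and each clone, and clone order
clone_path_shifts <- function(cfg, drift_idx) {
  cl <- names(cfg$clones)
  shift <- matrix(0, nrow = length(drift_idx), ncol = length(cl),
                  dimnames = list(NULL, cl))
  parent_of <- stats::setNames(cfg$tree$parent, cfg$tree$child)
  edge_shift <- list()
  for (i in seq_len(nrow(cfg$tree))) {
    e <- cfg$tree[i, ]
    edge_shift[[e$child]] <-
      stats::rnorm(length(drift_idx), 0, cfg$sigma_drift * sqrt(e$length))
  }
  for (c0 in cl) {
    node <- c0
    while (node != cfg$root_clone) {
      shift[, c0] <- shift[, c0] + edge_shift[[node]]
      node <- parent_of[[node]]
    }
  }
  shift
}

#' Simulate a multi-region methylation cohort with planted ground truth
#'
#' Draws baseline betas from the configured bimodal mixture, applies
#' heritable M-space drift on the clone-defining probe subset along the
#' clone tree, adds per-sample technical noise in M space, mixes the tumor
#' signal with stromal cell-type signature profiles at \code{1 - purity},
#' writes clone copy-number segments onto the intensity log2 channel, and
#' sets MGMT promoter probes per clone state. Identical seed and
#' configuration give identical output.
#'
#' @param cfg a \code{"cohort_config"}.
#' @return list of class \code{"meth_cohort"} with elements \code{beta}
#'   (probe x sample matrix), \code{log2} (probe x sample intensity log2
#'   ratios), \code{annotation} (probe annotation data.frame), \code{meta}
#'   (sample metadata), \code{signature} (signature-probe x cell-type beta
#'   matrix), and \code{truth} (clone assignment, clone tree, drift-probe
#'   ids, CNV truth segments, MGMT states, cell-fraction matrix).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  np <- cfg$n_probes
  samp <- cfg$samples$sample_id
  ns <- length(samp)
  clone_of <- stats::setNames(rep(names(cfg$clones), lengths(cfg$clones)),
                              unlist(cfg$clones, use.names = FALSE))[samp]

  probe_ids <- sprintf("cg%06d", seq_len(np))
  per_chrom <- ceiling(np / cfg$n_chrom)
  chrom_i <- ((seq_len(np) - 1L) %/% per_chrom) + 1L
  chrom <- paste0("chr", chrom_i)
  pos_in <- ((seq_len(np) - 1L) %% per_chrom)
  pos <- pos_in * cfg$probe_spacing_bp + 500L

  # probe-role blocks: signature probes at the tail, MGMT just before them
  n_sig <- cfg$celltypes$n_sig_probes
  n_mgmt <- cfg$mgmt$n_probes
  sig_idx <- if (n_sig > 0) (np - n_sig + 1L):np else integer(0)
  mgmt_idx <- if (n_mgmt > 0) (np - n_sig - n_mgmt + 1L):(np - n_sig) else integer(0)
  regular <- setdiff(seq_len(np), c(sig_idx, mgmt_idx))

  # baseline bimodal betas -> baseline M
  comp <- 1L + (stats::runif(np) >= cfg$baseline$weights[1L])
  base_b <- stats::rbeta(np, cfg$baseline$shape1[comp], cfg$baseline$shape2[comp])
  base_b <- pmin(pmax(base_b, 1e-4), 1 - 1e-4)
  base_m <- log2(base_b / (1 - base_b))

  n_drift <- round(cfg$fraction_drift_probes * np)
  drift_idx <- sort(sample(regular, min(n_drift, length(regular))))
  shifts <- clone_path_shifts(cfg, drift_idx)

  # tumor M per sample: baseline + clone drift + technical noise
  M <- matrix(base_m, np, ns, dimnames = list(probe_ids, samp))
  for (j in seq_len(ns))
    M[drift_idx, j] <- M[drift_idx, j] + shifts[, clone_of[j]]

  # cell-type signature: block-marker design over the signature probes
  types <- cfg$celltypes$types
  S <- NULL
  if (n_sig > 0) {
    S <- matrix(cfg$celltypes$beta_low, n_sig, length(types),
                dimnames = list(probe_ids[sig_idx], types))
    block <- split(seq_len(n_sig),
                   rep(seq_along(types), length.out = n_sig))
    for (t in seq_along(types)) S[block[[t]], t] <- cfg$celltypes$beta_high
    M[sig_idx, ] <- log2(S[, "tumor"] / (1 - S[, "tumor"]))
  }
  if (cfg$sigma_noise > 0)
    M <- M + stats::rnorm(np * ns, 0, cfg$sigma_noise)
  tumor_b <- 2^M / (1 + 2^M)

  # MGMT promoter betas are a clone-state property (one profile per state)
  mgmt_state <- cfg$mgmt$states[clone_of]
  names(mgmt_state) <- samp
  if (n_mgmt > 0) {
    prof <- list(
      methylated = stats::rbeta(n_mgmt, cfg$mgmt$beta_meth[1L],
                                cfg$mgmt$beta_meth[2L]),
      unmethylated = stats::rbeta(n_mgmt, cfg$mgmt$beta_unmeth[1L],
                                  cfg$mgmt$beta_unmeth[2L]))
    for (j in seq_len(ns)) tumor_b[mgmt_idx, j] <- prof[[mgmt_state[j]]]
  }

  # stromal admixture: per-sample cell fractions (tumor fraction = purity)
  sw <- cfg$celltypes$stroma_weights[types[-1L]]
  frac <- matrix(0, ns, length(types), dimnames = list(samp, types))
  for (j in seq_len(ns)) {
    w <- sw
    if (identical(clone_of[[j]], cfg$celltypes$fibroblast_boost_clone) &&
        "fibroblast" %in% names(w))
      w["fibroblast"] <- w["fibroblast"] * cfg$celltypes$fibroblast_boost
    if (cfg$celltypes$stroma_jitter_sd > 0)
      w <- w * exp(stats::rnorm(length(w), 0, cfg$celltypes$stroma_jitter_sd))
    w <- w / sum(w)
    frac[j, ] <- c(cfg$purity[j], (1 - cfg$purity[j]) * w)
  }

  beta <- tumor_b
  for (j in seq_len(ns)) {
    pu <- cfg$purity[j]
    if (pu < 1) {
      # stroma matches the baseline genome-wide, is MGMT-unmethylated, and
      # follows the signature columns on the signature probes
      stroma <- base_b
      if (n_mgmt > 0) stroma[mgmt_idx] <- cfg$celltypes$beta_low
      beta[regular, j] <- pu * tumor_b[regular, j] + (1 - pu) * stroma[regular]
      if (n_mgmt > 0)
        beta[mgmt_idx, j] <- pu * tumor_b[mgmt_idx, j] + (1 - pu) * stroma[mgmt_idx]
      if (n_sig > 0)
        beta[sig_idx, j] <- S %*% frac[j, types] / sum(frac[j, types])
    }
  }

  # intensity log2 channel: clone CNV segments + probe noise
  L2 <- matrix(stats::rnorm(np * ns, 0, 0.1), np, ns,
               dimnames = list(probe_ids, samp))
  cnv_truth <- NULL
  if (nrow(cfg$cnv)) {
    rows <- lapply(seq_len(nrow(cfg$cnv)), function(i) {
      seg <- cfg$cnv[i, ]
      idx <- which(chrom == seg$chrom & pos >= seg$start & pos <= seg$end)
      members <- samp[clone_of == seg$clone]
      L2[idx, members] <<- L2[idx, members] + seg$log2
      data.frame(clone = seg$clone, chrom = seg$chrom,
                 start = seg$start, end = seg$end, log2 = seg$log2,
                 n_probes = length(idx), stringsAsFactors = FALSE)
    })
    cnv_truth <- do.call(rbind, rows)
  }

  annotation <- build_annotation(probe_ids, chrom, pos, regular,
                                 mgmt_idx, sig_idx, cfg)

  truth <- list(
    clone_of = clone_of,
    clone_tree = cfg$tree,
    root_clone = cfg$root_clone,
    drift_probes = probe_ids[drift_idx],
    cnv_segments = cnv_truth,
    mgmt_state = mgmt_state,
    cell_fractions = frac)

  structure(list(beta = beta, log2 = L2, annotation = annotation,
                 meta = cfg$samples, signature = S, truth = truth,
                 config = cfg),
            class = "meth_cohort")
}

# Gene structure for regular probes: consecutive 10-probe genes whose first
# probes carry promoter/upstream/utr classes, then gene body, then two
# intergenic flanks; MGMT promoter probes and signature probes get fixed roles.
build_annotation <- function(probe_ids, chrom, pos, regular,
                             mgmt_idx, sig_idx, cfg) {
  np <- length(probe_ids)
  gene <- character(np)
  region <- rep("intergenic", np)
  tss <- rep(NA_real_, np)
  pattern <- c("upstream", "promoter", "utr", rep("gene_body", 5L),
               "intergenic", "intergenic")
  gene_no <- ((seq_along(regular) - 1L) %/% 10L) + 1L
  slot <- ((seq_along(regular) - 1L) %% 10L) + 1L
  gene[regular] <- sprintf("G%05d", gene_no)
  region[regular] <- pattern[slot]
  # TSS sits at the promoter probe of the gene's block
  tss_pos <- tapply(pos[regular][slot == 2L], gene_no[slot == 2L], identity)
  tss[regular] <- tss_pos[as.character(gene_no)]
  gene[regular][region[regular] == "intergenic"] <- ""
  tss[regular][gene[regular] == ""] <- NA_real_
  if (length(mgmt_idx)) {
    gene[mgmt_idx] <- "MGMT"
    region[mgmt_idx] <- "promoter"
    tss[mgmt_idx] <- pos[mgmt_idx[1L]]
  }
  data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
             gene = gene, tss = tss, strand = "+",
             region_class = region,
             distance_to_tss = ifelse(is.na(tss), NA_real_, pos - tss),
             stringsAsFactors = FALSE)
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("meth_cohort: %d probes x %d samples, clones: %s\n",
              nrow(x$beta), ncol(x$beta),
              paste(names(x$config$clones), collapse = ", ")))
  invisible(x)
}

#' Write all cohort artifacts to a directory as plain-text formats
#'
#' Emits the beta matrix, intensity log2 matrix, probe annotation, sample
#' metadata and signature matrix as TSV, plus the ground truth as JSON.
#'
#' @param cohort a \code{"meth_cohort"}.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_beta_matrix(cohort$log2, file.path(dir, "log2.tsv"))
  write_probe_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_sample_meta(cohort$meta, file.path(dir, "samples.tsv"))
  if (!is.null(cohort$signature))
    write_beta_matrix(cohort$signature, file.path(dir, "signature.tsv"))
  truth <- cohort$truth
  truth$cell_fractions <- as.data.frame(truth$cell_fractions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
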