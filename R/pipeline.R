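#' Assemble a full pipeline configuration
#'
#' One list with a section per stage; every stage can be toggled and every
#' stage parameter has the pipeline default. Stages consume either the
#' simulated cohort (when \code{simulate} is enabled) or files named in
#' \code{inputs}.
#'
#' @param outdir output directory (\code{NULL} to keep results in memory
#'   only).
#' @param seed master seed; stochastic stages derive their seeds from it.
#' @param cohort optional \code{"cohort_config"} for the simulate stage
#'   (defaults to [default_cohort_config()] with the master seed).
#' @param inputs named list of file paths (\code{beta}, \code{annotation},
#'   \code{meta}, \code{log2}, \code{signature}, \code{gmt}) used when the
#'   simulate stage is disabled.
#' @param stages character vector of enabled stages, a subset of the
#'   default ordering.
#' @param select,cluster,dmp,cnv,mgmt,gsea named lists of per-stage
#'   parameter overrides.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(outdir = NULL, seed = 1L, cohort = NULL,
                            inputs = list(),
                            stages = c("simulate", "select", "cluster",
                                       "phylogeny", "path", "dmp", "genes",
                                       "venn", "cnv", "mgmt", "deconv",
                                       "gsea"),
                            select = list(), cluster = list(), dmp = list(),
                            cnv = list(), mgmt = list(), gsea = list()) {
  defaults <- list(
    select = list(k = 10000L, criterion = "sd"),
    cluster = list(k_clusters = 3L, metric = "euclidean",
                   linkage = "ward.D2", space = "m"),
    dmp = list(fdr_q = 0.01, top_n = 50L, sd_floor = 0.1),
    cnv = list(bin_size = 50L, alpha = 0.01, min_segment_bins = 3L,
               n_perm = 1000L, amp_threshold = 0.3, gain_threshold = 0.1,
               loss_threshold = -0.1),
    mgmt = list(threshold = 0.35),
    gsea = list(n_perm = 1000L, p = 1))
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              cohort = cohort, inputs = inputs, stages = stages,
              select = utils::modifyList(defaults$select, select),
              cluster = utils::modifyList(defaults$cluster, cluster),
              dmp = utils::modifyList(defaults$dmp, dmp),
              cnv = utils::modifyList(defaults$cnv, cnv),
              mgmt = utils::modifyList(defaults$mgmt, mgmt),
              gsea = utils::modifyList(defaults$gsea, gsea))
  class(cfg) <- "pipeline_config"
  cfg
}

# stable hash of the configuration (identifies a run)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg$outdir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  unname(tools::md5sum(tmp))
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate, top-variable probe
#' selection, hierarchical clustering, neighbor-joining phylogeny, spread
#' path, pairwise differential methylation, gene summaries, Venn overlaps,
#' copy-number profiling, MGMT calls, microenvironment deconvolution and
#' preranked enrichment. Any stage failure halts the run with the stage
#' name in the error. When \code{outdir} is set, stage outputs are written
#' atomically as the standard plain-text formats plus a JSON run report.
#'
#' @param cfg a \code{"pipeline_config"}.
#' @return list of class \code{"run_report"}: per-stage status, parameter
#'   echo, headline outputs (cluster partition, Newick string, MGMT table,
#'   segment counts, top-gene lists, Venn counts), package version and
#'   config hash.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  enabled <- function(s) s %in% cfg$stages
  report <- list(stages = character(0),
                 parameters = cfg[c("select", "cluster", "dmp", "cnv",
                                    "mgmt", "gsea")],
                 version = as.character(utils::packageVersion("spatialmeth")),
                 config_hash = config_hash(cfg))
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(writer, file) {
    if (!is.null(outdir)) write_atomic(writer, file.path(outdir, file))
  }

  beta <- ann <- meta <- l2 <- sig <- gene_sets <- NULL
  cohort <- NULL
  if (enabled("simulate")) {
    ccfg <- if (is.null(cfg$cohort)) default_cohort_config(seed = cfg$seed)
    else cfg$cohort
    cohort <- on_stage("simulate", simulate_cohort(ccfg))
    beta <- cohort$beta; ann <- cohort$annotation; meta <- cohort$meta
    l2 <- cohort$log2; sig <- cohort$signature
    if (!is.null(outdir)) write_cohort(cohort, file.path(outdir, "cohort"))
    report$stages <- c(report$stages, "simulate")
  } else {
    ins <- cfg$inputs
    if (!is.null(ins$beta)) beta <- on_stage("inputs", read_beta_matrix(ins$beta))
    if (!is.null(ins$annotation)) ann <- read_probe_annotation(ins$annotation)
    if (!is.null(ins$meta)) meta <- read_sample_meta(ins$meta)
    if (!is.null(ins$log2)) {
      l2 <- as.matrix(utils::read.delim(ins$log2, row.names = 1L,
                                        check.names = FALSE))
    }
    if (!is.null(ins$signature))
      sig <- as.matrix(utils::read.delim(ins$signature, row.names = 1L,
                                         check.names = FALSE))
    if (!is.null(ins$gmt)) gene_sets <- read_gmt(ins$gmt)
  }

  sel <- NULL
  if (enabled("select")) {
    if (is.null(beta)) stop("stage 'select' needs a beta matrix")
    sel <- on_stage("select", select_top_variable_probes(
      beta, k = cfg$select$k, criterion = cfg$select$criterion))
    report$n_selected_probes <- length(sel)
    report$stages <- c(report$stages, "select")
  }

  assignment <- NULL
  if (enabled("cluster")) {
    if (is.null(beta)) stop("stage 'cluster' needs a beta matrix")
    mat <- beta[if (is.null(sel)) rownames(beta) else sel, , drop = FALSE]
    assignment <- on_stage("cluster", hierarchical_cluster(
      mat, k_clusters = cfg$cluster$k_clusters, metric = cfg$cluster$metric,
      linkage = cfg$cluster$linkage, space = cfg$cluster$space))
    report$clusters <- split(names(assignment$labels), assignment$labels)
    report$k <- assignment$k
    emit(function(p) write_cluster_assignment(assignment, p), "clusters.tsv")
    report$stages <- c(report$stages, "cluster")
  }

  tree <- NULL
  if (enabled("phylogeny")) {
    if (is.null(assignment)) stop("stage 'phylogeny' needs the cluster stage")
    root <- if (!is.null(meta) && any(meta$collection == "primary"))
      meta$sample_id[meta$collection == "primary"][1L]
    else colnames(beta)[1L]
    tree <- on_stage("phylogeny", build_phylogeny(assignment$dist, root))
    report$newick <- ape::write.tree(tree)
    emit(function(p) write_newick(tree, p), "phylogeny.nwk")
    report$stages <- c(report$stages, "phylogeny")
  }

  if (enabled("path")) {
    if (is.null(tree) || is.null(meta)) stop("stage 'path' needs a tree and coordinates")
    path <- on_stage("path", infer_spread_path(tree, meta))
    report$spread_path <- as.data.frame(path)
    emit(function(p) utils::write.table(path, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE), "spread_path.tsv")
    report$stages <- c(report$stages, "path")
  }

  dmps <- NULL
  if (enabled("dmp")) {
    if (is.null(assignment)) stop("stage 'dmp' needs the cluster stage")
    dmps <- on_stage("dmp", all_pairwise_dmp(
      beta, assignment, fdr_q = cfg$dmp$fdr_q, sd_floor = cfg$dmp$sd_floor))
    report$n_significant <- vapply(dmps, function(d) sum(d$significant), 0L)
    for (nm in names(dmps))
      emit(function(p) utils::write.table(dmps[[nm]], p, sep = "\t",
                                          quote = FALSE, row.names = FALSE),
           paste0("dmp_", nm, ".tsv"))
    report$stages <- c(report$stages, "dmp")
  }

  genes <- NULL
  if (enabled("genes")) {
    if (is.null(dmps) || is.null(ann)) stop("stage 'genes' needs dmp + annotation")
    genes <- on_stage("genes", lapply(dmps, summarize_genes, annotation = ann,
                                      top_n = cfg$dmp$top_n))
    report$top_genes <- lapply(genes, function(g)
      list(hyper = g$hyper$gene, hypo = g$hypo$gene))
    report$stages <- c(report$stages, "genes")
  }

  if (enabled("venn")) {
    if (is.null(genes) || length(genes) != 3L)
      stop("stage 'venn' needs gene summaries for exactly 3 comparisons")
    report$venn <- list(
      hyper = venn_overlap(lapply(genes, function(g) g$hyper$gene)),
      hypo  = venn_overlap(lapply(genes, function(g) g$hypo$gene)))
    report$stages <- c(report$stages, "venn")
  }

  if (enabled("cnv")) {
    if (is.null(l2) || is.null(ann)) stop("stage 'cnv' needs log2 + annotation")
    seg <- on_stage("cnv", cnv_profile(
      l2, ann, bin_size = cfg$cnv$bin_size, alpha = cfg$cnv$alpha,
      min_segment_bins = cfg$cnv$min_segment_bins, n_perm = cfg$cnv$n_perm,
      amp_threshold = cfg$cnv$amp_threshold,
      gain_threshold = cfg$cnv$gain_threshold,
      loss_threshold = cfg$cnv$loss_threshold, seed = cfg$seed))
    report$n_segments <- table(seg$sample_id)
    report$n_altered_segments <- sum(seg$call != "neutral")
    emit(function(p) write_seg(seg, p), "segments.seg")
    report$stages <- c(report$stages, "cnv")
  }

  if (enabled("mgmt")) {
    if (is.null(beta) || is.null(ann)) stop("stage 'mgmt' needs beta + annotation")
    probes <- ann$probe_id[ann$gene == "MGMT" & ann$region_class == "promoter"]
    calls <- on_stage("mgmt", call_mgmt(beta, probes,
                                        threshold = cfg$mgmt$threshold))
    report$mgmt <- calls
    emit(function(p) utils::write.table(calls, p, sep = "\t", quote = FALSE,
                                        row.names = FALSE), "mgmt.tsv")
    report$stages <- c(report$stages, "mgmt")
  }

  if (enabled("deconv")) {
    if (is.null(beta) || is.null(sig)) stop("stage 'deconv' needs beta + signature")
    fr <- on_stage("deconv", estimate_fractions(beta, sig))
    report$cell_fractions <- fr$fractions
    if (!is.null(assignment))
      report$fraction_tests <- compare_fractions(fr, assignment)
    emit(function(p) write_beta_matrix(t(fr$fractions), p, "cell_type"),
         "cell_fractions.tsv")
    report$stages <- c(report$stages, "deconv")
  }

  if (enabled("gsea")) {
    if (is.null(dmps) || is.null(ann)) stop("stage 'gsea' needs dmp + annotation")
    report$gsea <- on_stage("gsea", {
      out <- list()
      for (nm in names(dmps)) {
        ranking <- rank_genes(dmps[[nm]], ann)
        sets <- if (!is.null(gene_sets)) gene_sets
        else demo_gene_sets(names(ranking), seed = cfg$seed)
        res <- gsea_preranked(ranking, sets, n_perm = cfg$gsea$n_perm,
                              p = cfg$gsea$p, seed = cfg$seed)
        res$leading_edge <- NULL
        out[[nm]] <- res
      }
      out
    })
    report$stages <- c(report$stages, "gsea")
  }

  class(report) <- "run_report"
  if (!is.null(outdir))
    write_atomic(function(p) jsonlite::write_json(
      unclass(report), p, auto_unbox = TRUE, digits = NA, force = TRUE,
      na = "null"), file.path(outdir, "report.json"))
  report
}

# deterministic demonstration gene sets over a gene universe, used when the
# caller supplies no GMT file
demo_gene_sets <- function(genes, n_sets = 10L, set_size = 50L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, min(set_size, length(genes))))
  names(sets) <- sprintf("demo_set_%02d", seq_len(n_sets))
  sets
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$k)) cat("clusters:", x$k, "\n")
  if (!is.null(x$newick)) cat("phylogeny:", x$newick, "\n")
  invisible(x)
}
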