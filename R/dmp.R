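#' Pairwise differential methylation between two clusters
#'
#' Tests every probe for differential methylation between two clusters of
#' samples. Testing is done on M values (variance stabilizing); effect
#' sizes are reported as \code{delta_beta}, the difference of cluster mean
#' betas (first minus second), for interpretability. With at least two
#' samples per cluster a Welch t-test is used; when one cluster is a single
#' sample (the primary-resection case) that sample is scored with a
#' z-statistic against the other cluster's probe-wise mean and SD, the SD
#' floored at \code{sd_floor} M units so that near-constant probes cannot
#' produce unbounded statistics. P-values are two-sided;
#' Benjamini-Hochberg q-values are computed across all tested probes and
#' the significant set is \code{q < fdr_q}.
#'
#' @param beta probe x sample beta matrix.
#' @param assignment a \code{"cluster_assignment"} (or a named integer
#'   vector of cluster labels).
#' @param pair length-2 vector of cluster labels, first vs second.
#' @param space test on \code{"m"} (default) or \code{"beta"} values.
#' @param fdr_q FDR threshold for the significant flag (default 0.01).
#' @param sd_floor minimum SD in the single-sample z-test (M units).
#' @param eps M-transform offset.
#' @return data.frame with one row per probe: \code{probe_id},
#'   \code{comparison}, \code{delta_beta}, \code{statistic}, \code{p_value},
#'   \code{q_value}, \code{direction} (\code{hyper}/\code{hypo} relative to
#'   the first cluster) and \code{significant}. The test used is recorded
#'   in the \code{"test"} attribute.
#' @export
pairwise_dmp <- function(beta, assignment, pair, space = c("m", "beta"),
                         fdr_q = 0.01, sd_floor = 0.1, eps = 0.01) {
  space <- match.arg(space)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  if (length(pair) != 2L || !all(pair %in% labels))
    stop("pair must name two clusters present in the assignment")
  a <- names(labels)[labels == pair[1L]]
  b <- names(labels)[labels == pair[2L]]
  if (!length(a) || !length(b)) stop("empty cluster")
  x <- if (space == "m") beta_to_m(beta, eps) else beta
  A <- x[, a, drop = FALSE]; B <- x[, b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  delta_beta <- rowMeans(beta[, a, drop = FALSE]) -
    rowMeans(beta[, b, drop = FALSE])

  if (na >= 2L && nb >= 2L) {
    va <- rowSums((A - ma)^2) / (na - 1L)
    vb <- rowSums((B - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    p <- 2 * stats::pt(-abs(stat), df)
    test <- "welch_t"
  } else if (na == 1L && nb >= 2L) {
    vb <- rowSums((B - mb)^2) / (nb - 1L)
    stat <- (ma - mb) / pmax(sqrt(vb), sd_floor)
    p <- 2 * stats::pnorm(-abs(stat))
    test <- "z_vs_cluster"
  } else if (nb == 1L && na >= 2L) {
    va <- rowSums((A - ma)^2) / (na - 1L)
    stat <- (ma - mb) / pmax(sqrt(va), sd_floor)
    p <- 2 * stats::pnorm(-abs(stat))
    test <- "z_vs_cluster"
  } else {
    stop("at least one cluster must contain 2 or more samples")
  }
  p[is.na(p)] <- 1   # zero-variance ties under the null
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    probe_id = rownames(beta),
    comparison = sprintf("C%s_vs_C%s", pair[1L], pair[2L]),
    delta_beta = delta_beta, statistic = stat,
    p_value = p, q_value = q,
    direction = ifelse(delta_beta > 0, "hyper",
                       ifelse(delta_beta < 0, "hypo", NA_character_)),
    significant = q < fdr_q,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "test") <- test
  attr(out, "sd_floor") <- if (test == "z_vs_cluster") sd_floor else NA_real_
  out
}

#' Run all pairwise cluster comparisons
#'
#' @inheritParams pairwise_dmp
#' @param ... passed to [pairwise_dmp()].
#' @return named list of DMP data.frames, one per unordered cluster pair.
#' @export
all_pairwise_dmp <- function(beta, assignment, ...) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  ks <- sort(unique(labels))
  pairs <- utils::combn(ks, 2L, simplify = FALSE)
  out <- lapply(pairs, function(p) pairwise_dmp(beta, assignment, p, ...))
  names(out) <- vapply(pairs, function(p)
    sprintf("C%s_vs_C%s", p[1L], p[2L]), "")
  out
}

#' Gene-level summary of a DMP table: top hyper- and hypomethylated genes
#'
#' Restricts to significant probes that map to a gene through a
#' non-intergenic region class (gene body, promoter, UTR or upstream
#' regulatory window), scores each gene by the mean \code{delta_beta} of
#' those probes, and reports the top \code{top_n} genes per direction
#' ranked by absolute score (ties broken by gene symbol). A gene with no
#' significant probe is excluded, not scored zero.
#'
#' @param dmp DMP data.frame from [pairwise_dmp()].
#' @param annotation probe annotation data.frame.
#' @param top_n genes to report per direction (default 50).
#' @return list with \code{hyper} and \code{hypo} data.frames
#'   (\code{gene}, \code{comparison}, \code{score}, \code{n_probes},
#'   \code{rank}).
#' @export
summarize_genes <- function(dmp, annotation, top_n = 50L) {
  ann <- annotation[match(dmp$probe_id, annotation$probe_id), ]
  keep <- dmp$significant & !is.na(ann$gene) & nzchar(ann$gene) &
    ann$region_class != "intergenic"
  d <- dmp[keep, ]
  g <- ann$gene[keep]
  comparison <- if (nrow(dmp)) dmp$comparison[1L] else NA_character_
  if (!nrow(d)) {
    empty <- data.frame(gene = character(0), comparison = character(0),
                        score = numeric(0), n_probes = integer(0),
                        rank = integer(0))
    return(list(hyper = empty, hypo = empty))
  }
  score <- tapply(d$delta_beta, g, mean)
  n_probes <- as.integer(table(g)[names(score)])
  tab <- data.frame(gene = names(score), comparison = comparison,
                    score = as.numeric(score), n_probes = n_probes,
                    stringsAsFactors = FALSE, row.names = NULL)
  pick <- function(sub) {
    sub <- sub[order(-abs(sub$score), sub$gene, method = "radix"), ]
    sub <- utils::head(sub, top_n)
    sub$rank <- seq_len(nrow(sub))
    rownames(sub) <- NULL
    sub
  }
  list(hyper = pick(tab[tab$score > 0, ]),
       hypo  = pick(tab[tab$score < 0, ]))
}

#' Three-way Venn region cardinalities for gene lists
#'
#' Computes the exact sizes of the seven regions of a three-set Venn
#' diagram; the counts sum to the size of the union.
#'
#' @param sets named list of exactly three character vectors.
#' @return named integer vector with one entry per Venn region
#'   (\code{only_<name>}, pairwise intersections, \code{all}).
#' @export
venn_overlap <- function(sets) {
  if (length(sets) != 3L) stop("venn_overlap expects exactly 3 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", 1:3)
  s <- lapply(sets, unique)
  nm <- names(s)
  u <- unique(unlist(s))
  member <- sapply(s, function(x) u %in% x)   # |union| x 3 logical
  if (!length(u)) member <- matrix(logical(0), 0, 3)
  code <- member %*% c(1L, 2L, 4L)
  cnt <- function(k) sum(code == k)
  out <- c(cnt(1L), cnt(2L), cnt(4L), cnt(3L), cnt(5L), cnt(6L), cnt(7L))
  names(out) <- c(paste0("only_", nm),
                  paste(nm[1L], nm[2L], sep = "&"),
                  paste(nm[1L], nm[3L], sep = "&"),
                  paste(nm[2L], nm[3L], sep = "&"),
                  "all")
  out
}
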