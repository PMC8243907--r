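#' Select the most variable probes across samples
#'
#' Ranks probes by across-sample variability of their beta values
#' (standard deviation by default, median absolute deviation optionally)
#' and returns the top \code{k}. Ties are broken lexicographically by probe
#' id, so the selection is deterministic.
#'
#' @param beta probe x sample beta matrix.
#' @param k number of probes to retain (default 10000, the usual choice for
#'   methylation-based tumor clustering).
#' @param criterion \code{"sd"} or \code{"mad"}.
#' @return character vector of probe ids, ranked most variable first;
#'   length \code{min(k, nrow(beta))}.
#' @export
select_top_variable_probes <- function(beta, k = 10000L, criterion = c("sd", "mad")) {
  criterion <- match.arg(criterion)
  if (k < 1) stop("k must be >= 1")
  if (ncol(beta) < 2L) stop("need at least 2 samples")
  score <- switch(criterion,
                  sd = apply(beta, 1L, stats::sd),
                  mad = apply(beta, 1L, stats::mad))
  ord <- order(-score, rownames(beta), method = "radix")
  rownames(beta)[ord][seq_len(min(k, nrow(beta)))]
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns, by default with Euclidean
#' distance on M values and Ward linkage. The partition is obtained by
#' cutting the dendrogram at \code{k_clusters}; when \code{k_clusters} is
#' \code{NULL}, k is chosen automatically as the cut with the highest mean
#' silhouette width over \code{k in 2..min(6, n_samples - 1)} (singleton
#' clusters contribute silhouette 0, the standard convention).
#'
#' @param beta probe x sample beta matrix (typically already restricted to
#'   the top-variable probes).
#' @param k_clusters number of clusters, or \code{NULL} for automatic
#'   selection.
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @param space cluster on \code{"m"} values (default, variance
#'   stabilizing) or raw \code{"beta"}.
#' @param eps M-transform offset.
#' @return list of class \code{"cluster_assignment"}: \code{labels} (named
#'   integer vector, contiguous from 1), \code{k}, \code{hclust} (the
#'   dendrogram), \code{dist}, \code{silhouette} (mean width per candidate
#'   k when automatic selection ran) and \code{method}.
#' @export
hierarchical_cluster <- function(beta, k_clusters = 3L,
                                 metric = "euclidean", linkage = "ward.D2",
                                 space = c("m", "beta"), eps = 0.01) {
  space <- match.arg(space)
  n <- ncol(beta)
  if (n < 2L) stop("need at least 2 samples")
  if (!is.null(k_clusters) && k_clusters > n)
    stop("k_clusters exceeds the number of samples")
  x <- if (space == "m") beta_to_m(beta, eps) else beta
  d <- stats::dist(t(x), method = metric)
  hc <- stats::hclust(d, method = linkage)
  sil <- NULL
  if (is.null(k_clusters)) {
    ks <- 2:min(6L, n - 1L)
    sil <- vapply(ks, function(k)
      mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"]),
      numeric(1))
    names(sil) <- ks
    k_clusters <- ks[which.max(sil)]   # ties: smallest k wins
    selection <- "silhouette"
  } else selection <- "fixed"
  labels <- stats::cutree(hc, k_clusters)
  structure(list(labels = labels, k = as.integer(k_clusters),
                 hclust = hc, dist = d, silhouette = sil,
                 method = list(metric = metric, linkage = linkage,
                               space = space, k_selection = selection)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d samples in %d cluster(s) [%s/%s, %s space, k by %s]\n",
              length(x$labels), x$k, x$method$metric, x$method$linkage,
              x$method$space, x$method$k_selection))
  print(x$labels)
  invisible(x)
}

#' Write a cluster assignment as TSV
#' @param assignment a \code{"cluster_assignment"}.
#' @param path output path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  df <- data.frame(sample_id = names(assignment$labels),
                   cluster = unname(assignment$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
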