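#' Median-center log2 intensity ratios per sample
#'
#' Implements "relative to baseline": after centering, a sample's median
#' probe log2 ratio is 0, so calls are relative to that sample's own
#' dominant copy state.
#'
#' @param log2mat probe x sample matrix of log2 copy ratios.
#' @return centered matrix.
#' @export
center_log2 <- function(log2mat) {
  sweep(log2mat, 2L, apply(log2mat, 2L, stats::median))
}

#' Bin probe-level log2 ratios into fixed-size genomic bins
#'
#' Groups consecutive probes (position-sorted within each chromosome) into
#' bins of \code{bin_size} probes; the last bin of a chromosome may be
#' short. The bin value is the median probe log2 ratio, robust to single
#' probe outliers; the bin interval spans the first to last member probe.
#' Unsorted input is sorted internally (with a message).
#'
#' @param log2mat probe x sample matrix of log2 copy ratios.
#' @param annotation probe annotation with \code{probe_id}, \code{chrom},
#'   \code{pos}.
#' @param bin_size probes per bin (default 50).
#' @return data.frame with \code{sample_id}, \code{chrom}, \code{bin}
#'   (index within chromosome), \code{start}, \code{end}, \code{n_probes},
#'   \code{value}.
#' @export
bin_log2 <- function(log2mat, annotation, bin_size = 50L) {
  ann <- annotation[match(rownames(log2mat), annotation$probe_id), ]
  if (anyNA(ann$probe_id)) stop("probes missing from annotation")
  out <- list()
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    p <- ann$pos[idx]
    if (is.unsorted(p)) {
      message("bin_log2: probes unsorted on ", ch, "; sorting")
      idx <- idx[order(p)]
      p <- ann$pos[idx]
    }
    grp <- ((seq_along(idx) - 1L) %/% bin_size) + 1L
    for (s in colnames(log2mat)) {
      v <- log2mat[idx, s]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, chrom = ch, bin = unique(grp),
        start = tapply(p, grp, min), end = tapply(p, grp, max),
        n_probes = as.integer(table(grp)),
        value = as.numeric(tapply(v, grp, stats::median)),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# max |two-sample t| over all splits of x leaving >= min_bins on each side;
# returns c(stat, split) with split = last index of the left part
max_split_t <- function(x, min_bins) {
  n <- length(x)
  lo <- min_bins; hi <- n - min_bins
  if (lo > hi) return(c(0, NA))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  i <- lo:hi
  n1 <- i; n2 <- n - i
  m1 <- cs[i] / n1; m2 <- (cs[n] - cs[i]) / n2
  ss1 <- cs2[i] - cs[i]^2 / n1
  ss2 <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / n2
  sp2 <- pmax((ss1 + ss2) / (n - 2L), 1e-12)
  t <- abs(m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  k <- which.max(t)
  c(t[k], i[k])
}

#' Segment a binned log2 series by recursive binary splitting
#'
#' At each interval the split maximizing the two-sample t statistic between
#' the left and right means is located; the split is accepted when its
#' permutation p-value (max-t statistic over shuffled bins, at least 1000
#' permutations, seeded) is below \code{alpha}, and segmentation recurses
#' into both halves. Maximal accepted segments are emitted with their
#' probe-weighted mean log2 ratio.
#'
#' @param bins data.frame for one sample/chromosome as produced by
#'   [bin_log2()] (needs \code{value}, \code{n_probes}, \code{start},
#'   \code{end}), or a bare numeric vector of bin values.
#' @param alpha significance level for accepting a split (default 0.01).
#' @param min_segment_bins minimum bins per emitted segment (default 3).
#' @param n_perm permutations for the split test (default 1000).
#' @param seed RNG seed for the permutation test.
#' @return data.frame with \code{start_bin}, \code{end_bin}, \code{start},
#'   \code{end}, \code{n_probes}, \code{mean_log2} per segment.
#' @export
segment_bins <- function(bins, alpha = 0.01, min_segment_bins = 3L,
                         n_perm = 1000L, seed = 1L) {
  if (is.numeric(bins))
    bins <- data.frame(value = bins, n_probes = 1L,
                       start = seq_along(bins), end = seq_along(bins))
  x <- bins$value
  n <- length(x)
  if (n < min_segment_bins) stop("need at least min_segment_bins bins")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  segs <- list()
  recurse <- function(lo, hi) {
    v <- x[lo:hi]
    obs <- max_split_t(v, min_segment_bins)
    accept <- FALSE
    if (!is.na(obs[2L]) && obs[1L] > 0) {
      exceed <- vapply(seq_len(n_perm), function(p)
        max_split_t(sample(v), min_segment_bins)[1L] >= obs[1L], logical(1))
      p_val <- (1 + sum(exceed)) / (n_perm + 1)
      accept <- p_val < alpha
    }
    if (accept) {
      recurse(lo, lo + obs[2L] - 1L)
      recurse(lo + obs[2L], hi)
    } else {
      segs[[length(segs) + 1L]] <<- c(lo, hi)
    }
  }
  recurse(1L, n)
  do.call(rbind, lapply(segs, function(s) {
    idx <- s[1L]:s[2L]
    data.frame(start_bin = s[1L], end_bin = s[2L],
               start = bins$start[s[1L]], end = bins$end[s[2L]],
               n_probes = sum(bins$n_probes[idx]),
               mean_log2 = sum(x[idx] * bins$n_probes[idx]) /
                 sum(bins$n_probes[idx]))
  }))
}

#' Assign categorical copy-number calls to segments
#'
#' Amplification when mean log2 is at or above \code{amp_threshold}
#' (default 0.3, the conventional bound), gain between
#' \code{gain_threshold} and the amplification bound, loss at or below
#' \code{loss_threshold}, neutral otherwise.
#'
#' @param segments data.frame with a \code{mean_log2} column.
#' @param amp_threshold,gain_threshold,loss_threshold call boundaries;
#'   must satisfy loss < gain <= amp.
#' @return the segments with a \code{call} column added.
#' @export
call_segments <- function(segments, amp_threshold = 0.3,
                          gain_threshold = 0.1, loss_threshold = -0.1) {
  if (!(loss_threshold < gain_threshold && gain_threshold <= amp_threshold))
    stop("thresholds must satisfy loss < gain <= amp")
  m <- segments$mean_log2
  segments$call <- ifelse(m >= amp_threshold, "amplification",
                   ifelse(m >= gain_threshold, "gain",
                   ifelse(m <= loss_threshold, "loss", "neutral")))
  segments
}

#' Full copy-number profile: center, bin, segment and call
#'
#' @param log2mat probe x sample matrix of log2 copy ratios.
#' @param annotation probe annotation.
#' @param bin_size probes per bin.
#' @param center median-center each sample first (default TRUE).
#' @param seed RNG seed for the permutation split tests.
#' @param ... thresholds passed to [call_segments()] and parameters passed
#'   to [segment_bins()] (\code{alpha}, \code{min_segment_bins},
#'   \code{n_perm}).
#' @inheritParams segment_bins
#' @inheritParams call_segments
#' @return SEG-style data.frame: \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_probes}, \code{mean_log2},
#'   \code{call}.
#' @export
cnv_profile <- function(log2mat, annotation, bin_size = 50L, center = TRUE,
                        alpha = 0.01, min_segment_bins = 3L, n_perm = 1000L,
                        amp_threshold = 0.3, gain_threshold = 0.1,
                        loss_threshold = -0.1, seed = 1L) {
  if (center) log2mat <- center_log2(log2mat)
  binned <- bin_log2(log2mat, annotation, bin_size)
  out <- list()
  key <- unique(binned[, c("sample_id", "chrom")])
  for (i in seq_len(nrow(key))) {
    b <- binned[binned$sample_id == key$sample_id[i] &
                  binned$chrom == key$chrom[i], ]
    seg <- segment_bins(b, alpha = alpha,
                        min_segment_bins = min_segment_bins,
                        n_perm = n_perm, seed = seed + i)
    seg$sample_id <- key$sample_id[i]
    seg$chrom <- key$chrom[i]
    out[[i]] <- seg
  }
  seg <- do.call(rbind, out)
  seg <- call_segments(seg[, c("sample_id", "chrom", "start", "end",
                               "n_probes", "mean_log2")],
                       amp_threshold, gain_threshold, loss_threshold)
  rownames(seg) <- NULL
  seg
}
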