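#' Call MGMT promoter methylation status per sample
#'
#' Averages beta over the supplied MGMT promoter probes and calls a sample
#' methylated when the mean is at or above the threshold. Listed probes
#' absent from the matrix are reported via \code{message()} and skipped.
#'
#' @param beta probe x sample beta matrix.
#' @param mgmt_probes character vector of MGMT promoter probe ids.
#' @param threshold mean-beta decision boundary (default 0.35).
#' @return data.frame with \code{sample_id}, \code{mean_beta},
#'   \code{status} (\code{methylated}/\code{unmethylated}) and
#'   \code{threshold}.
#' @export
call_mgmt <- function(beta, mgmt_probes, threshold = 0.35) {
  present <- intersect(mgmt_probes, rownames(beta))
  absent <- setdiff(mgmt_probes, rownames(beta))
  if (length(absent))
    message("call_mgmt: ", length(absent), " listed probe(s) absent: ",
            paste(utils::head(absent, 5L), collapse = ", "))
  if (!length(present)) stop("none of the listed MGMT probes are present")
  mb <- colMeans(beta[present, , drop = FALSE])
  data.frame(sample_id = colnames(beta), mean_beta = unname(mb),
             status = ifelse(mb >= threshold, "methylated", "unmethylated"),
             threshold = threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Exact simplex-constrained least squares: minimize ||S f - b||^2 subject
# to f >= 0, sum(f) = 1, by enumerating candidate supports. The optimizer's
# active set yields an equality-constrained solution on its support, so the
# feasible candidate with minimal residual is the global optimum.
simplex_lsq <- function(S, b) {
  k <- ncol(S)
  if (k > 15L) stop("support enumeration is limited to 15 cell types")
  StS <- crossprod(S); Stb <- crossprod(S, b)
  best <- NULL; best_rss <- Inf
  for (mask in seq_len(2^k - 1L)) {
    K <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    kk <- length(K)
    A <- rbind(cbind(2 * StS[K, K, drop = FALSE], rep(1, kk)),
               c(rep(1, kk), 0))
    rhs <- c(2 * Stb[K], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    fK <- sol[seq_len(kk)]
    if (any(fK < -1e-9)) next
    f <- numeric(k); f[K] <- pmax(fK, 0)
    f <- f / sum(f)
    rss <- sum((S %*% f - b)^2)
    if (rss < best_rss - 1e-15) { best <- f; best_rss <- rss }
  }
  list(f = best, rss = best_rss)
}

#' Reference-based cell-type deconvolution by constrained least squares
#'
#' For each sample, estimates mixing fractions over the signature's cell
#' types by minimizing \eqn{\|S f - b\|^2} subject to \eqn{f \ge 0} and
#' \eqn{\sum f = 1}, where S is the signature beta matrix over the
#' signature probes and b the sample's betas at those probes. The solver
#' is exact and deterministic (active-set enumeration). A rank-deficient
#' signature triggers a warning but is still solved.
#'
#' @param beta probe x sample beta matrix.
#' @param signature signature-probe x cell-type beta matrix; its probes
#'   must be present in \code{beta}.
#' @return list of class \code{"cell_fractions"}: \code{fractions} (sample
#'   x cell-type matrix, rows sum to 1) and \code{residual} (per-sample
#'   root-mean-square fit residual).
#' @export
estimate_fractions <- function(beta, signature) {
  if (ncol(signature) < 2L) stop("need at least 2 cell types")
  miss <- setdiff(rownames(signature), rownames(beta))
  if (length(miss))
    stop("signature probe(s) absent from beta matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  S <- as.matrix(signature)
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient; fractions may be unstable")
  B <- beta[rownames(S), , drop = FALSE]
  frac <- matrix(NA_real_, ncol(B), ncol(S),
                 dimnames = list(colnames(B), colnames(S)))
  resid <- stats::setNames(numeric(ncol(B)), colnames(B))
  for (j in seq_len(ncol(B))) {
    fit <- simplex_lsq(S, B[, j])
    frac[j, ] <- fit$f
    resid[j] <- sqrt(fit$rss / nrow(S))
  }
  structure(list(fractions = frac, residual = resid),
            class = "cell_fractions")
}

#' Compare cell-type fractions between clusters
#'
#' Rank-based tests per cell type: exact Mann-Whitney (Wilcoxon rank sum)
#' for two clusters, Kruskal-Wallis for more. P-values are reported per
#' cell type without multiplicity correction by default (the per-type
#' reporting convention); \code{adjust = "BH"} adds q-values. A cell type
#' constant across all samples is untestable and reported with p = 1.
#'
#' @param fractions a \code{"cell_fractions"} or a sample x cell-type
#'   matrix.
#' @param assignment a \code{"cluster_assignment"} or named labels.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with \code{cell_type}, \code{statistic},
#'   \code{p_value} (and \code{q_value} when adjusted).
#' @export
compare_fractions <- function(fractions, assignment,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  F <- if (inherits(fractions, "cell_fractions")) fractions$fractions else fractions
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else assignment
  labels <- labels[rownames(F)]
  if (anyNA(labels)) stop("assignment does not cover all samples")
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  g <- factor(labels)
  rows <- lapply(colnames(F), function(ct) {
    v <- F[, ct]
    if (stats::sd(v) == 0)
      return(data.frame(cell_type = ct, statistic = NA_real_, p_value = 1))
    if (nlevels(g) == 2L) {
      tst <- suppressWarnings(
        stats::wilcox.test(v[g == levels(g)[1L]], v[g == levels(g)[2L]],
                           exact = TRUE))
      data.frame(cell_type = ct, statistic = unname(tst$statistic),
                 p_value = tst$p.value)
    } else {
      tst <- stats::kruskal.test(v, g)
      data.frame(cell_type = ct, statistic = unname(tst$statistic),
                 p_value = tst$p.value)
    }
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$q_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
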