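#' Read a probe-by-sample beta-value matrix from TSV
#'
#' The expected layout is the one methylation-array pipelines exchange:
#' a header row of sample identifiers, a first column of probe identifiers,
#' and beta values (methylation fractions in \eqn{[0,1]}) in the body.
#' Missing values may be encoded as empty fields or \code{NA}.
#'
#' Probes missing in more than \code{max_missing} of samples are dropped
#' (their ids are recorded in the \code{"dropped_probes"} attribute of the
#' result); remaining missing values are imputed by the probe-wise median,
#' which is deterministic and independent of sample order.
#'
#' @param path path to a tab-delimited file.
#' @param max_missing maximum tolerated fraction of missing values per probe
#'   before the probe is dropped (default 0.5).
#' @return a numeric matrix (probes x samples) with unique dimnames and all
#'   values in \eqn{[0,1]}; attribute \code{"dropped_probes"} lists probe ids
#'   removed by the missingness filter.
#' @export
read_beta_matrix <- function(path, max_missing = 0.5) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("beta matrix must have a probe-id column and at least one sample")
  probes <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]   # before subsetting, which mangles dups
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- probes
  colnames(mat) <- sample_ids
  validate_beta_values(mat)
  keep <- rowMeans(is.na(mat)) <= max_missing
  dropped <- rownames(mat)[!keep]
  if (length(dropped))
    message(sprintf("read_beta_matrix: dropped %d probe(s) with > %g%% missing: %s",
                    length(dropped), 100 * max_missing,
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  mat <- mat[keep, , drop = FALSE]
  mat <- impute_probe_median(mat)
  structure(mat, dropped_probes = dropped)
}

#' Write a beta (or any probe-by-sample) matrix to TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_column name of the first (probe id) column.
#' @export
write_beta_matrix <- function(mat, path, id_column = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared invariant checks for a beta matrix already in memory.
validate_beta_values <- function(mat) {
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("probe ids must be present and unique")
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat)))
    stop("sample ids must be present and unique")
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
                 mat[bad[1L, , drop = FALSE]]))
  }
  invisible(mat)
}

impute_probe_median <- function(mat) {
  nas <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(nas)) {
    med <- apply(mat, 1L, stats::median, na.rm = TRUE)
    mat[nas] <- med[nas[, 1L]]
  }
  mat
}

#' Convert beta values to M values
#'
#' The M value is the log2-odds of methylation,
#' \eqn{m = \log_2((\beta+\epsilon)/(1-\beta+\epsilon))}. A small positive
#' offset keeps extreme betas finite; the transform is strictly increasing in
#' beta and antisymmetric about beta = 0.5 when the offset is zero.
#'
#' @param beta numeric vector or matrix of methylation fractions.
#' @param eps non-negative offset (default 0.01). Zero is allowed when all
#'   betas are strictly inside (0,1).
#' @return object of the same shape as \code{beta}, in M units.
#' @seealso [m_to_beta()] for the exact inverse at \code{eps = 0}.
#' @export
beta_to_m <- function(beta, eps = 0.01) {
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0)
    stop("eps must be a single non-negative number")
  log2((beta + eps) / (1 - beta + eps))
}

#' Convert M values back to beta values (exact inverse at eps = 0)
#'
#' @param m numeric vector or matrix of log2 methylation odds.
#' @return methylation fractions in (0,1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
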