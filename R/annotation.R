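#' Classify a probe relative to a gene's structure
#'
#' Assigns one of \code{gene_body}, \code{promoter}, \code{utr},
#' \code{upstream}, \code{intergenic} using 1-based, fully closed
#' coordinates (array-manifest convention) and strand-aware upstream
#' distance. A probe is \code{upstream} when it lies strictly upstream of
#' the TSS by at most \code{upstream_window} bp on the gene's strand
#' (1.5 kb by default, the usual window for proximal regulatory regions).
#' Promoter and UTR sub-intervals, when supplied, take precedence over the
#' gene body. A probe on a different chromosome than the gene is always
#' \code{intergenic}; the function is total and never throws for
#' well-formed inputs.
#'
#' @param probe_chrom,probe_pos probe chromosome label and 1-based position.
#' @param gene_chrom gene chromosome label.
#' @param gene_start,gene_end gene interval (1-based, closed).
#' @param tss transcription start site position.
#' @param strand \code{"+"} or \code{"-"}.
#' @param promoter optional \code{c(start, end)} promoter sub-interval.
#' @param utr optional \code{c(start, end)} UTR sub-interval.
#' @param upstream_window upstream window in bp (default 1500).
#' @return a single string, the region class.
#' @export
annotate_region_class <- function(probe_chrom, probe_pos,
                                  gene_chrom, gene_start, gene_end,
                                  tss, strand = "+",
                                  promoter = NULL, utr = NULL,
                                  upstream_window = 1500L) {
  stopifnot(probe_pos >= 1, gene_start >= 1, gene_start <= gene_end)
  if (!identical(as.character(probe_chrom), as.character(gene_chrom)))
    return("intergenic")
  in_iv <- function(iv) !is.null(iv) && probe_pos >= iv[1L] && probe_pos <= iv[2L]
  if (in_iv(promoter)) return("promoter")
  if (in_iv(utr)) return("utr")
  if (probe_pos >= gene_start && probe_pos <= gene_end) return("gene_body")
  # signed distance to TSS on the gene's strand; positive = downstream
  d <- if (strand == "-") tss - probe_pos else probe_pos - tss
  if (d < 0 && -d <= upstream_window) return("upstream")
  "intergenic"
}

#' Read a BED-like probe annotation table
#'
#' Tab-delimited with columns \code{probe_id}, \code{chrom}, \code{pos},
#' \code{gene}, \code{tss}, \code{strand}, \code{region_class} (and
#' optionally \code{distance_to_tss}). \code{gene} may be empty for
#' intergenic probes.
#'
#' @param path input TSV path.
#' @return a data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("probe_id", "chrom", "pos", "gene", "region_class")
  miss <- setdiff(required, colnames(ann))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe ids in annotation")
  if (any(ann$pos < 1)) stop("annotation positions must be >= 1 (1-based)")
  ok <- ann$region_class %in%
    c("gene_body", "promoter", "utr", "upstream", "intergenic")
  if (!all(ok))
    stop("unknown region_class: ", paste(unique(ann$region_class[!ok]), collapse = ", "))
  ann
}

#' @rdname read_probe_annotation
#' @param ann annotation data.frame.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (anatomical site and 3-D coordinates)
#'
#' Tab-delimited with columns \code{sample_id}, \code{site},
#' \code{x}, \code{y}, \code{z} (mm) and \code{collection}
#' (\code{primary} or \code{autopsy}); at most one sample may be primary.
#'
#' @param path input TSV path.
#' @return a data.frame with one row per sample.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "site", "x", "y", "z", "collection")
  miss <- setdiff(required, colnames(meta))
  if (length(miss))
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids")
  if (sum(meta$collection == "primary") > 1L)
    stop("at most one sample may be flagged primary")
  meta
}

#' @rdname read_sample_meta
#' @param meta metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
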