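#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Lines with fewer than three fields are rejected.
#'
#' @param path file path.
#' @return named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ", short[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read and write SEG segment tables
#'
#' Tab-delimited columns: \code{sample_id}, \code{chrom}, \code{start},
#' \code{end}, \code{n_probes}, \code{mean_log2} and (optionally)
#' \code{call}. Coordinates are 1-based, closed.
#'
#' @param path file path.
#' @return a data.frame of segments.
#' @export
read_seg <- function(path) {
  seg <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "chrom", "start", "end", "n_probes", "mean_log2")
  miss <- setdiff(required, colnames(seg))
  if (length(miss))
    stop("SEG missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(seg$end < seg$start)
  if (length(bad))
    stop(sprintf("SEG row %d has end < start", bad[1L]))
  seg
}

#' @rdname read_seg
#' @param seg segments data.frame.
#' @export
write_seg <- function(seg, path) {
  bad <- which(seg$end < seg$start)
  if (length(bad))
    stop(sprintf("SEG row %d has end < start", bad[1L]))
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape}, kept so every on-disk format the pipeline
#' touches has a matching reader/writer pair with validation.
#'
#' @param path file path.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo} object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
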