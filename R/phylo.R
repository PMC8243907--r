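#' Build a rooted sample phylogeny by neighbor joining
#'
#' Runs neighbor joining on a symmetric, non-negative, zero-diagonal
#' sample-distance matrix (methylation distances), clamps any negative NJ
#' branch lengths to zero (a standard NJ artifact; clamps are reported via
#' \code{message()}), and roots the tree on the edge adjacent to the given
#' root sample, following the convention that recurrences diverged from the
#' primary tumor.
#'
#' @param d symmetric distance matrix (or \code{dist}) over samples.
#' @param root_sample sample id to root on (typically the primary sample).
#' @return an \code{ape::phylo} rooted tree whose tips are the sample ids,
#'   with branch lengths in methylation-distance units.
#' @export
build_phylogeny <- function(d, root_sample) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distance matrix must be non-negative")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (!root_sample %in% rownames(m)) stop("root_sample not in sample set")
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("build_phylogeny: clamped %d negative branch length(s) to 0",
                    sum(neg)))
    tr$edge.length[neg] <- 0
  }
  ape::root(tr, outgroup = root_sample, resolve.root = TRUE)
}

#' Infer an anatomical spread path from a rooted phylogeny
#'
#' Traverses the phylogeny depth-first starting at the origin sample (the
#' primary tumor), visiting at each node the unexplored branches in order
#' of increasing methylation branch length (the nearer clone first).
#' Degree-2 internal nodes -- the artifact of rooting a tree on an edge --
#' are passed through transparently with their branch lengths summed, so a
#' two-leaf tree yields the single edge between the two samples. Every
#' traversal edge is annotated with the Euclidean anatomical distance (mm)
#' between its endpoints; an internal node inherits the centroid of its
#' descendant-side leaves' coordinates.
#'
#' @param tree a rooted \code{ape::phylo} whose tips are sample ids.
#' @param meta sample metadata data.frame with \code{sample_id}, \code{x},
#'   \code{y}, \code{z} (mm) and optionally \code{collection}.
#' @param origin tip to start from; defaults to the sample flagged
#'   \code{primary} in \code{meta}, else the first tip.
#' @return data.frame of class \code{"spread_path"}: one row per traversal
#'   edge with \code{from}, \code{to}, \code{meth_dist} and
#'   \code{anat_dist_mm}, in traversal order starting at the origin.
#' @export
infer_spread_path <- function(tree, meta, origin = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tips <- tree$tip.label
  miss <- setdiff(tips, meta$sample_id)
  if (length(miss))
    stop("missing coordinates for sample(s): ", paste(miss, collapse = ", "))
  if (is.null(origin))
    origin <- if ("collection" %in% colnames(meta) &&
                  any(meta$collection == "primary" & meta$sample_id %in% tips))
      meta$sample_id[meta$collection == "primary" & meta$sample_id %in% tips][1L]
    else tips[1L]
  if (!origin %in% tips) stop("origin is not a tip of the tree")
  coords <- as.matrix(meta[match(tips, meta$sample_id), c("x", "y", "z")])
  rownames(coords) <- tips

  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  node_xyz <- matrix(NA_real_, n_node, 3L)
  node_xyz[seq_len(n_tip), ] <- coords
  for (v in (n_tip + 1L):n_node) {
    below <- tips_below(tree, v)
    node_xyz[v, ] <- colMeans(coords[below, , drop = FALSE])
  }
  node_label <- c(tips, paste0("node", (n_tip + 1L):n_node))

  # undirected adjacency
  edges <- rbind(tree$edge, tree$edge[, 2:1])
  lens <- c(tree$edge.length, tree$edge.length)
  deg <- tabulate(edges[, 1L], n_node)
  visited <- logical(n_node)
  rows <- list()
  start <- match(origin, tips)
  visit <- function(v) {
    visited[v] <<- TRUE
    nb_rows <- which(edges[, 1L] == v & !visited[edges[, 2L]])
    nb_rows <- nb_rows[order(lens[nb_rows])]
    for (r in nb_rows) {
      w <- edges[r, 2L]
      if (visited[w]) next
      len <- lens[r]
      # pass through chains of degree-2 internal nodes (rooting artifacts)
      while (w > n_tip && deg[w] == 2L) {
        visited[w] <<- TRUE
        nxt <- which(edges[, 1L] == w & !visited[edges[, 2L]])
        if (!length(nxt)) break
        len <- len + lens[nxt[1L]]
        w <- edges[nxt[1L], 2L]
      }
      if (visited[w]) next
      rows[[length(rows) + 1L]] <<- data.frame(
        from = node_label[v], to = node_label[w],
        meth_dist = len,
        anat_dist_mm = sqrt(sum((node_xyz[v, ] - node_xyz[w, ])^2)),
        stringsAsFactors = FALSE)
      visit(w)
    }
  }
  visit(start)
  out <- do.call(rbind, rows)
  class(out) <- c("spread_path", class(out))
  out
}

# tip labels of all leaves below node v (v may itself be a tip)
tips_below <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(tree$tip.label[v])
  acc <- character(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == u, 2L]
    acc <- c(acc, tree$tip.label[kids[kids <= n_tip]])
    stack <- c(stack, kids[kids > n_tip])
  }
  acc
}
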