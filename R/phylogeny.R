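#' Pairwise distance between two aligned sequences
#'
#' The family's evolutionary distance: the number of aligned columns where
#' both sequences carry a residue and the residues differ, divided by the
#' smaller of the two ungapped sequence lengths. Ranges over \[0, 1\] for
#' homologous proteins and equals the classic p-distance when neither
#' sequence is gapped.
#'
#' @param a,b Aligned sequences (equal aligned length, gaps as `-`).
#' @return A number in \[0, 1\].
#' @examples
#' pairwise_distance("AAAT", "AAAA")  # 0.25
#' @export
pairwise_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    pc_error("aligned lengths differ", "validation_error")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- sum(ca != "-"); lb <- sum(cb != "-")
  if (la == 0L && lb == 0L)
    pc_error("both sequences are all-gap; distance undefined", "distance_error")
  if (la == 0L || lb == 0L)
    pc_error("a sequence is all-gap; distance undefined", "distance_error")
  diff <- sum(ca != "-" & cb != "-" & ca != cb)
  diff / min(la, lb)
}

#' Pairwise distance matrix of a family
#'
#' @param family An [aligned_family].
#' @return Symmetric numeric matrix with zero diagonal; dimnames are the
#'   sequence ids in family order.
#' @export
distance_matrix <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  ids <- names(family$seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- pairwise_distance(family$seqs[[i]], family$seqs[[j]])
  }
  d
}

validate_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    pc_error("distance matrix must be square", "validation_error")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (any(D < 0))
    pc_error("distance matrix has negative entries", "validation_error")
  if (max(abs(D - t(D))) > 1e-12)
    pc_error("distance matrix is not symmetric", "validation_error")
  D
}

# Format branch lengths for newick assembly without precision loss.
fmt_bl <- function(x) sprintf("%.15g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: repeatedly joins the pair
#' minimizing the Q-criterion and assigns limb lengths by the usual
#' formulas until three nodes remain, which are joined at an unresolved
#' central node. Ties in the Q minimum are broken deterministically by the
#' lowest (row, column) index pair in input order. Negative limb lengths
#' are clamped to zero; the total clamped amount is attached as attribute
#' `"clamped_deficit"`.
#'
#' @param D Symmetric distance matrix with dimnames (e.g. from
#'   [distance_matrix()]).
#' @return An unrooted tree of class `phylo` (see [ape::read.tree()]).
#' @examples
#' D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(D)$edge.length  # limbs 0.05, 0.15, 0.25
#' @export
neighbor_joining <- function(D) {
  D <- validate_dist(D)
  n <- nrow(D)
  if (n < 2L) pc_error("need >= 2 taxa", "validation_error")
  labels <- rownames(D)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], fmt_bl(D[1, 2] / 2),
                   labels[2], fmt_bl(D[1, 2] / 2))
    tr <- ape::read.tree(text = nwk)
    attr(tr, "clamped_deficit") <- deficit
    return(tr)
  }
  # node labels carry partial newick strings as joining proceeds
  nodes <- labels
  while (length(nodes) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest (i, j), i < j, among minima: scan column-major over upper triangle
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      if (Q[i, j] < qmin - 1e-15) { qmin <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_bl(li),
                        nodes[j], fmt_bl(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- pmax(dk, 0)
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    dimnames(D2) <- list(seq_along(nodes), seq_along(nodes))
    D <- D2
  }
  # closed-form star resolution of the final three nodes
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_bl(la),
                 nodes[2], fmt_bl(lb), nodes[3], fmt_bl(lc))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' Root a tree on the edge leading to an outgroup
#'
#' Places the root on the terminal edge of the outgroup leaf, splitting it
#' at `fraction` of its length measured from the outgroup tip (default:
#' midpoint). All leaf-to-leaf path lengths are preserved.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_id Leaf label to root with.
#' @param fraction Where along the outgroup edge the root goes, as the
#'   fraction of the edge length on the outgroup side (default 0.5).
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id, fraction = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup_id, tree$tip.label)
  if (is.na(tip))
    pc_error(sprintf("outgroup '%s' is not a leaf of the tree", outgroup_id),
             "lookup_error")
  edge_i <- which(tree$edge[, 2] == tip)
  len <- tree$edge.length[edge_i]
  rooted <- phytools::reroot(tree, tip, position = fraction * len)
  rooted
}

#' Read / write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so the
#' command-line interface and pipeline share one entry point.
#' @param path File path.
#' @param tree A `phylo` tree.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
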