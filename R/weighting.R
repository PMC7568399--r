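#' Branch-length sequence weights from a rooted tree
#'
#' Converts the branch lengths of a rooted phylogeny into per-sequence
#' weights that down-weight over-represented subfamilies. The raw weight of
#' leaf *a* is the sum, over the edges on the root-to-*a* path, of each
#' edge's length divided by the number of (non-outgroup) leaves below that
#' edge — the Gerstein–Sonnhammer–Chothia scheme also used for ClustalW
#' alignment weights. Edges shared by a whole clade are split evenly among
#' its members, so k near-identical copies of a sequence share what a single
#' copy would have received. Weights are normalized to sum to one.
#'
#' @param tree A rooted `phylo` tree (see [root_with_outgroup()]).
#' @param outgroup_id Optional leaf label excluded from the weights and from
#'   all leaf counts (it exists only to place the root).
#' @param epsilon_factor A leaf whose root path has zero total length gets
#'   `epsilon_factor * mean(raw weights)` before normalization (default
#'   1e-8), so no sequence is silently dropped.
#' @param rooted Whether to treat the tree as rooted. Defaults to
#'   [ape::is.rooted()]; pass `TRUE` for a deliberately rooted basal
#'   polytomy (e.g. a star tree with the root at its center), which ape
#'   cannot distinguish from an unrooted tree.
#' @return Named numeric vector of normalized weights (sums to 1), one per
#'   non-outgroup leaf; raw pre-normalization weights are attached as
#'   attribute `"raw"`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' branch_weights(tr)  # (0.3, 0.3, 0.4)
#' @export
branch_weights <- function(tree, outgroup_id = NULL, epsilon_factor = 1e-8,
                           rooted = ape::is.rooted(tree)) {
  stopifnot(inherits(tree, "phylo"))
  if (!rooted)
    pc_error("tree must be rooted (see root_with_outgroup)", "precondition_error")
  tips <- tree$tip.label
  weighted_tips <- setdiff(tips, outgroup_id)
  if (length(weighted_tips) < 2L)
    pc_error("need >= 2 non-outgroup leaves", "precondition_error")
  if (is.null(tree$edge.length))
    pc_error("tree has no branch lengths", "precondition_error")

  raw <- stats::setNames(numeric(length(weighted_tips)), weighted_tips)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  for (e in seq_len(nrow(tree$edge))) {
    below <- tips[desc[[e]]]
    below <- setdiff(below, outgroup_id)
    k <- length(below)
    if (k == 0L) next
    raw[below] <- raw[below] + tree$edge.length[e] / k
  }
  if (all(raw == 0)) {
    pc_warning("all branch lengths are zero; returning uniform weights",
               "degenerate_tree_warning")
    w <- rep(1 / length(raw), length(raw))
    names(w) <- names(raw)
    attr(w, "raw") <- raw
    return(w)
  }
  eps <- epsilon_factor * mean(raw)
  raw[raw == 0] <- eps
  w <- raw / sum(raw)
  attr(w, "raw") <- raw
  w
}

#' Write sequence weights as TSV
#'
#' @param weights Output of [branch_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  df <- data.frame(sequence_id = names(weights),
                   raw_weight = as.numeric(attr(weights, "raw")),
                   normalized_weight = as.numeric(weights))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
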