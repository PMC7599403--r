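# Weighted UniFrac beta diversity. The raw (unnormalized) form is
# d(A,B) = sum over branches b of length(b) * |p_A(b) - p_B(b)|, where
# p_X(b) is the fraction of sample X's reads on tips descending from b.

#' Weighted UniFrac distances between samples
#'
#' Computes pairwise weighted UniFrac dissimilarities from an OTU count
#' matrix and a rooted phylogeny whose tips are OTU identifiers. Counts are
#' converted to within-sample proportions, so the distance is invariant to
#' sequencing depth. Tips absent from the count matrix contribute zero
#' weight; OTUs with non-zero counts that are missing from the tree are an
#' error.
#'
#' @param counts samples x OTUs integer matrix with OTU column names.
#' @param tree rooted `phylo` tree with non-negative branch lengths.
#' @param normalized if `TRUE`, divide each pairwise distance by its maximum
#'   attainable value `sum_j (p_A(j) + p_B(j)) * depth(j)` over tips j
#'   (root-to-tip branch-length depth), scaling it into [0, 1].
#' @return a `dist` object over the samples.
#' @export
weighted_unifrac <- function(counts, tree, normalized = FALSE) {
  counts <- .check_counts(counts)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' tree")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree must have finite, non-negative branch lengths")
  present <- colnames(counts)[colSums(counts) > 0]
  offenders <- setdiff(present, tree$tip.label)
  if (length(offenders))
    stop("OTUs with reads but no tree tip: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ...")

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_samp <- nrow(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) stop("sample(s) with zero total reads")

  # per-node proportion mass, accumulated tips-up in postorder
  prop <- matrix(0, n_node, n_samp)
  idx <- match(tree$tip.label, colnames(counts))
  has <- !is.na(idx)
  prop[which(has), ] <- t(counts[, idx[has], drop = FALSE] / totals)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    prop[tr$edge[e, 1], ] <- prop[tr$edge[e, 1], ] + prop[tr$edge[e, 2], ]

  # branch-weighted profile per sample; manhattan distance gives the sum
  weighted <- prop[tr$edge[, 2], , drop = FALSE] * tr$edge.length
  d <- stats::dist(t(weighted), method = "manhattan")
  attr(d, "Labels") <- rownames(counts)
  if (normalized) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
    tipmass <- prop[seq_len(n_tip), , drop = FALSE]
    scale <- outer(colSums(tipmass * depth), colSums(tipmass * depth), "+")
    d[] <- as.vector(d) / as.dist(scale)
  }
  d
}
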