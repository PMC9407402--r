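#' Neighbour-joining tree from a distance matrix
#'
#' Builds an unrooted neighbour-joining (Saitou-Nei) topology from a
#' symmetric, zero-diagonal distance matrix via [ape::nj()], then clamps
#' any negative branch lengths to zero. Used both for the PAV tree
#' (distances `1 - Jaccard`, see [pav_distance()]) and the SNP tree
#' (allele-sharing distances, see [snp_distance_matrix()]).
#'
#' @param d Symmetric distance matrix with zero diagonal and row/column
#'   labels, or a `dist` object.
#' @param path Optional file; when given the tree is also written there in
#'   Newick format.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d, path = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be a square matrix")
  if (nrow(d) < 3L) abort("neighbour joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("`d` must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) abort("`d` must have a zero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  if (!is.null(path)) ape::write.tree(tree, file = path)
  tree
}
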