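## Thin, validating wrappers around ape for the Newick plumbing the pipeline
## needs, plus the two tree-derived matrices used downstream: patristic
## distances (delimitation divergence alternative) and the Brownian-motion
## variance-covariance matrix (phylogenetic signal).

#' Read a Newick tree
#'
#' @param path path to a Newick file containing a single tree.
#' @param text optional Newick string, used instead of `path`.
#' @return an `ape::phylo` tree.  Duplicate leaf labels are an error.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 10 significant digits so that a
#' read/write round trip preserves topology and lengths.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Patristic distances between the leaves of a tree
#'
#' `d(i, j)` is the sum of branch lengths along the path between leaves `i`
#' and `j`.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, ordered as
#'   `tree$tip.label`.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Brownian-motion variance-covariance matrix of a rooted tree
#'
#' `V[i, j]` is the depth (distance from the root) of the most recent common
#' ancestor of leaves `i` and `j`: the expected trait covariance under
#' Brownian motion.  The diagonal holds root-to-tip distances.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @return symmetric positive semidefinite matrix ordered as `tree$tip.label`.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ## a star phylogeny (every tip attached at the root) counts as rooted:
  ## its Brownian covariance is simply diagonal
  n_tip <- length(tree$tip.label)
  is_star <- sum(tree$edge[, 1] == n_tip + 1) == n_tip
  if (!ape::is.rooted(tree) && !is_star) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  v <- ape::vcv.phylo(tree)
  v[tree$tip.label, tree$tip.label]
}
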