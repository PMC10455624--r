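#' Read a phylogenetic tree from a newick file
#'
#' Parses a newick tree and validates it for patristic-distance analysis:
#' tip labels must be unique and every edge must carry a non-negative branch
#' length (in substitutions/site, as written by maximum-likelihood programs
#' such as RAxML). Trees without branch lengths are rejected unless
#' `assume_unit_lengths = TRUE`, which substitutes 1.0 on every edge for
#' topology-only exploration.
#'
#' @param path path to a newick file.
#' @param assume_unit_lengths replace missing branch lengths by 1.0 instead
#'   of failing (default `FALSE`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, assume_unit_lengths = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse newick file ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse newick file ", path)
  validate_tree(tree, assume_unit_lengths = assume_unit_lengths)
}

validate_tree <- function(tree, assume_unit_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (!assume_unit_lengths)
      stop("tree has missing branch lengths; patristic distances need them ",
           "(set assume_unit_lengths = TRUE to substitute 1.0)")
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(1, nrow(tree$edge))
    else tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  tree
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Pairwise tip-to-tip distances: the sum of branch lengths along the unique
#' path between each pair of tips, as used for the phylogenetic variant of
#' the barcode-gap analysis. Computed with [ape::cophenetic.phylo()].
#'
#' @param tree a `phylo` tree with branch lengths (see [read_tree()]).
#' @param assume_unit_lengths see [read_tree()].
#' @return A [distance_matrix()] with `model = "cophenetic"`.
#' @export
cophenetic_matrix <- function(tree, assume_unit_lengths = FALSE) {
  tree <- validate_tree(tree, assume_unit_lengths = assume_unit_lengths)
  if (length(tree$tip.label) < 2L) stop("need at least 2 tips")
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label, drop = FALSE]
  distance_matrix(m, model = "cophenetic")
}
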