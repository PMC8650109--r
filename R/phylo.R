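#' Parse a Newick tree with validation
#'
#' Reads a rooted phylogeny from a Newick string or file and validates it for
#' use in phylogenetic null models: tip labels must be unique, every edge must
#' carry a branch length, and no branch length may be negative. Zero-length
#' branches are permitted (tree inference programs routinely emit them);
#' multifurcations are permitted.
#'
#' @param text Newick string. Exactly one of `text` or `file` must be given.
#' @param file Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object that passed validation.
#' @examples
#' tr <- read_phylo("((A:1,B:1):1,(C:1,D:1):1);")
#' tr$tip.label
#' @export
read_phylo <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree))
    stop("malformed Newick: no tree could be parsed", call. = FALSE)
  validate_phylo(tree)
  tree
}

#' Validate a phylogeny for null modeling
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  invisible(tree)
}

#' Patristic (cophenetic) distances between tips
#'
#' Entry (i, j) is the sum of branch lengths along the path between tips i
#' and j. This matrix is the substrate of betaMNTD and of the taxon-shuffling
#' null model.
#'
#' @param tree A validated `phylo` object.
#' @return A symmetric matrix with zero diagonal, labelled by tip.
#' @examples
#' patristic_distances(read_phylo("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
patristic_distances <- function(tree) {
  validate_phylo(tree)
  dm <- ape::cophenetic.phylo(tree)
  dm[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Shuffle taxon identities of a distance matrix
#'
#' Applies one uniform random permutation to the rows and columns of a taxon
#' distance matrix. This is the null randomization used for betaMNTD: labels
#' are shuffled across the phylogeny while the tree shape (hence the
#' multiset of pairwise distances) is conserved.
#'
#' @param dm Square labelled distance matrix.
#' @return A matrix with the same labels in the same order, whose values are
#'   those of `dm` under a random relabelling of taxa.
#' @export
shuffle_taxon_identities <- function(dm) {
  check_distance_matrix(dm)
  p <- sample.int(nrow(dm))
  out <- dm[p, p, drop = FALSE]
  dimnames(out) <- dimnames(dm)
  out
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm)) || !identical(rownames(dm), colnames(dm)))
    stop("distance matrix must have identical row and column labels")
  if (any(dm < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  invisible(dm)
}

#' Prune a tree and abundance table to their shared taxa
#'
#' Taxa present in the table but absent from the tree are a hard error in the
#' analysis functions; this utility performs the intersection explicitly so
#' that dropping taxa is always a visible, deliberate step.
#'
#' @param tree A `phylo` object.
#' @param counts Sample-by-taxon abundance matrix.
#' @return A list with elements `tree` (pruned) and `counts` (columns
#'   restricted to shared taxa, in tree tip order).
#' @export
prune_to_shared <- function(tree, counts) {
  validate_phylo(tree)
  shared <- intersect(tree$tip.label, colnames(counts))
  if (length(shared) < 2)
    stop("fewer than two taxa shared between tree and table")
  tree2 <- ape::keep.tip(tree, shared)
  list(tree = tree2, counts = counts[, tree2$tip.label, drop = FALSE])
}

#' Read or write a labelled distance matrix as TSV
#'
#' @param path File path.
#' @param dm Square labelled matrix.
#' @return `read_distance_matrix` returns the matrix; `write_distance_matrix`
#'   returns `path` invisibly.
#' @export
read_distance_matrix <- function(path) {
  x <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  check_distance_matrix(x)
  x
}

#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(dm, path) {
  check_distance_matrix(dm)
  df <- data.frame(taxon = rownames(dm), dm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
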