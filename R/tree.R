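#' Parse a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] accepting a Newick string or a file
#' path, with an explicit parse error on malformed input. Branch lengths and
#' internal labels are optional; polytomies are allowed.
#'
#' @param x A Newick string or the path to a Newick file.
#' @return A `phylo` tree.
#' @export
#' @examples
#' parse_newick("((A:1,B:2):3,C:4);")
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- tryCatch(
    if (file.exists(x) && !grepl("\\(", x)) ape::read.tree(file = x)
    else ape::read.tree(text = x),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tr)) {
    abort(sprintf("malformed Newick input near character %d",
                  regexpr("[^(),:;A-Za-z0-9_. '-]", x)[1]))
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

new_dist_matrix <- function(m, source, units) {
  m <- m[order(rownames(m)), order(colnames(m))]
  attr(m, "source") <- source
  attr(m, "units") <- units
  m
}

#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j. Path distances are invariant under rerooting.
#'
#' @param tree A `phylo` tree with branch lengths on every edge.
#' @return A symmetric labeled matrix (labels sorted), zero diagonal, with
#'   attributes `source = "patristic"` and `units = "branch length"`.
#' @export
#' @examples
#' patristic_matrix(parse_newick("((A:1,B:2):3,C:4);"))
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort(paste("tree has no branch lengths;",
                "use topological_matrix() for edge-count distances"))
  }
  new_dist_matrix(stats::cophenetic(tree), "patristic", "branch length")
}

#' Topological (edge-count) distance matrix
#'
#' Entry (i, j) is the number of edges on the path between leaves i and j -
#' the distance used when a phylogeny carries no branch lengths.
#'
#' @param tree A `phylo` tree (branch lengths ignored).
#' @return A symmetric labeled integer matrix with attributes
#'   `source = "topological"` and `units = "edges"`.
#' @export
topological_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  m <- round(stats::cophenetic(t2))
  storage.mode(m) <- "integer"
  new_dist_matrix(m, "topological", "edges")
}

#' Tree distance matrix with automatic fallback
#'
#' Patristic distances when the tree has branch lengths, topological
#' otherwise.
#'
#' @param tree A `phylo` tree, or an already-computed labeled matrix
#'   (returned unchanged).
#' @return A symmetric labeled matrix.
#' @export
tree_distance_matrix <- function(tree) {
  if (is.matrix(tree)) return(tree)
  if (!is.null(tree$edge.length)) patristic_matrix(tree)
  else topological_matrix(tree)
}

#' Extract a clade by internal-node label
#'
#' For trees with named internal nodes (GTDB-style clade labels), returns the
#' subtree rooted at the named node.
#'
#' @param tree A `phylo` tree with `node.label`s.
#' @param label The internal node label.
#' @return A `phylo` subtree.
#' @export
extract_clade <- function(tree, label) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) abort("tree has no internal node labels")
  i <- match(label, tree$node.label)
  if (is.na(i)) abort(sprintf("no internal node labelled '%s'", label))
  ape::extract.clade(tree, node = length(tree$tip.label) + i)
}

#' Long form of a labeled distance matrix
#'
#' @param m A symmetric labeled matrix.
#' @param value Name of the value column.
#' @return A tibble with columns `query`, `reference` (query < reference
#'   lexicographically) and the value column, one row per unordered pair.
#' @export
dist_long <- function(m, value = "distance") {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  labs <- sort(rownames(m))
  pairs <- utils::combn(labs, 2)
  out <- tibble::tibble(
    query = pairs[1, ], reference = pairs[2, ]
  )
  out[[value]] <- m[cbind(pairs[1, ], pairs[2, ])]
  out
}
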