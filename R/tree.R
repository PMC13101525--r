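#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the
#' diversity module relies on: a single rooted tree, unique leaf labels and
#' branch lengths present. Single-leaf trees (e.g. `"A:3;"`), which
#' `ape::read.tree` cannot represent, are handled explicitly so that
#' Faith's PD stays total.
#'
#' @param path Newick file path.
#' @param text Newick string, as an alternative to `path`.
#' @return an object of class `phylo` (or `singleton_tree` for the
#'   one-leaf case, a list with `tip.label` and `edge.length`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  ## ape cannot build a phylo object with a single tip
  if (!grepl("\\(", text)) {
    m <- regmatches(text, regexec("^([^:;,()]+):([0-9.eE+-]+);?$", text))[[1]]
    if (length(m) != 3) stop("malformed Newick string: ", text)
    out <- list(tip.label = m[2], edge.length = as.numeric(m[3]))
    class(out) <- "singleton_tree"
    return(out)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick string")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found several")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Total branch length of a tree
#' @param tree a `phylo` or `singleton_tree` object.
#' @return sum of all branch lengths.
#' @export
total_branch_length <- function(tree) {
  if (inherits(tree, "singleton_tree")) return(tree$edge.length)
  sum(tree$edge.length)
}

## Faith's PD, root-inclusive: total length of the branches on the paths
## from every present leaf up to the root. Works directly on the phylo
## edge matrix so one-leaf subsets and singleton trees behave.
faith_pd <- function(tree, present) {
  if (length(present) == 0) return(0)
  if (inherits(tree, "singleton_tree")) {
    if (!all(present %in% tree$tip.label))
      stop("taxa absent from tree: ",
           paste(setdiff(present, tree$tip.label), collapse = ", "))
    return(tree$edge.length)
  }
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  tips <- match(present, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  keep <- logical(max(tree$edge))
  for (tip in tips) {
    node <- tip
    while (node != 0 && !keep[node]) {
      keep[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(elen[keep])
}
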