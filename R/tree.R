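#' Parse a Newick tree with validation
#'
#' Reads a rooted phylogeny from a Newick string or file and validates it for
#' downstream comparative analyses: unique non-empty tip labels, non-negative
#' branch lengths, a single root. Polytomies (including a basal trifurcation
#' from an unrooted input) are preserved and treated as rooted polytomies.
#' Trees without branch lengths get unit lengths with a warning, because the
#' parsimony stages are length-free but the Mk and regression stages are not.
#'
#' @param x Newick string, or path to a file containing one.
#' @return An [ape::phylo] object (tips `1..n`, root `n + 1`).
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(x) {
  txt <- if (length(x) == 1 && !grepl("(", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse error: malformed tree text")
  if (inherits(tr, "multiPhylo")) abort("expected a single tree, found several")
  validate_tree(tr)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) abort("empty tip label")
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    abort(paste0("duplicate tip labels: ", paste(unique(dup), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting every branch to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warn("missing branch lengths; defaulting them to 1")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(paste0("negative branch length (", tree$edge.length[bad],
                 ") on the edge to node ", tree$edge[bad, 2]))
  }
  tree
}

#' Tip labels descending from a node
#'
#' @param tree A `phylo` object.
#' @param node Integer node id (tips are `1..Ntip`, root is `Ntip + 1`), or a
#'   tip label.
#' @return Character vector of tip labels in the clade.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' clade_tips(tr, ape::Ntip(tr) + 1)  # root: all tips
#' @export
clade_tips <- function(tree, node) {
  node <- resolve_node(tree, node)
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  # iterative stack descent, no recursion limit worries
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v) else stack <- c(stack, kids[[as.character(v)]])
  }
  tree$tip.label[sort(out)]
}

#' Sister node(s) of a node
#'
#' For a node whose parent is binary, the unique other child; at a polytomy,
#' the full set of co-children is returned and the caller decides how to use
#' the tie-set.
#'
#' @inheritParams clade_tips
#' @return Integer node id(s); tip ids are named with their labels.
#' @examples
#' tr <- parse_newick("(A,B,C);")
#' sister_of(tr, "A")  # polytomy: tie-set {B, C}
#' @export
sister_of <- function(tree, node) {
  node <- resolve_node(tree, node)
  root <- ape::Ntip(tree) + 1L
  if (node == root) abort("the root has no sister")
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
  nm <- ifelse(sibs <= ape::Ntip(tree), tree$tip.label[sibs], NA)
  setNames(sibs, nm)
}

resolve_node <- function(tree, node) {
  if (is.character(node)) {
    idx <- match(node, tree$tip.label)
    if (is.na(idx)) abort(paste0("unknown tip label: ", node))
    return(idx)
  }
  node <- as.integer(node)
  if (node < 1 || node > ape::Ntip(tree) + tree$Nnode) {
    abort(paste0("unknown node id: ", node))
  }
  node
}

#' Root-to-tip depth of a tree
#'
#' Maximum root-to-tip path length; the unit in which Mk transition rates are
#' expressed after rescaling.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A single non-negative number.
#' @export
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Rescale a tree to a given depth
#'
#' @param tree A `phylo` object.
#' @param depth Target root-to-tip depth (default 1).
#' @return The rescaled tree.
#' @export
rescale_tree_depth <- function(tree, depth = 1) {
  d <- tree_depth(tree)
  if (d <= 0) abort("tree has zero depth; cannot rescale")
  tree$edge.length <- tree$edge.length * (depth / d)
  tree
}

# children of each node as a list indexed by node id character
node_children <- function(tree) split(tree$edge[, 2], tree$edge[, 1])
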