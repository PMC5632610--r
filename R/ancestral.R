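#' Parsimony trace of a binary character
#'
#' Minimum number of state changes of a binary character on a tree, plus the
#' set of states each node can take in at least one most-parsimonious
#' reconstruction (MPR). Computed by a unit-cost dynamic program (down-pass
#' subtree costs, up-pass outside costs), which coincides with Fitch parsimony
#' on binary trees and stays exact at polytomies. Branch lengths are ignored.
#'
#' @param tree A `phylo` object.
#' @param states Named 0/1 vector over tips; missing tips (or `NA`) are free
#'   and get whichever state is parsimonious.
#' @return An object of class `parsimony_trace`: `min_changes`,
#'   `node_states` (tibble with `node`, `state_set` as `"0"`, `"1"` or
#'   `"01"`), and the tree.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch_trace(tr, c(A = 0, B = 0, C = 1, D = 1))$min_changes  # 1
#' @export
fitch_trace <- function(tree, states) {
  st <- align_tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  INF <- ntot + 1  # more than any possible number of changes
  down <- matrix(0, ntot, 2)  # min changes in subtree given node state 0/1
  for (i in seq_len(ntip)) {
    if (st[i] == 0) down[i, 2] <- INF
    if (st[i] == 1) down[i, 1] <- INF
  }
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]
    down[p, 1] <- down[p, 1] + min(down[ch, 1], down[ch, 2] + 1)
    down[p, 2] <- down[p, 2] + min(down[ch, 2], down[ch, 1] + 1)
  }
  root <- ntip + 1L
  min_changes <- min(down[root, ])
  # up-pass: cost of the rest of the tree given this node's state
  up <- matrix(0, ntot, 2)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  kids <- node_children(tree)
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; ch <- pre[e, 2]
    sibs <- setdiff(kids[[as.character(p)]], ch)
    sib_cost <- c(0, 0)
    for (s in sibs) {
      sib_cost[1] <- sib_cost[1] + min(down[s, 1], down[s, 2] + 1)
      sib_cost[2] <- sib_cost[2] + min(down[s, 2], down[s, 1] + 1)
    }
    for (sc in 1:2) {
      up[ch, sc] <- min(up[p, 1] + sib_cost[1] + (sc != 1),
                        up[p, 2] + sib_cost[2] + (sc != 2))
    }
  }
  total <- down + up
  in_mpr <- total == min_changes
  set_str <- apply(in_mpr, 1, function(z) paste(c("0", "1")[z], collapse = ""))
  out <- structure(list(
    min_changes = as.integer(min_changes),
    node_states = tibble(node = seq_len(ntot), state_set = set_str),
    tree = tree
  ), class = "parsimony_trace")
  stopifnot((min_changes == 0) ==
              (length(unique(st[st >= 0])) <= 1))
  out
}

#' @export
print.parsimony_trace <- function(x, ...) {
  cat(sprintf("Parsimony trace: %d change(s); %d node(s) ambiguous\n",
              x$min_changes, sum(x$node_states$state_set == "01")))
  invisible(x)
}

#' Squared-change parsimony trace of a continuous character
#'
#' Assigns internal-node values minimizing the sum of squared changes over
#' edges, by solving the stationarity system in which every internal node
#' equals the mean of its neighbours (a discrete Laplace problem; tip values
#' stay fixed). Unweighted by default (branch lengths ignored, the convention
#' for a length-free visualization aid); `weighted = TRUE` divides each
#' squared change by the branch length.
#'
#' @param tree A `phylo` object.
#' @param values Named numeric vector over all tips (e.g. host diversity).
#' @param weighted Weight changes by inverse branch length?
#' @return An object of class `continuous_trace`: `node_values` (numeric over
#'   all node ids, tips first) and `objective` (the minimized sum).
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' squared_change_trace(tr, c(A = 0, B = 2))$node_values  # root = 1
#' @export
squared_change_trace <- function(tree, values, weighted = FALSE) {
  ntip <- ape::Ntip(tree)
  if (!setequal(names(values), tree$tip.label)) {
    abort("`values` must cover every tip, named by tip label")
  }
  vals <- unname(values[tree$tip.label])
  ntot <- ntip + tree$Nnode
  internal <- (ntip + 1L):ntot
  w <- if (weighted) 1 / tree$edge.length else rep(1, nrow(tree$edge))
  if (any(!is.finite(w))) abort("weighted trace requires positive branch lengths")
  A <- matrix(0, tree$Nnode, tree$Nnode)
  b <- numeric(tree$Nnode)
  idx <- function(v) v - ntip
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    A[idx(p), idx(p)] <- A[idx(p), idx(p)] + w[e]
    if (ch > ntip) {
      A[idx(ch), idx(ch)] <- A[idx(ch), idx(ch)] + w[e]
      A[idx(p), idx(ch)] <- A[idx(p), idx(ch)] - w[e]
      A[idx(ch), idx(p)] <- A[idx(ch), idx(p)] - w[e]
    } else {
      b[idx(p)] <- b[idx(p)] + w[e] * vals[ch]
    }
  }
  x <- solve(A, b)
  node_values <- c(vals, x)
  obj <- sum(w * (node_values[tree$edge[, 1]] - node_values[tree$edge[, 2]])^2)
  structure(list(node_values = setNames(node_values, seq_len(ntot)),
                 objective = obj),
            class = "continuous_trace")
}

#' @export
print.continuous_trace <- function(x, ...) {
  cat(sprintf("Squared-change trace: objective = %.6g over %d nodes\n",
              x$objective, length(x$node_values)))
  invisible(x)
}
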