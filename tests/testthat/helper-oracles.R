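# Independent oracles, deliberately naive: exhaustive enumeration and generic
# optimization, never the package's own algorithms.

# All rooted binary labeled topologies on `labels` as Newick strings (unit
# branch lengths). Recursion: split the label set into {subset containing the
# first label} x {rest}, combine all subtrees; each unordered topology arises
# exactly once.
all_rooted_topologies <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  out <- character(0)
  rest <- labels[-1]
  for (k in 0:(n - 2)) {
    picks <- utils::combn(rest, k, simplify = FALSE)
    for (p in picks) {
      left <- c(labels[1], p)
      right <- setdiff(labels, left)
      for (lt in all_rooted_topologies(left)) {
        for (rt in all_rooted_topologies(right)) {
          out <- c(out, paste0("(", lt, ":1,", rt, ":1)"))
        }
      }
    }
  }
  out
}

topo_trees <- function(labels) {
  lapply(all_rooted_topologies(labels), function(s) {
    oscillate::parse_newick(paste0(s, ";"))
  })
}

# full state matrix for every assignment of internal states: rows =
# assignments, cols = nodes 1..(ntip + nnode); tip columns fixed
internal_assignments <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  k <- tree$Nnode
  M <- as.matrix(expand.grid(rep(list(0:1), k)))
  cbind(matrix(rep(tip_states[tree$tip.label], each = nrow(M)), nrow(M)), M)
}

# Mk (ER) likelihood by brute-force summation over internal states, flat root
mk_loglik_enum <- function(tree, tip_states, q) {
  S <- internal_assignments(tree, tip_states)
  ps <- 0.5 * (1 + exp(-2 * q * tree$edge.length))
  lik <- 0
  for (r in seq_len(nrow(S))) {
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge))) {
      same <- S[r, tree$edge[e, 1]] == S[r, tree$edge[e, 2]]
      pr <- pr * if (same) ps[e] else 1 - ps[e]
    }
    lik <- lik + pr
  }
  if (lik <= 0) -Inf else log(lik)
}

# minimum number of changes by brute force over internal labelings
fitch_enum <- function(tree, tip_states) {
  S <- internal_assignments(tree, tip_states)
  changes <- rowSums(abs(S[, tree$edge[, 1], drop = FALSE] -
                           S[, tree$edge[, 2], drop = FALSE]))
  min(changes)
}

# squared-change objective minimized by a generic quadratic optimizer
sqchange_enum <- function(tree, tip_values) {
  ntip <- ape::Ntip(tree)
  vals <- tip_values[tree$tip.label]
  obj <- function(internal) {
    x <- c(vals, internal)
    sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2)
  }
  o <- stats::optim(rep(mean(vals), tree$Nnode), obj, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$value
}

random_binary_states <- function(tree, p = 0.5) {
  setNames(rbinom(ape::Ntip(tree), 1, p), tree$tip.label)
}
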