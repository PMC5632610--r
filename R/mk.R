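#' Mk (ER) log-likelihood of a binary trait on a tree
#'
#' Log-likelihood of tip states under the symmetric two-state continuous-time
#' Markov model with a single transition rate `q` and a flat (1/2, 1/2) root
#' prior, computed by Felsenstein's pruning algorithm. Along an edge of length
#' `t` the chain stays with probability `(1 + exp(-2qt))/2` and switches with
#' probability `(1 - exp(-2qt))/2`. Tips without an observed state contribute
#' the partial likelihood (1, 1).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param states Named 0/1 vector over tip labels; `NA` marks a missing state.
#'   Every name must be a tip of the tree.
#' @param q Transition rate per unit branch length, `q >= 0`.
#' @return The log-likelihood; `-Inf` when the data have probability zero
#'   (only possible at `q = 0` with discordant tips).
#' @examples
#' tr <- parse_newick("(A:1,B:1);")
#' mk_loglik(tr, c(A = 1, B = 1), 0)  # log(1/2): no change possible
#' @export
mk_loglik <- function(tree, states, q) {
  stopifnot(q >= 0)
  st <- align_tip_states(tree, states)
  po <- ape::reorder.phylo(tree, "postorder")
  mk_pruning_loglik(po$edge, po$edge.length, ape::Ntip(tree), tree$Nnode, st, q)
}

# named 0/1 (+NA) vector -> integer vector in tip order with -1 for missing
align_tip_states <- function(tree, states) {
  if (is.null(names(states))) abort("`states` must be named by tip label")
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown)) {
    abort(paste0("state(s) given for non-tips: ", paste(unknown, collapse = ", ")))
  }
  bad <- !is.na(states) & !(states %in% c(0, 1))
  if (any(bad)) abort("tip states must be 0, 1, or NA")
  st <- rep(-1L, ape::Ntip(tree))
  idx <- match(names(states), tree$tip.label)
  st[idx] <- ifelse(is.na(states), -1L, as.integer(states))
  st
}

#' Maximum-likelihood Mk transition rate
#'
#' Fits the single ER transition rate by bounded one-dimensional optimization
#' of the pruning log-likelihood. For numerical conditioning the tree is
#' rescaled to unit depth and the rate bounded in `[1e-8, 1e3]` on that
#' scale (optimized on the log scale); the fitted rate is reported on the
#' original branch-length scale. A low rate relative to tree depth means high
#' phylogenetic signal.
#'
#' @inheritParams mk_loglik
#' @return An object of class `mk_fit`: `q` (rate, original scale),
#'   `q_unit` (rate per unit tree depth), `loglik`, `converged`,
#'   `bounds_hit` (`"none"`, `"lower"` or `"upper"`), `n_observed`.
#' @export
mk_fit_rate <- function(tree, states) {
  st <- align_tip_states(tree, states)
  n_obs <- sum(st >= 0)
  if (n_obs < 2) abort("need at least 2 tips with observed states")
  depth <- tree_depth(tree)
  tr1 <- rescale_tree_depth(tree, 1)
  po <- ape::reorder.phylo(tr1, "postorder")
  ntip <- ape::Ntip(tree)
  lo <- log(1e-8); hi <- log(1e3)
  f <- function(lq) mk_pruning_loglik(po$edge, po$edge.length, ntip,
                                      tree$Nnode, st, exp(lq))
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lq <- opt$maximum
  # optimize() never returns the exact interval ends; snap when the endpoint
  # likelihood is at least as good
  bounds_hit <- "none"
  if (lq - lo < 1e-4 && f(lo) >= opt$objective) {
    lq <- lo; bounds_hit <- "lower"
  } else if (hi - lq < 1e-4 && f(hi) >= opt$objective) {
    lq <- hi; bounds_hit <- "upper"
  }
  structure(list(
    q = exp(lq) / depth,
    q_unit = exp(lq),
    loglik = f(lq),
    converged = TRUE,
    bounds_hit = bounds_hit,
    n_observed = n_obs
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk (ER) fit: q = %.4g (per unit depth: %.4g), logLik = %.4f%s\n",
              x$q, x$q_unit, x$loglik,
              if (x$bounds_hit != "none") paste0(" [", x$bounds_hit, " bound]") else ""))
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  tibble(term = "q", estimate = x$q, estimate_unit_depth = x$q_unit,
         bounds_hit = x$bounds_hit)
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble(logLik = x$loglik, converged = x$converged, nobs = x$n_observed)
}

#' Permutation test of phylogenetic signal for a binary trait
#'
#' Fits the ML Mk transition rate for the observed tip states, then refits it
#' for `n_perm` random shuffles of the states across the tips (state counts
#' preserved, missing states shuffled along). Low observed rates relative to
#' the permutation distribution indicate phylogenetic signal; the p-value is
#' the raw fraction of permuted rates at or below the observed rate (so a
#' perfectly clustered trait can print p = 0). The `(k+1)/(n+1)` upper bound
#' is also reported since a raw 0 is not a valid probability statement.
#'
#' @inheritParams mk_loglik
#' @param n_perm Number of permutations (the reference analysis used 1000).
#' @param seed Optional integer seed; the RNG state is restored afterwards.
#' @return An object of class `signal_test`: `observed_q`, `permuted_q`,
#'   `p_value`, `p_upper`, `n_perm`, `seed`, `constant`.
#' @export
permutation_signal_test <- function(tree, states, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  st <- align_tip_states(tree, states)
  obs <- st[st >= 0]
  fit <- mk_fit_rate(tree, states)
  if (length(unique(obs)) < 2) {
    warn("trait is constant across observed tips; p = 1 by construction")
    return(structure(list(
      observed_q = fit$q, permuted_q = rep(fit$q, n_perm),
      p_value = 1, p_upper = 1, n_perm = as.integer(n_perm),
      seed = seed, constant = TRUE
    ), class = "signal_test"))
  }
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      perm <- setNames(sample(unname(states)), names(states))
      mk_fit_rate(tree, perm)$q
    }, numeric(1))
  }
  permuted <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  k <- sum(permuted <= fit$q)  # ties count as <=: conservative for a low tail
  structure(list(
    observed_q = fit$q, permuted_q = permuted,
    p_value = k / n_perm, p_upper = (k + 1) / (n_perm + 1),
    n_perm = as.integer(n_perm), seed = seed, constant = FALSE
  ), class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("Phylogenetic signal (Mk rate) test: q = %.4g, p = %.4g (n_perm = %d)\n",
              x$observed_q, x$p_value, x$n_perm))
  invisible(x)
}

#' @export
tidy.signal_test <- function(x, ...) {
  tibble(t_rate = x$observed_q, p_value = x$p_value, p_upper = x$p_upper,
         n_perm = x$n_perm, constant = x$constant)
}

#' @export
glance.signal_test <- tidy.signal_test

#' Signal tests for a matrix of binary traits
#'
#' Runs [permutation_signal_test()] for every column of a taxon-by-trait
#' binary matrix (such as the polyphagy codings plus the per-order host-use
#' columns), producing a rate-and-p table. Per-column seeds are derived
#' deterministically from the master seed as `seed + column index`.
#'
#' @param tree A `phylo` object.
#' @param trait_matrix Binary matrix, `rownames` = tip labels, one column per
#'   trait (see [order_usage_matrix()]).
#' @param n_perm Permutations per trait.
#' @param seed Master integer seed.
#' @return A tibble of class `signal_table`: `trait`, `t_rate`, `p_value`,
#'   `p_upper`, `constant`.
#' @export
batch_signal <- function(tree, trait_matrix, n_perm = 1000, seed = NULL) {
  stopifnot(is.matrix(trait_matrix), !is.null(rownames(trait_matrix)))
  cols <- colnames(trait_matrix)
  if (is.null(cols)) cols <- paste0("trait", seq_len(ncol(trait_matrix)))
  res <- purrr::map(seq_along(cols), function(j) {
    states <- setNames(trait_matrix[, j], rownames(trait_matrix))
    sj <- if (is.null(seed)) NULL else seed + j
    withCallingHandlers(
      permutation_signal_test(tree, states, n_perm = n_perm, seed = sj),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  out <- tibble(
    trait = cols,
    t_rate = purrr::map_dbl(res, "observed_q"),
    p_value = purrr::map_dbl(res, "p_value"),
    p_upper = purrr::map_dbl(res, "p_upper"),
    constant = purrr::map_lgl(res, "constant")
  )
  class(out) <- c("signal_table", class(out))
  out
}
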