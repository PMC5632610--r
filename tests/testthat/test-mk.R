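test_that("pruning likelihood handles closed-form cherry cases", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(mk_loglik(tr, c(A = 1, B = 1), 0), -log(2))
  expect_equal(mk_loglik(tr, c(A = 1, B = 0), 0), -Inf)
  # q > 0 cherry, states (1, 0): P = 2 * (1/2) * pstay * pswitch
  q <- 0.3
  ps <- 0.5 * (1 + exp(-2 * q)); pw <- 0.5 * (1 - exp(-2 * q))
  expect_equal(mk_loglik(tr, c(A = 1, B = 0), q), log(ps * pw), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  withr::local_seed(101)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    tr <- simulate_yule_tree(n, 1)
    st <- random_binary_states(tr)
    for (q in c(0, 0.05, 0.3, 1, 5)) {
      expect_equal(mk_loglik(tr, st, q), mk_loglik_enum(tr, st, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("missing tip states act as partial likelihood (1,1)", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  # marginalizing C by hand: sum of enumerated likelihoods over C in {0,1}
  st0 <- c(A = 1, B = 1, C = 0); st1 <- c(A = 1, B = 1, C = 1)
  q <- 0.4
  marg <- log(exp(mk_loglik_enum(tr, st0, q)) + exp(mk_loglik_enum(tr, st1, q)))
  expect_equal(mk_loglik(tr, c(A = 1, B = 1, C = NA), q), marg, tolerance = 1e-10)
  expect_error(mk_loglik(tr, c(A = 1, B = 1, Z = 0), q), "non-tips")
})

test_that("likelihood saturates at q -> Inf to independent Bernoulli tips", {
  tr <- rescale_tree_depth(simulate_yule_tree(12, 1, seed = 33), 1)
  st <- random_binary_states(tr)
  expect_equal(mk_loglik(tr, st, 1e3), 12 * log(0.5), tolerance = 1e-6)
})

test_that("ML rate matches a fine grid search and flags bounds", {
  withr::local_seed(7)
  tr <- rescale_tree_depth(simulate_yule_tree(6, 1), 1)
  st <- random_binary_states(tr)
  while (length(unique(st)) == 1) st <- random_binary_states(tr)
  fit <- mk_fit_rate(tr, st)
  grid <- 10^seq(-8, 3, by = 1e-4 * 11)  # 1e-4 resolution in log10 q
  ll <- vapply(grid, function(q) mk_loglik(tr, st, q), numeric(1))
  q_grid <- grid[which.max(ll)]
  expect_equal(log10(fit$q), log10(q_grid), tolerance = 2e-3)
  expect_gte(fit$loglik, max(ll) - 1e-8)

  const <- setNames(rep(0, ape::Ntip(tr)), tr$tip.label)
  cfit <- mk_fit_rate(tr, const)
  expect_equal(cfit$bounds_hit, "lower")
  expect_equal(cfit$q_unit, 1e-8)
})

test_that("fitted rate agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(40, 1, seed = 55)
  st <- simulate_mk_trait(tr, q = 0.5 / tree_depth(tr), seed = 56)
  while (length(unique(st)) < 2) st <- simulate_mk_trait(tr, 1, seed = 57)
  fit <- mk_fit_rate(tr, st)
  ref <- phytools::fitMk(tr, factor(st[tr$tip.label], levels = 0:1),
                         model = "ER", pi = "equal")
  expect_equal(fit$q, ref$rates[1], tolerance = 1e-3)
  expect_equal(fit$loglik, ref$logLik, tolerance = 1e-6)
})

test_that("rate recovery: median ML estimate near truth at q = 0.2", {
  # unit-depth trees; a reduced but unbiased version of the recovery design
  qhat <- vapply(1:40, function(i) {
    tr <- rescale_tree_depth(simulate_yule_tree(200, 1, seed = 300 + i), 1)
    st <- simulate_mk_trait(tr, 0.2, seed = 600 + i)
    mk_fit_rate(tr, st)$q
  }, numeric(1))
  expect_gte(median(qhat), 0.15)
  expect_lte(median(qhat), 0.25)
})

test_that("permutation test short-circuits constant traits and respects symmetry", {
  tr <- simulate_yule_tree(20, 1, seed = 77)
  const <- setNames(rep(1, 20), tr$tip.label)
  expect_warning(res <- permutation_signal_test(tr, const, n_perm = 19, seed = 1),
                 "constant")
  expect_equal(res$p_value, 1)

  st <- simulate_mk_trait(tr, 0.3 / tree_depth(tr), seed = 78)
  a <- permutation_signal_test(tr, st, n_perm = 99, seed = 5)
  b <- permutation_signal_test(tr, setNames(1 - st, names(st)),
                               n_perm = 99, seed = 5)
  expect_equal(a$observed_q, b$observed_q, tolerance = 1e-8)
  expect_equal(a$p_value, b$p_value)
  expect_length(a$permuted_q, 99)
  expect_error(permutation_signal_test(tr, st, n_perm = 0), "n_perm")
})

test_that("a clustered trait scores lower p than a shuffled copy", {
  wins <- 0
  for (i in 1:20) {
    tr <- rescale_tree_depth(simulate_yule_tree(60, 1, seed = 400 + i), 1)
    clustered <- simulate_mk_trait(tr, 0.1, seed = 500 + i)
    if (length(unique(clustered)) < 2) next
    shuffled <- withr::with_seed(600 + i,
      setNames(sample(unname(clustered)), names(clustered)))
    pc <- permutation_signal_test(tr, clustered, n_perm = 49, seed = 700 + i)$p_value
    ps <- permutation_signal_test(tr, shuffled, n_perm = 49, seed = 800 + i)$p_value
    wins <- wins + (pc <= ps)
  }
  expect_gte(wins, 15)
})

test_that("batch_signal derives per-column seeds and flags constants", {
  tr <- simulate_yule_tree(25, 1, seed = 90)
  st <- simulate_mk_trait(tr, 0.4 / tree_depth(tr), seed = 91)
  m <- cbind(a = st, b = st, const = rep(1L, 25))
  rownames(m) <- names(st)
  out <- batch_signal(tr, m, n_perm = 49, seed = 10)
  expect_s3_class(out, "signal_table")
  expect_equal(out$t_rate[1], out$t_rate[2], tolerance = 1e-8)
  # same trait, different derived seeds: p equal within Monte-Carlo error
  expect_lte(abs(out$p_value[1] - out$p_value[2]), 0.2)
  expect_true(out$constant[3])
  expect_equal(out$p_value[3], 1)
})
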