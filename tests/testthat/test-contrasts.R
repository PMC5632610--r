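two_tip_traits <- function(hd_a, hd_b, r_a = 10, r_b = 5) {
  tibble::tibble(
    taxon = c("A", "B"),
    n_species = c(r_a, r_b),
    host_orders = list(host_order_sample(hd_a), host_order_sample(hd_b)),
    hd = c(hd_a, hd_b),
    max_polyphagy = c(hd_a, hd_b)
  )
}

host_order_sample <- function(k) paste0("Order", seq_len(k))

test_that("two-tip contrasts respect the minimum-difference rule", {
  tr <- parse_newick("(A:1,B:1);")
  cs <- build_contrasts(tr, two_tip_traits(5, 1), min_hd_diff = 3)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$hd1, 5L)
  expect_equal(cs$hd2, 1L)
  expect_equal(unlist(cs$clade1), "A")

  none <- build_contrasts(tr, two_tip_traits(5, 4), min_hd_diff = 3)
  expect_equal(nrow(none), 0)
  # the permissive variant pairs them
  loose <- build_contrasts(tr, two_tip_traits(5, 4), min_hd_diff = 1)
  expect_equal(nrow(loose), 1)
})

test_that("clades merge upward until the difference criterion is met", {
  # ((A,B),(C,D)): neither cherry differs enough on its own, but the
  # A+B vs C+D union does
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  traits <- tibble::tibble(
    taxon = c("A", "B", "C", "D"),
    n_species = c(5L, 5L, 2L, 2L),
    host_orders = list(paste0("O", 1:4), paste0("O", 3:6),
                       "O1", "O2"),
    hd = c(4L, 4L, 1L, 1L),
    max_polyphagy = c(3L, 2L, 1L, 1L)
  )
  cs <- build_contrasts(tr, traits, min_hd_diff = 3)
  expect_equal(nrow(cs), 1)
  expect_setequal(unlist(cs$clade1), c("A", "B"))  # union HD 6 vs 2
  expect_equal(cs$hd1, 6L)
  expect_equal(cs$hd2, 2L)
  expect_equal(cs$r1, 10L)
  expect_equal(cs$max_poly_side, "1")
})

test_that("emitted pairs never reuse taxa and sides are HD-ordered", {
  withr::local_seed(42)
  for (i in 1:5) {
    tr <- simulate_yule_tree(30, 1)
    uni <- simulate_host_universe(tr, sim_config(n_tips = 30), seed = 100 + i)
    traits <- derive_genus_traits(uni$records, uni$richness)
    cs <- suppressWarnings(build_contrasts(tr, traits, 3))
    taxa <- c(unlist(cs$clade1), unlist(cs$clade2))
    expect_equal(anyDuplicated(taxa), 0)
    if (nrow(cs)) {
      expect_true(all(cs$hd1 - cs$hd2 >= 3))
      expect_true(all(cs$rel > 0))
      expect_equal(cs$positive, cs$log10rel > 0)
    }
  }
})

test_that("polytomous candidate nodes are skipped with a warning", {
  tr <- parse_newick("(A:1,B:1,C:1);")
  traits <- tibble::tibble(
    taxon = c("A", "B", "C"), n_species = c(3L, 1L, 1L),
    host_orders = list(paste0("O", 1:5), "O1", "O2"),
    hd = c(5L, 1L, 1L), max_polyphagy = c(4L, 1L, 1L))
  expect_warning(cs <- build_contrasts(tr, traits, 3), "polytomy")
  expect_equal(nrow(cs), 0)
})

test_that("relative richness follows the printed convention", {
  out <- relative_richness(tibble::tibble(r1 = 45L, r2 = 2L))
  expect_equal(out$rel, 22.5)
  expect_equal(round(out$log10rel, 3), 1.352)

  eq <- relative_richness(tibble::tibble(r1 = 7L, r2 = 7L))
  expect_equal(eq$rel, 1)
  expect_equal(eq$log10rel, 0)
  expect_false(eq$positive)

  swapped <- relative_richness(tibble::tibble(r1 = 2L, r2 = 45L))
  expect_equal(swapped$log10rel, -out$log10rel)

  expect_error(relative_richness(tibble::tibble(r1 = 3L, r2 = 0L)), "at least one")
})

test_that("sign test matches closed forms and is symmetric", {
  expect_equal(sign_test(10, 10)$p_value, 2 * 0.5^10)
  expect_equal(sign_test(9, 10)$p_value, 0.021484375)
  expect_equal(sign_test(5, 10)$p_value, 1)
  # symmetry k <-> n - k
  for (n in c(5, 10, 17)) {
    for (k in 0:n) {
      expect_equal(sign_test(k, n)$p_value, sign_test(n - k, n)$p_value)
    }
  }
  # agreement with the exact binomial test at p = 1/2
  for (k in 0:10) {
    expect_equal(sign_test(k, 10)$p_value,
                 stats::binom.test(k, 10)$p.value, tolerance = 1e-12)
  }
  expect_error(sign_test(0, 0), "n = 0")
})

test_that("paired log-t matches the textbook formula and stats::t.test", {
  cs <- tibble::tibble(log10rel = c(1, 2, 3))
  res <- paired_log_t(cs)
  expect_equal(res$mean, 2)
  expect_equal(res$sd, 1)
  expect_equal(res$t, 2 / (1 / sqrt(3)))
  expect_equal(res$df, 2L)
  ref <- stats::t.test(c(1, 2, 3))
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  expect_error(paired_log_t(tibble::tibble(log10rel = c(0, 0, 0))), "degenerate")
  expect_error(paired_log_t(tibble::tibble(log10rel = 1)), "at least 2")
})

test_that("t statistic is invariant to richness rescaling and row order", {
  cs <- relative_richness(tibble::tibble(
    r1 = c(6L, 74L, 45L), r2 = c(2L, 55L, 2L)))
  t1 <- paired_log_t(cs)$t
  t2 <- paired_log_t(cs[c(3, 1, 2), ])$t
  scaled <- relative_richness(dplyr::mutate(cs, r1 = r1 * 7L, r2 = r2 * 7L))
  expect_equal(t1, t2)
  expect_equal(paired_log_t(scaled)$t, t1)
})

test_that("concordance test drops ties and uses the exact sign test", {
  cs <- tibble::tibble(max_poly_side = c(rep("1", 10)))
  res <- concordance_most_polyphagous(cs)
  expect_equal(res$k_concordant, 10L)
  expect_equal(res$p_value, 2 * 0.5^10)

  mixed <- tibble::tibble(max_poly_side = c("1", "2", "tie", "1"))
  res2 <- concordance_most_polyphagous(mixed)
  expect_equal(res2$n, 3L)
  expect_equal(res2$k_concordant, 2L)

  expect_error(concordance_most_polyphagous(tibble::tibble(max_poly_side = "tie")),
               "ties")
})

test_that("concordance can be recomputed from traits when the side is absent", {
  traits <- tibble::tibble(taxon = c("A", "B"), max_polyphagy = c(5L, 2L))
  cs <- tibble::tibble(clade1 = list("A"), clade2 = list("B"))
  res <- concordance_most_polyphagous(cs, traits)
  expect_equal(res$k_concordant, 1L)
})

test_that("concordance null calibration: ~1% rejections at alpha = .01", {
  withr::local_seed(77)
  rej <- 0; nrep <- 1000
  for (i in seq_len(nrep)) {
    side <- ifelse(runif(10) < 0.5, "1", "2")
    rej <- rej + (concordance_most_polyphagous(
      tibble::tibble(max_poly_side = side))$p_value < 0.01)
  }
  # only 10/10 or 0/10 reject (p = .00195); expect about 2 * 0.5^10 * 1000
  expect_lte(rej / nrep, 0.01)
})

test_that("hd/max-polyphagy correlation covers the exact and null corners", {
  perfect <- tibble::tibble(taxon = letters[1:5], hd = c(1L, 3L, 5L, 9L, 12L),
                            max_polyphagy = c(1L, 3L, 5L, 9L, 12L))
  expect_equal(hd_maxpoly_correlation(perfect)$r_squared, 1)

  orth <- tibble::tibble(taxon = letters[1:4], hd = c(1L, 1L, 9L, 9L),
                         max_polyphagy = c(1L, 9L, 1L, 9L))
  expect_equal(hd_maxpoly_correlation(orth)$r_squared, 0)

  uni <- simulate_host_universe(simulate_yule_tree(55, 1, seed = 8),
                                sim_config(), seed = 9)
  traits <- derive_genus_traits(uni$records, uni$richness)
  expect_gt(hd_maxpoly_correlation(traits)$r_squared, 0.8)
  expect_error(hd_maxpoly_correlation(perfect[1, ]), "at least 3")
})

test_that("the packaged printed fixture validates and reproduces its columns", {
  cs <- published_contrasts()
  expect_equal(nrow(cs), 10)
  expect_true(all(cs$hd1 - cs$hd2 >= 3))
  expect_equal(cs$rel[cs$pair == "Somena-Kidokuga"], 3)
  # recomputed log matches the printed column to 3 decimals on every row
  expect_equal(round(cs$log10rel, 3), cs$log_printed)
})
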