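make_records <- function(...) {
  tibble::tribble(~moth_species, ~genus_taxon, ~plant_family, ~plant_order, ...)
}

test_that("host-record loading de-duplicates (species, order) pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(make_records(
    "s1", "G", "Fabaceae", "Fabales",
    "s1", "G", "Mimosaceae", "Fabales",
    "s2", "G", "Rosaceae", "Rosales"
  ), f)
  expect_message(rec <- read_host_records(f), "de-duplicated")
  expect_equal(nrow(rec), 2)

  readr::write_tsv(make_records(), f)
  expect_warning(empty <- read_host_records(f), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("host-record loading rejects missing columns and blank cells", {
  expect_error(as_host_records(data.frame(moth_species = "a")), "missing column")
  expect_error(
    as_host_records(make_records("s1", "G", "", "Fabales")),
    "row"
  )
})

test_that("genus traits aggregate order counts per species and taxon", {
  rec <- make_records(
    "s1", "G", "f", "Fabales",
    "s1", "G", "f", "Rosales",
    "s2", "G", "f", "Fabales"
  )
  tr <- derive_genus_traits(rec, c(G = 5))
  expect_equal(tr$hd, 2L)
  expect_equal(tr$max_polyphagy, 2L)
  expect_equal(tr$poly3, 0L)

  # threshold edge: one species on exactly 7 distinct orders
  orders7 <- c("Fabales", "Rosales", "Poales", "Fagales", "Myrtales",
               "Ericales", "Lamiales")
  rec7 <- do.call(make_records, as.list(rbind("s", "H", "f", orders7)))
  tr7 <- derive_genus_traits(rec7, c(H = 1))
  expect_equal(tr7$poly7, 1L)
  expect_equal(tr7$max_polyphagy, 7L)

  expect_error(derive_genus_traits(rec, c(X = 1)), "missing from the richness")
})

test_that("trait derivation is order-independent and case-insensitive", {
  uni <- simulate_host_universe(simulate_yule_tree(12, 1, seed = 3),
                                sim_config(n_tips = 12), seed = 4)
  t1 <- derive_genus_traits(uni$records, uni$richness)
  shuffled <- uni$records[withr::with_seed(1, sample(nrow(uni$records))), ]
  t2 <- derive_genus_traits(shuffled, uni$richness)
  expect_equal(t1, t2)

  rec <- make_records("s1", "G", "f", "Fabales", "s1", "G", "f", " fabales ")
  expect_equal(derive_genus_traits(rec, c(G = 1))$hd, 1L)
})

test_that("binary coding thresholds are inclusive and nested", {
  tr <- tibble::tibble(taxon = c("a", "b", "c"), max_polyphagy = c(3L, 6L, 7L))
  expect_equal(unname(code_binary_trait(tr, 3)), c(1L, 1L, 1L))
  expect_equal(unname(code_binary_trait(tr, 7)), c(0L, 0L, 1L))

  uni <- simulate_host_universe(simulate_yule_tree(25, 1, seed = 5),
                                sim_config(n_tips = 25), seed = 6)
  traits <- derive_genus_traits(uni$records, uni$richness)
  k3 <- code_binary_trait(traits, 3)
  k7 <- code_binary_trait(traits, 7)
  expect_true(all(names(which(k7 == 1)) %in% names(which(k3 == 1))))
})

test_that("order-usage matrix matches a direct recount and flags unknowns", {
  one <- tibble::tibble(taxon = "G", host_orders = list("Fabales"))
  expect_warning(
    m <- order_usage_matrix(one, c("Fabales", "Poales")),
    "no taxon"
  )
  expect_equal(unname(m["G", ]), c(1L, 0L))

  uni <- simulate_host_universe(simulate_yule_tree(20, 1, seed = 11),
                                sim_config(n_tips = 20), seed = 12)
  traits <- derive_genus_traits(uni$records, uni$richness)
  orders <- sort(unique(uni$records$plant_order))
  m <- order_usage_matrix(traits, orders)
  recount <- table(factor(
    unique(dplyr::select(uni$records, genus_taxon, plant_order))$plant_order,
    levels = orders))
  expect_equal(unname(colSums(m)), as.integer(recount))
  expect_true(all(traits$hd >= traits$max_polyphagy))
})

test_that("rank-weighted sampling makes the canonical orders the most used", {
  uni <- simulate_host_universe(simulate_yule_tree(55, 1, seed = 21),
                                sim_config(), seed = 22)
  traits <- derive_genus_traits(uni$records, uni$richness)
  top <- top_host_orders(traits, 10)
  expect_true(all(c("Malpighiales", "Fabales", "Fagales", "Rosales",
                    "Sapindales") %in% top$plant_order))
})
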