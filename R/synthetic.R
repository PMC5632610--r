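# Plant-order pool for synthetic host universes: 42 angiosperm orders plus 4
# non-angiosperm orders, listed roughly by how widely tussock moths use them
# so that rank-weighted sampling makes the first few the most-used.
host_order_pool <- c(
  "Malpighiales", "Fabales", "Fagales", "Rosales", "Sapindales",
  "Myrtales", "Ericales", "Poales", "Malvales", "Lamiales",
  "Gentianales", "Asterales", "Laurales", "Solanales", "Arecales",
  "Zingiberales", "Ranunculales", "Caryophyllales", "Brassicales",
  "Cucurbitales", "Celastrales", "Cornales", "Dipsacales", "Apiales",
  "Aquifoliales", "Asparagales", "Liliales", "Dioscoreales", "Pandanales",
  "Alismatales", "Piperales", "Magnoliales", "Canellales", "Chloranthales",
  "Austrobaileyales", "Nymphaeales", "Vitales", "Geraniales",
  "Crossosomatales", "Zygophyllales", "Oxalidales", "Santalales",
  "Pinales", "Polypodiales", "Cyatheales", "Gnetales"
)

#' Configuration for the synthetic host-use universe
#'
#' Bundles and validates the generator parameters. Defaults describe the
#' regime the pipeline is meant to analyse: about 55 genus-level taxa, a
#' log-log richness-on-host-diversity slope of 0.77 with phylogenetic
#' residual signal lambda = 0.70, and host diversity tightly coupled to the
#' polyphagy of the single most polyphagous species.
#'
#' @param n_tips Number of genus-level taxa (tree tips).
#' @param birth_rate Yule speciation rate (per lineage per unit time).
#' @param mk_rate Transition rate for simulated binary Mk traits.
#' @param hd_signal Brownian variance of log host breadth per unit depth.
#' @param beta_true Log-log slope of species richness on host diversity.
#' @param noise_sigma SD (log10 units) of the richness residual.
#' @param lambda_true Pagel's lambda of the richness residual, in [0, 1].
#' @param coupling Strength in [0, 1] tying the most polyphagous species'
#'   breadth to the taxon's host diversity.
#' @param richness_intercept Intercept of the log10 richness model.
#' @param n_orders_pool Size of the plant-order pool (at most 46 named
#'   orders are available).
#' @param max_recorded_species Cap on species with host records per taxon,
#'   mimicking incomplete species-level recording.
#' @param seed Optional integer seed used by the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 55, birth_rate = 1, mk_rate = 0.1,
                       hd_signal = 1.5, beta_true = 0.77, noise_sigma = 0.37,
                       lambda_true = 0.70, coupling = 0.7,
                       richness_intercept = 1.2, n_orders_pool = 46,
                       max_recorded_species = 30, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0, mk_rate >= 0, hd_signal >= 0,
            noise_sigma >= 0, lambda_true >= 0, lambda_true <= 1,
            coupling >= 0, coupling <= 1, n_orders_pool >= 1,
            n_orders_pool <= length(host_order_pool), max_recorded_species >= 1)
  structure(as.list(environment()), class = "sim_config")
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate a pure-birth (Yule) tree
#'
#' Grows a tree from two lineages: while `k` lineages are alive the next
#' split waits an Exp(`k * birth_rate`) time and hits a uniformly chosen
#' lineage; after the `n`-th lineage appears a final Exp(`n * birth_rate`)
#' epoch runs to the present. Expected root-to-tip depth is therefore
#' `(1/birth_rate) * sum(1/k, k = 2..n)`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed.
#' @return A binary `phylo` object with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  with_seed_maybe(seed, {
    n <- as.integer(n_tips)
    waits <- rexp(n - 1, rate = birth_rate * (2:n))
    split_times <- cumsum(c(0, waits[seq_len(n - 2)]))  # time of 2..n lineages
    t_end <- sum(waits)
    n_edge <- 2L * n - 2L
    edge <- matrix(0L, n_edge, 2)
    elen <- numeric(n_edge)
    parent <- integer(0)  # parent internal id of each pending lineage
    born <- numeric(0)
    root <- n + 1L
    next_internal <- n + 2L
    parent <- c(root, root); born <- c(0, 0)
    ne <- 0L
    add_edge <- function(p, c, len) {
      ne <<- ne + 1L
      edge[ne, ] <<- c(p, c)
      elen[ne] <<- len
    }
    for (ev in seq_len(n - 2)) {
      s <- split_times[ev + 1]
      i <- sample.int(length(parent), 1)
      nd <- next_internal
      next_internal <- next_internal + 1L
      add_edge(parent[i], nd, s - born[i])
      parent <- c(parent[-i], nd, nd)
      born <- c(born[-i], s, s)
    }
    for (i in seq_along(parent)) add_edge(parent[i], i, t_end - born[i])
    tr <- list(edge = edge, edge.length = elen, Nnode = n - 1L,
               tip.label = paste0("t", seq_len(n)))
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
}

#' Simulate a binary trait under the Mk (ER) model
#'
#' Evolves a two-state character edge by edge from the root: along an edge of
#' length `t` the state switches with probability `(1 - exp(-2 q t)) / 2`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param q Transition rate (>= 0).
#' @param root_state 0, 1, or `NULL` to draw the root from the stationary
#'   (1/2, 1/2) distribution.
#' @param seed Optional integer seed.
#' @return Named 0/1 vector over tips.
#' @export
simulate_mk_trait <- function(tree, q, root_state = NULL, seed = NULL) {
  stopifnot(q >= 0)
  with_seed_maybe(seed, {
    ntip <- ape::Ntip(tree)
    ntot <- ntip + tree$Nnode
    state <- integer(ntot)
    root <- ntip + 1L
    state[root] <- if (is.null(root_state)) sample(0:1, 1) else as.integer(root_state)
    pre <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(pre$edge)))
    for (e in ord) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      pswitch <- 0.5 * (1 - exp(-2 * q * pre$edge.length[e]))
      flip <- runif(1) < pswitch
      state[ch] <- if (flip) 1L - state[p] else state[p]
    }
    setNames(state[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate Brownian motion on a tree
#'
#' @param tree A `phylo` object with branch lengths.
#' @param sigma2 Brownian variance per unit branch length.
#' @param root Root value.
#' @param seed Optional integer seed.
#' @return Named numeric vector over tips.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root = 0, seed = NULL) {
  stopifnot(sigma2 >= 0)
  with_seed_maybe(seed, {
    ntip <- ape::Ntip(tree)
    ntot <- ntip + tree$Nnode
    val <- numeric(ntot)
    val[ntip + 1L] <- root
    pre <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(pre$edge)))) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      val[ch] <- val[p] + rnorm(1, 0, sqrt(sigma2 * pre$edge.length[e]))
    }
    setNames(val[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate a species-level host-record universe
#'
#' Generates the tabular inputs the pipeline analyses, with the statistical
#' structure the analysis assumes: per-taxon log host breadth evolves by
#' Brownian motion on the (unit-depth-rescaled) tree and is exponentiated and
#' rounded to a host diversity `hd >= 1`; each taxon's host orders are drawn
#' rank-weighted from a pool of named plant orders (so a few orders dominate,
#' as in real host compilations); one "champion" species per taxon feeds on a
#' `coupling`-controlled share of the taxon's orders, tying maximum
#' single-species polyphagy to host diversity; and species richness follows
#' `round(10^(a + beta_true * log10(hd) + eps))`, floored at 1, where `eps`
#' is multivariate normal with a Pagel's-lambda-scaled Brownian covariance
#' (`lambda_true`, `noise_sigma`), so that the residual itself carries
#' phylogenetic signal.
#'
#' @param tree A `phylo` object over the genus-level taxa.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (overrides `config$seed`).
#' @return A list: `records` (host-record tibble), `richness` (tibble
#'   `taxon`, `n_species`), `ledger` (tibble `taxon`, `hd`, `max_polyphagy`,
#'   `n_species` as generated; [derive_genus_traits()] on `records` +
#'   `richness` reproduces `hd` and `max_polyphagy` exactly).
#' @export
simulate_host_universe <- function(tree, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed_maybe(seed, {
    tr1 <- rescale_tree_depth(tree, 1)
    n <- ape::Ntip(tree)
    pool <- host_order_pool[seq_len(config$n_orders_pool)]
    w <- 1 / seq_along(pool)

    z <- simulate_bm_trait(tr1, sigma2 = config$hd_signal, root = log(6))
    hd <- pmin(length(pool), pmax(1L, as.integer(round(exp(z)))))

    V <- ape::vcv(tr1)
    Vl <- config$lambda_true * V
    diag(Vl) <- diag(V)
    eps <- as.numeric(MASS::mvrnorm(1, rep(0, n), config$noise_sigma^2 * Vl))
    n_species <- pmax(1L, as.integer(round(
      10^(config$richness_intercept + config$beta_true * log10(hd) + eps))))

    taxa <- tree$tip.label
    rec <- vector("list", n)
    max_poly <- integer(n)
    for (i in seq_len(n)) {
      orders <- sample(pool, hd[i], prob = w)
      m <- min(n_species[i], config$max_recorded_species)
      champ_b <- if (m == 1) hd[i] else
        min(hd[i], 1L + rbinom(1, hd[i] - 1L, config$coupling))
      assign <- vector("list", m)
      assign[[1]] <- orders[seq_len(champ_b)]
      rest <- orders[-seq_len(champ_b)]
      if (length(rest)) {
        who <- rep(seq_len(m - 1) + 1L, length.out = length(rest))
        for (j in seq_along(rest)) {
          assign[[who[j]]] <- c(assign[[who[j]]], rest[j])
        }
      }
      for (s in seq_len(m)) {
        if (!length(assign[[s]])) assign[[s]] <- sample(orders, 1)
      }
      max_poly[i] <- max(lengths(assign))
      rec[[i]] <- tibble(
        moth_species = rep(paste0(taxa[i], "_sp", seq_len(m)), lengths(assign)),
        genus_taxon = taxa[i],
        plant_order = unlist(assign)
      )
    }
    records <- dplyr::bind_rows(rec) |>
      dplyr::mutate(plant_family = paste0(sub("ales$", "", .data$plant_order), "aceae"),
                    .before = "plant_order")
    list(
      records = records,
      richness = tibble(taxon = taxa, n_species = n_species),
      ledger = tibble(taxon = taxa, hd = hd, max_polyphagy = max_poly,
                      n_species = n_species),
      config = config
    )
  })
}

#' The packaged printed sister-contrast fixture
#'
#' The ten published sister-clade contrasts in host diversity for tussock
#' moth genus-level taxa, exactly as printed (host diversities, summed
#' species richness, sign, relative richness and its log), plus the printed
#' report that in every contrast the higher-host-diversity side holds the
#' most polyphagous single species. The printed `rel`/`log` columns are kept
#' as `rel_printed`/`log_printed`; `rel`, `log10rel` are recomputed from
#' `r1`, `r2`.
#'
#' @return A `contrast_set` tibble with 10 rows.
#' @export
published_contrasts <- function() {
  path <- system.file("extdata", "published_contrasts.tsv", package = "oscillate",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = "cciiiiccdc", progress = FALSE)
  out <- raw |>
    dplyr::mutate(
      clade1 = strsplit(.data$clade1, "+", fixed = TRUE),
      clade2 = strsplit(.data$clade2, "+", fixed = TRUE),
      rel_printed = as.numeric(.data$rel_printed),
      log_printed = as.numeric(.data$log_printed),
      max_poly_side = .data$most_polyphagous_side
    ) |>
    dplyr::mutate(pair = paste0(purrr::map_chr(.data$clade1, side_label), "-",
                                purrr::map_chr(.data$clade2, side_label)),
                  .before = 1) |>
    dplyr::select(-"most_polyphagous_side") |>
    relative_richness()
  taxa <- c(unlist(out$clade1), unlist(out$clade2))
  stopifnot(all(out$hd1 - out$hd2 >= 3), !anyDuplicated(taxa))
  attr(out, "min_hd_diff") <- 3
  class(out) <- c("contrast_set", class(out))
  out
}
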