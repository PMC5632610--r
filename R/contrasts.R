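#' Build sister-clade contrasts under a minimum host-diversity difference
#'
#' Deterministic replacement for the informal, visually guided selection of
#' sister-group contrasts: a post-order sweep over internal nodes. At every
#' binary node whose two daughter clades contain no taxon already used, the
#' daughters form a candidate pair; the pair is emitted when the host
#' diversity of the two sides (distinct plant orders in the union of each
#' side's host-order sets) differs by at least `min_hd_diff`, otherwise the
#' clades stay free and may merge at the next ancestor. Emitted pairs never
#' share taxa, so the contrasts are phylogenetically independent. Setting
#' `min_hd_diff = 1` gives the "any sister pair that differs at all" variant.
#'
#' @param tree A `phylo` object whose tips all appear in `traits$taxon`.
#' @param traits Genus-trait table from [derive_genus_traits()].
#' @param min_hd_diff Minimum host-diversity difference (default 3).
#' @return A tibble of class `contrast_set`, one row per contrast: `pair`
#'   (label), `clade1`/`clade2` (list-columns of taxa; side 1 is the
#'   higher-HD side), `hd1`, `hd2`, `r1`, `r2`, `rel`, `log10rel`,
#'   `positive`, `max_poly_side` (1, 2 or `"tie"`). Attribute `min_hd_diff`
#'   records the rule.
#' @export
build_contrasts <- function(tree, traits, min_hd_diff = 3) {
  stopifnot(min_hd_diff >= 1)
  missing_taxa <- setdiff(tree$tip.label, traits$taxon)
  if (length(missing_taxa)) {
    abort(paste0("tips without trait entries: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  tr <- traits[match(tree$tip.label, traits$taxon), ]
  canon <- function(x) tolower(trimws(x))
  orders_of <- setNames(lapply(tr$host_orders, canon), tr$taxon)
  rich <- setNames(tr$n_species, tr$taxon)
  mpoly <- setNames(tr$max_polyphagy, tr$taxon)

  po <- ape::reorder.phylo(tree, "postorder")$edge
  internal_po <- unique(po[, 1])
  kids <- node_children(tree)
  used <- character(0)
  rows <- list()
  for (nd in internal_po) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) != 2) {
      warn(paste0("polytomy at node ", nd, " skipped during contrast building"))
      next
    }
    side <- lapply(ch, function(v) clade_tips(tree, v))
    if (any(unlist(side) %in% used)) next
    hd <- vapply(side, function(tx) length(unique(unlist(orders_of[tx]))), 1L)
    if (abs(hd[1] - hd[2]) < min_hd_diff) next
    hi <- which.max(hd); lo <- 3 - hi
    r1 <- sum(rich[side[[hi]]]); r2 <- sum(rich[side[[lo]]])
    mp <- vapply(side, function(tx) max(as.numeric(mpoly[tx])), numeric(1))
    rows[[length(rows) + 1]] <- tibble(
      pair = paste0(side_label(side[[hi]]), "-", side_label(side[[lo]])),
      clade1 = list(side[[hi]]), clade2 = list(side[[lo]]),
      hd1 = hd[hi], hd2 = hd[lo],
      r1 = as.integer(r1), r2 = as.integer(r2),
      max_poly_side = if (mp[hi] > mp[lo]) "1" else if (mp[lo] > mp[hi]) "2" else "tie"
    )
    used <- c(used, unlist(side))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    pair = character(), clade1 = list(), clade2 = list(),
    hd1 = integer(), hd2 = integer(), r1 = integer(), r2 = integer(),
    max_poly_side = character()
  )
  out <- relative_richness(out)
  attr(out, "min_hd_diff") <- min_hd_diff
  class(out) <- c("contrast_set", class(out))
  out
}

side_label <- function(taxa) {
  if (length(taxa) == 1) taxa else paste0("(", paste(taxa, collapse = "+"), ")")
}

#' Relative richness of contrast pairs
#'
#' Adds (or recomputes) the relative species richness `rel = r1 / r2` of each
#' contrast (richness of the higher-host-diversity side over the other side)
#' and its base-10 logarithm, the quantity whose mean the paired t test
#' examines. Base 10 matches the conventional presentation (45/2 = 22.5,
#' log 1.352); the t statistic itself is base-invariant.
#'
#' @param contrasts Data frame with integer columns `r1`, `r2` (and
#'   optionally `hd1`, `hd2`).
#' @return The input with columns `rel`, `log10rel`, `positive` recomputed.
#' @export
relative_richness <- function(contrasts) {
  stopifnot(all(c("r1", "r2") %in% names(contrasts)))
  if (nrow(contrasts) && any(contrasts$r2 < 1 | contrasts$r1 < 1)) {
    abort("every clade must contain at least one species (r1, r2 >= 1)")
  }
  dplyr::mutate(contrasts,
    rel = .data$r1 / .data$r2,
    log10rel = log10(.data$rel),
    positive = .data$r1 > .data$r2
  )
}

#' Exact two-tailed sign test
#'
#' Exact binomial sign test at success probability 1/2:
#' `p = 2 * min(P(X <= k), P(X >= k))`, capped at 1. Ties must be removed
#' from `n` before calling (the convention used throughout this package).
#'
#' @param k_positive Number of positive outcomes.
#' @param n Number of non-tied trials, `n >= 1`.
#' @return An object of class `sign_test`: `k`, `n`, `p_value`.
#' @examples
#' sign_test(9, 10)$p_value   # 0.0215
#' sign_test(10, 10)$p_value  # 0.00195
#' @export
sign_test <- function(k_positive, n) {
  if (n < 1) abort("sign test undefined for n = 0 (all ties?)")
  stopifnot(k_positive >= 0, k_positive <= n)
  p <- min(1, 2 * min(pbinom(k_positive, n, 0.5),
                      pbinom(n - k_positive, n, 0.5)))
  structure(list(k = as.integer(k_positive), n = as.integer(n), p_value = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("Exact sign test: %d/%d positive, two-tailed p = %.4g\n",
              x$k, x$n, x$p_value))
  invisible(x)
}

#' @export
tidy.sign_test <- function(x, ...) {
  tibble(k = x$k, n = x$n, p_value = x$p_value)
}

#' Paired t test on log relative richness
#'
#' One-sample two-tailed t test of whether the mean of the contrasts'
#' log10 relative richness values exceeds zero — the parametric companion to
#' the sign test. Mean, SD and SE are reported separately.
#'
#' @param contrasts A `contrast_set` (or any data frame with `log10rel`).
#' @return An object of class `paired_log_t`: `mean`, `sd`, `se`, `t`, `df`,
#'   `p_value`, `n`.
#' @export
paired_log_t <- function(contrasts) {
  x <- contrasts$log10rel
  n <- length(x)
  if (n < 2) abort("need at least 2 contrasts")
  s <- sd(x)
  if (s == 0) abort("degenerate data: all log relative richness values identical")
  se <- s / sqrt(n)
  tval <- mean(x) / se
  structure(list(
    mean = mean(x), sd = s, se = se, t = tval, df = n - 1L,
    p_value = 2 * pt(abs(tval), n - 1, lower.tail = FALSE), n = n
  ), class = "paired_log_t")
}

#' @export
print.paired_log_t <- function(x, ...) {
  cat(sprintf(
    "Paired t on log10 relative richness: mean = %.2f (SD %.2f, SE %.2f), t_%d = %.2f, p = %.4g\n",
    x$mean, x$sd, x$se, x$df, x$t, x$p_value))
  invisible(x)
}

#' @export
tidy.paired_log_t <- function(x, ...) {
  tibble(estimate = x$mean, sd = x$sd, std.error = x$se,
         statistic = x$t, df = x$df, p.value = x$p_value)
}

#' Concordance of maximum polyphagy with host diversity across contrasts
#'
#' For each contrast, asks whether the higher-host-diversity side also holds
#' the single most polyphagous species (strictly larger `max_polyphagy`).
#' Ties are dropped; the concordant count is referred to an exact two-tailed
#' sign test. Uses the `max_poly_side` column when present (as in sets built
#' by [build_contrasts()] or the packaged printed fixture), otherwise
#' recomputes it from `traits`.
#'
#' @param contrasts A `contrast_set`.
#' @param traits Genus-trait table; only needed when `max_poly_side` is
#'   absent.
#' @return A list: `k_concordant`, `n`, `p_value`.
#' @export
concordance_most_polyphagous <- function(contrasts, traits = NULL) {
  side <- if ("max_poly_side" %in% names(contrasts)) contrasts$max_poly_side else NULL
  if (is.null(side)) {
    if (is.null(traits)) abort("need `traits` when `max_poly_side` is absent")
    mpoly <- setNames(traits$max_polyphagy, traits$taxon)
    m1 <- purrr::map_dbl(contrasts$clade1, ~ max(mpoly[.x]))
    m2 <- purrr::map_dbl(contrasts$clade2, ~ max(mpoly[.x]))
    side <- ifelse(m1 > m2, "1", ifelse(m2 > m1, "2", "tie"))
  }
  keep <- side != "tie"
  if (!any(keep)) abort("all contrasts are ties for maximum polyphagy")
  st <- sign_test(sum(side[keep] == "1"), sum(keep))
  list(k_concordant = st$k, n = st$n, p_value = st$p_value)
}

#' Correlation of host diversity with maximum polyphagy across taxa
#'
#' Squared Pearson correlation between a taxon's host diversity and the
#' polyphagy of its most polyphagous single species, with the standard
#' t-based p-value. A high value indicates that clade-level host diversity
#' reflects actual species-level polyphagy rather than summation over
#' specialists.
#'
#' @param traits Genus-trait table (at least 3 taxa).
#' @return A list: `r_squared`, `p_value`, `n`.
#' @export
hd_maxpoly_correlation <- function(traits) {
  ok <- traits$hd > 0
  if (sum(ok) < 3) abort("need at least 3 taxa with hd > 0")
  x <- traits$hd[ok]; y <- traits$max_polyphagy[ok]
  if (var(x) == 0 || var(y) == 0) abort("zero variance in hd or max_polyphagy")
  ct <- stats::cor.test(x, y)
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = sum(ok))
}
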