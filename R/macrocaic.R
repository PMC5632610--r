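#' Species-richness contrasts on a trait (MacroCAIC)
#'
#' Extends Felsenstein's independent contrasts to species richness: at every
#' internal node the trait contrast is the standard branch-length-standardized
#' daughter difference (Felsenstein's nodal reconstruction with weighted
#' averages and branch-length adjustment), oriented so the daughter with the
#' larger trait value is clade 1 (trait contrasts are therefore >= 0); the
#' response is the relative-rate-difference style richness contrast
#' `ln(N1 / N2)` with `N` summed over each daughter clade. The richness
#' contrasts are regressed on the trait contrasts through the origin.
#'
#' @param data Data frame with columns `taxon`, the trait column and the
#'   richness column, one row per tip.
#' @param tree A binary `phylo` object (see `polytomy` for the alternative).
#' @param trait Name of the trait column (character), e.g. `"log_hd"`.
#' @param richness Name of the richness column; values must be `>= 1`.
#' @param polytomy `"error"` (default) refuses multifurcating trees;
#'   `"resolve"` resolves each polytomy into a pectinate series of
#'   zero-length branches with a warning.
#' @return An object of class `caic_fit`: `contrasts` (tibble: `node`,
#'   `trait_contrast`, `richness_contrast`), `slope` (through the origin),
#'   `se`, `f_stat`, `p_value`, `adj_r_squared`, `df`.
#' @export
macrocaic <- function(data, tree, trait, richness, polytomy = c("error", "resolve")) {
  polytomy <- match.arg(polytomy)
  if (any(tabulate(tree$edge[, 1]) > 2)) {
    if (polytomy == "error") {
      abort("tree has polytomies; rerun with polytomy = \"resolve\" to accept a pectinate zero-length resolution")
    }
    warn("resolving polytomies into pectinate series of zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  for (col in c("taxon", trait, richness)) {
    if (!col %in% names(data)) abort(paste0("`data` lacks column ", col))
  }
  missing_tips <- setdiff(tree$tip.label, data$taxon)
  if (length(missing_tips)) {
    abort(paste0("no data for tip(s): ", paste(missing_tips, collapse = ", ")))
  }
  data <- data[match(tree$tip.label, data$taxon), ]
  x <- data[[trait]]
  N <- data[[richness]]
  if (any(N < 1)) abort("every tip must have richness >= 1")

  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edge_len <- numeric(ntot)  # length of edge above each node
  edge_len[po$edge[, 2]] <- po$edge.length
  xhat <- c(x, numeric(tree$Nnode))
  vadj <- c(edge_len[seq_len(ntip)], numeric(tree$Nnode))
  nsum <- c(N, numeric(tree$Nnode))
  kids <- node_children(tree)

  internal_po <- unique(po$edge[, 1])
  res <- vector("list", length(internal_po))
  for (i in seq_along(internal_po)) {
    nd <- internal_po[i]
    ch <- kids[[as.character(nd)]]
    c1 <- ch[1]; c2 <- ch[2]
    v1 <- vadj[c1]; v2 <- vadj[c2]
    if (v1 + v2 <= 0) abort("zero-length daughter pair; contrasts undefined")
    # orient so the daughter with the larger trait value is clade 1
    if (xhat[c2] > xhat[c1]) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- v1; v1 <- v2; v2 <- tmp }
    tc <- (xhat[c1] - xhat[c2]) / sqrt(v1 + v2)
    rc <- log(nsum[c1] / nsum[c2])
    res[[i]] <- tibble(node = nd, trait_contrast = tc, richness_contrast = rc)
    xhat[nd] <- (xhat[c1] / v1 + xhat[c2] / v2) / (1 / v1 + 1 / v2)
    vadj[nd] <- edge_len[nd] + v1 * v2 / (v1 + v2)
    nsum[nd] <- nsum[c1] + nsum[c2]
  }
  contrasts <- dplyr::bind_rows(res)
  stopifnot(all(contrasts$trait_contrast >= 0))

  m <- lm(richness_contrast ~ 0 + trait_contrast, data = contrasts)
  sm <- summary(m)
  nct <- nrow(contrasts)
  slope <- unname(coef(m)[1])
  if (all(contrasts$richness_contrast == 0)) slope <- 0  # exact, not 0 +/- eps
  fs <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
  structure(list(
    contrasts = contrasts,
    slope = slope,
    se = sm$coefficients[1, 2],
    p_value = sm$coefficients[1, 4],
    f_stat = fs,
    adj_r_squared = sm$adj.r.squared,
    df = nct - 1L,
    n_contrasts = nct
  ), class = "caic_fit")
}

#' @export
print.caic_fit <- function(x, ...) {
  cat("MacroCAIC species-richness contrast regression (through the origin)\n")
  cat(sprintf("  slope = %.3f; %s\n", x$slope, model_report(x)))
  invisible(x)
}

#' @export
tidy.caic_fit <- function(x, ...) {
  tibble(term = "trait_contrast", estimate = x$slope, std.error = x$se,
         statistic = x$slope / x$se, p.value = x$p_value)
}

#' @export
glance.caic_fit <- function(x, ...) {
  tibble(adj.r.squared = x$adj_r_squared, statistic = x$f_stat,
         df = x$df, p.value = x$p_value, nobs = x$n_contrasts)
}
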