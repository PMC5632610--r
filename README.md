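# oscillate

Comparative-phylogenetic tests of the **oscillation hypothesis**: the idea
that diversification in plant-feeding insects is driven by repeated
expansions (polyphagy) and contractions (re-specialization) of host range.
Its testable signature is that clades whose species collectively feed on
more host-plant orders — higher *host diversity*, HD — should contain more
species than related clades with narrower host use.

The package is aimed at entomologists and comparative biologists with a
genus-level phylogeny, species-level host records, and species-richness
estimates (the shape of data compiled for tussock moths, butterflies and
similar groups). It provides the full analysis chain as tidyverse-style
functions over `ape::phylo` trees and tibbles:

* **Phylogenetic signal for binary host-use traits.** The ML transition
  rate *q* of the symmetric two-state Markov (Mk/ER) model, with edge
  transition probability $P_\text{switch}(t) = \tfrac12(1 - e^{-2qt})$,
  computed by Felsenstein pruning (C++ kernel) with a flat root prior. Low
  *q* relative to tree depth means high signal; significance comes from
  refitting under random tip-label permutations,
  $p = \#\{\hat q_\text{perm} \le \hat q_\text{obs}\}/n_\text{perm}$.
* **Parsimony tracing.** Fitch-style minimum changes and exact MPR state
  sets for binary codings ("3+ orders", "7+ orders"); squared-change
  parsimony for HD as a continuous character.
* **Sister-clade contrasts.** Deterministic construction of phylogenetically
  independent pairs differing by at least `min_hd_diff` host orders
  (union HD per side, merging upward by tree adjacency), with relative
  richness $R_1/R_2$, the exact two-tailed sign test, the paired *t* test on
  $\log_{10}(R_1/R_2)$, and the most-polyphagous-species concordance check.
* **Phylogenetic regressions.** PGLS with Pagel's λ profiled by ML
  (covariance $\sigma^2 V_\lambda$, off-diagonals of the Brownian matrix
  scaled by λ), and MacroCAIC: independent contrasts with the
  species-richness response $\ln(N_1/N_2)$ regressed through the origin on
  standardized trait contrasts.
* **A synthetic-data module** (Yule trees, Mk traits, Brownian host
  breadth, richness log-linearly coupled to HD with λ-structured noise)
  so the whole pipeline is testable without any external data.

## Worked example

Reproduce the published ten-contrast analysis from the packaged fixture:

```r
library(oscillate)
run_contrast_reproduction()
#> Sister-contrast reproduction (packaged printed fixture)
#>   9 of 10 contrasts positive; Exact sign test: 9/10 positive, two-tailed p = 0.02148
#>   Paired t on log10 relative richness: mean = 0.60 (SD 0.48, SE 0.15), t_9 = 3.92, p = 0.003489
#>   concordance of max polyphagy: 10/10, p = 0.001953
```

Nine of ten contrasts have more species on the higher-HD side (sign test
p ≈ 0.021), the mean log₁₀ relative richness 0.60 is significantly above
zero (t₉ = 3.92), and in all ten contrasts the higher-HD side also holds
the single most polyphagous species (p ≈ 0.002) — host diversity tracks
real species-level polyphagy rather than an artifact of summing
specialists.

The same chain on a synthetic universe:

```r
tr     <- simulate_yule_tree(55, 1, seed = 30)
uni    <- simulate_host_universe(tr, sim_config(), seed = 31)
traits <- derive_genus_traits(uni$records, uni$richness)

permutation_signal_test(tr, code_binary_trait(traits, 7), n_perm = 999, seed = 32)
#> Phylogenetic signal (Mk rate) test: q = 0.2955, p = 0 (n_perm = 999)

d <- dplyr::mutate(traits, log_r = log10(n_species), log_hd = log10(hd))
pgls_fit(d, tr, log_r ~ log_hd)
#> PGLS (Pagel's lambda) fit
#>   beta = 0.79, SE = 0.15, F_53 = 28.43, p = 2.04e-06, R2 = 0.35, lambda = 0.79

cs <- build_contrasts(tr, traits, min_hd_diff = 3)
sign_test(sum(cs$positive), nrow(cs))
#> Exact sign test: 12/13 positive, two-tailed p = 0.003418

macrocaic(d, tr, "log_hd", "n_species")
#> MacroCAIC species-richness contrast regression (through the origin)
#>   slope = 1.806; df = 53; adjusted R-square = 0.124; F = 8.6; p = 0.00485
```

The "7+ orders" coding is strongly clustered on the tree (no permuted rate
as low as the observed one), and both regressions recover the positive
HD–richness relationship the universe was generated with. `autoplot()`
methods exist for contrast sets, signal tables and both fit types;
`tidy()`/`glance()` give broom-style summaries.

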