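---
title: "Methods: comparative tests of host-range oscillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative tests of host-range oscillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillate)
```

## The question and the data shape

The oscillation hypothesis holds that diversification in plant-feeding
insects is fuelled by repeated expansions (polyphagy) and contractions
(re-specialization) of host range. Its comparative signature is that clades
whose species collectively use more host-plant orders — higher *host
diversity* (HD) — should contain more species than related clades using
fewer orders. `oscillate` implements the full chain of analyses used to test
this signature on a genus-level phylogeny of herbivorous moths:

1. permutation-calibrated phylogenetic signal of binary host-use traits
   under a two-state Markov model;
2. parsimony tracing of polyphagy codings and of HD as a continuous
   character;
3. sister-clade contrasts of HD against species richness, with a sign test
   and a paired *t* test on log relative richness;
4. phylogenetic generalized least squares (PGLS) with Pagel's λ, and
   through-origin species-richness contrast regression (MacroCAIC).

The data model is deliberately tabular: a species-level host-record table
(moth species, genus-level taxon, plant family, plant order), an externally
supplied species richness per taxon, and a rooted tree with branch lengths
over the taxa. Everything user-facing takes and returns tibbles; trees are
`ape::phylo` objects.

## Phylogenetic signal for binary traits

Commonly used signal statistics (Pagel's λ, Blomberg's K) target continuous
traits. For binary host-use traits the package instead uses the maximum-
likelihood transition rate *q* of the symmetric two-state Markov (Mk/ER)
model as an inverse signal measure: a trait that switches rarely relative to
tree depth is phylogenetically conserved. Along a branch of length *t* the
chain stays with probability $(1 + e^{-2qt})/2$. The likelihood is computed
by Felsenstein pruning with a flat $(\tfrac12, \tfrac12)$ root prior (the ER
model is symmetric, so a stationary prior is identical); the kernel is in
C++ because the permutation test refits the rate tens of thousands of
times.

Numerical choices:

* the tree is rescaled to unit depth and *q* optimized on the log scale in
  $[10^{-8}, 10^3]$; the fitted rate is reported on the original scale.
  Rates are therefore interpretable only relative to tree depth, and rates
  from trees in different branch-length units must not be compared;
* a constant trait drives $\hat q$ to the lower bound (the likelihood is
  monotone decreasing in *q*), reported as `bounds_hit = "lower"`;
* missing tip states enter as partial likelihood $(1, 1)$ rather than tip
  deletion, so permutations act on a fixed tip set.

Significance comes from shuffling the observed states across the tips
(state counts preserved) and refitting: with `n_perm` permutations the
p-value is the raw fraction of permuted rates at or below the observed rate.
Ties count against the observed rate (conservative for a low-tail test). The
raw fraction can be exactly 0, which is how the result tables conventionally
print a perfectly clustered trait; the `(k+1)/(n+1)` upper bound is reported
alongside since a raw 0 is not a valid probability statement.

**What the calibration shows.** Under iid fair-coin tip states the test
rejects at the nominal 5% rate (the acceptance script measures this). Under
traits simulated at `q = 0.1` on unit-depth 100-tip trees, measured power is
only about 0.65: at that rate the expected number of state changes per tree
is ≈ 2.4, so roughly one simulated trait in eight is constant (untestable;
p = 1 by construction) and another quarter has only one or two minority
tips, configurations that no tip-shuffling test can distinguish from chance
at α = 0.05. Power conditional on at least two minority tips is ≈ 0.8. This
is a property of the simulation regime, not of the implementation.

## Parsimony tracing

Binary codings ("3+ orders", "7+ orders": does any species of the taxon
feed on at least 3, resp. 7, plant orders) are traced by unweighted
parsimony. `fitch_trace()` computes the minimum number of changes and the
exact set of states each node takes in at least one most-parsimonious
reconstruction, via a unit-cost dynamic program (down-pass subtree costs,
up-pass outside costs). On binary trees this is exactly Fitch parsimony; at
polytomies the DP remains exact, whereas the classical
intersection-else-union shortcut can undercount changes (four daughters with
states 0, 0, 1, 1 need two changes, the shortcut counts one) — that is why
the DP was chosen.

Host diversity is traced as a continuous character by squared-change
parsimony: internal values minimize the sum of squared changes over edges,
the solution of the linear system in which every internal node is the mean
of its neighbours. Branch lengths are ignored by default (the trace is a
length-free visualization aid, like the binary tracing); `weighted = TRUE`
divides each squared change by branch length for users who want the
Brownian-flavoured variant.

## Sister-clade contrasts

Published contrast analyses of this kind selected "putative sister clades"
partly by eye, guided by the traces. The package replaces that judgement
with a deterministic rule so results are reproducible: a post-order sweep
emits, at each binary node whose daughters contain no already-used taxon,
the daughter pair as a contrast when the union host diversities of the two
sides differ by at least `min_hd_diff` (default 3 orders; 1 gives the
permissive "any sister pair" variant). Clades that fail the criterion stay
free to merge at the next ancestor — merging strictly by tree adjacency,
never by HD-sorted cherry-picking, which would bias the contrast set. Pairs
never share taxa, so contrasts are phylogenetically independent. Polytomous
candidate nodes are skipped with a warning; users may pre-resolve them or
supply a hand-built pairs table (any data frame with the contrast columns
works downstream).

Each contrast is summarized by relative richness `rel = r1/r2` (side 1 is
the higher-HD side) and `log10(rel)`. Base 10 is the printed convention of
the reference tables (45/2 = 22.5 → 1.352); the paired *t* statistic is
base-invariant. The sign test is the exact two-tailed binomial test at
p = ½, `2·min(P(X ≤ k), P(X ≥ k))` capped at 1, with ties (r1 = r2)
dropped beforehand. The paired *t* test is the one-sample test of whether
mean log relative richness exceeds zero; mean, SD and SE are reported as
separate, correctly labelled fields (published prose sometimes mislabels the
SD as "SE" in this context — with ten contrasts the *t* value only checks
out against mean/(SD/√10)).

The concordance check asks, per contrast, whether the higher-HD side also
contains the single most polyphagous species; ties are dropped and the
concordant count goes through the same exact sign test.

The ten published contrasts ship as a plain-text fixture
(`published_contrasts()`), values exactly as printed. One printed relative-
richness cell (62/26 shown as 2.39) differs by one unit in the last digit
from the recomputed 2.3846 — its log column (0.377) is consistent with the
recomputation, so the package treats agreement to one unit in the last
printed place as reproduction.

## PGLS with Pagel's λ and MacroCAIC

`pgls_fit()` fits, by generalized least squares, models such as
`log10(richness) ~ log10(hd)` with error covariance
$\sigma^2 V_\lambda$, where $V$ is the Brownian shared-path-length matrix of
the tree and $V_\lambda$ multiplies its off-diagonals by λ. λ = 0 is
ordinary least squares, λ = 1 full Brownian covariance. λ is profiled by
full maximum likelihood on a 0.01 grid over [0, 1] followed by golden-
section refinement — a reproducible single-parameter search that avoids
multimodality surprises. $R^2$ is defined against the intercept-only model
fitted under the same $\hat\lambda$, in the whitened coordinates, and the F
statistic is the matching model comparison; this mirrors how the
reference analysis reported explained variance. Near-singular covariances
(zero-length terminal twins at λ = 1) get a $10^{-10}$ ridge with a
warning. Both variables are expected already log-transformed by the caller
(base 10 by default in the pipeline; slope and $R^2$ are base-invariant when
both variables share a base).

`macrocaic()` extends independent contrasts to species richness: trait
contrasts are the standard branch-length-standardized daughter differences
(Felsenstein's weighted-average nodal reconstruction), oriented so the
higher-trait daughter is clade 1; the response at each node is the
relative-rate-difference style `ln(N1/N2)` with N summed over the daughter
clades, deliberately unstandardized, and the regression is forced through
the origin. Degrees of freedom are `n_contrasts − 1`. Polytomies are
refused by default; an explicit policy resolves each into a pectinate
series of zero-length branches with a warning.

Because the `ln(N1/N2)` response is unstandardized while the trait contrast
is standardized, the per-node effect size scales with the (variable) branch
lengths, which costs the through-origin regression power relative to PGLS on
the same data: under the generator's default regime (below) PGLS attains
essentially full power at 60 taxa while MacroCAIC's measured power is about
0.8. The package reports both, as the original analyses did, treating
MacroCAIC as the robustness check.

## The synthetic universe

`simulate_host_universe()` generates data with the statistical structure the
analysis assumes, so every stage is testable without external data:

* **Tree** — pure-birth (Yule): with *k* lineages alive the next split waits
  Exp(*k*·birth_rate) and hits a uniform lineage; a final Exp(*n*·rate)
  epoch runs to the present, so expected depth is
  $(1/b)\sum_{k=2}^{n} 1/k$.
* **Host diversity** — log host breadth evolves by Brownian motion
  (variance `hd_signal = 1.5` per unit depth, root at log 6), exponentiated
  and rounded to `hd ≥ 1`. This spans HD ≈ 1–40 across taxa, the observed
  range in genus-level compilations.
* **Order identities** — drawn rank-weighted (weight ∝ 1/rank) from a pool
  of 46 named plant orders (42 angiosperm + 4 other), matching the number of
  orders recorded for tussock moths; the rank weighting makes a handful of
  orders dominate, as in real host compilations.
* **Species-level polyphagy** — one "champion" species per taxon feeds on
  `1 + Binomial(hd − 1, coupling)` of the taxon's orders; remaining orders
  are spread round-robin over the other recorded species (capped at
  `max_recorded_species = 30`, mimicking incomplete recording), every order
  covered by at least one species so the derived table reproduces the
  generator's ledger exactly.
* **Richness** — `round(10^(1.2 + beta_true·log10(hd) + ε))`, floored at 1,
  with ε multivariate normal, covariance `noise_sigma²·V_λ(lambda_true)`.
  The residual is phylogenetically correlated on purpose: analyses of these
  data find λ ≈ 0.7, and iid noise would make λ-recovery checks vacuous.

Defaults are the regime the reference analysis estimated from real data:
`beta_true = 0.77`, `lambda_true = 0.70`, 55 taxa. The two free noise knobs
were calibrated against published summary statistics, not against any test
outcome: `noise_sigma = 0.37` reproduces PGLS $R^2 ≈ 0.40$ and
`coupling = 0.7` brings the hd–max-polyphagy $r^2$ near 0.9 at 60 taxa.

What the generator does **not** emulate: taxonomic error and unreported
hosts (beyond the recording cap), genus re-circumscription, correlated
sampling effort between host records and species description, and
non-Yule tree shape. Passing recovery tests on these universes therefore
shows the estimators are consistent under the assumed model, not that the
real-data conclusions are immune to those biases.

## Problem sizes and determinism

Every generator accepts a seed and restores the RNG state afterwards
(`withr::with_seed`); pipelines fan a master seed out to fixed per-stage
offsets so stages can be re-run in isolation. The test suite exercises
exhaustive likelihood/parsimony oracles on all rooted topologies with up to
six tips, permutation calibration at 500 null replicates (99 permutations
each, 100-tip trees), PGLS recovery at 200 replicates of 60 tips, and
MacroCAIC calibration at 500 null replicates — sizes chosen to keep the
whole suite in a few minutes on one core while leaving Monte-Carlo bands
(e.g. [0.025, 0.075] for a 5% test) comfortably wider than simulation
error.

## Known limitations

* Transition rates are comparable only within one tree and branch-length
  scale; the package never pools rates across trees.
* The contrast-building rule is one deterministic resolution of an
  informal published procedure; alternative merge orders can yield
  different (equally defensible) contrast sets. The packaged printed
  contrast table is the fixture of record for reproduction.
* `sign_test()` assumes exchangeable contrast signs; the paired *t* test
  assumes approximate normality of log relative richness.
* Likelihood-based ancestral state estimation and trait-dependent
  diversification models (BiSSE-family) are out of scope by design; the
  signal machinery uses rates only.
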