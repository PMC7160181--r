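---
title: "Clade indices as surrogates for phylogenetic diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade indices as surrogates for phylogenetic diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladiv)
```

## The problem and the model

Phylogenetic diversity summarizes how much evolutionary history a community
contains and how it is distributed. Three dimensions are conventionally
distinguished, each with a leading metric:

* **richness** — Faith's PD, the sum of branch lengths of the subtree
  spanning the community's species;
* **divergence** — MPD, the mean pairwise patristic distance among them;
* **regularity** — VPD, the variance of those pairwise distances (low
  variance = high regularity).

All three require a dated phylogeny. The clade indices replace the phylogeny
with a categorical signal: species' membership in named clades (families,
orders, or any monophyletic partition), plus relative abundances. The premise
is that treating phylogeny as a category — effectively collapsing each clade
to a polytomy — discards within-clade structure while retaining the deep
structure that dominates the metrics, so index values should track the
metrics closely wherever the classification is reasonably fine.

With `S` the plot's species richness, `p_i` clade `i`'s proportion of the
plot's total cover, `CR_i` the clade's species richness in the reference
species pool, `CR_SP` the number of pool clades and `S_SP` the pool
richness:

* clade richness index: `log(S) + 3 Σ p_i / CR_i` (natural log). Cover in
  species-poor clades is up-weighted, because a species from a small clade
  is more likely to be a distant relative of the rest of the plot, which is
  what stretches Faith's PD.
* clade divergence index: `1 − Σ (p_i − 1/CR_SP)²`. MPD peaks when all pool
  clades are present in equal proportion; squared deviations from that
  optimum lower the index. The value is always in `(0, 1]`: the squared
  deviation sum of a point on the simplex is at most `1 − 1/CR_SP < 1`.
* clade regularity index: `1 − Σ (p_i − CR_i/S_SP)²`. VPD is lowest (the
  distance distribution most even) when each clade's cover matches its
  relative pool richness.

Both quadratic indices sum over **all** pool clades, with absent clades
contributing their full squared deviation. The alternative — summing only
over clades present in the plot — is available via `absent = "exclude"` as a
sensitivity switch, but the default is the only reading under which the
stated optima ("all clades present, in optimal proportion") actually attain
the maximum of one.

Two boundary facts are worth knowing. First, the regularity index is *not*
confined to `[0, 1]`: a plot concentrated on a small clade can push it
negative (e.g. pool richness vector (4,3,2,1) with all cover on the rarest
clade gives −0.10). Values are returned unclipped, so downstream filters
such as "use the regularity surrogate only above 0.2" operate on the raw
scale. Second, the constant multiplier 3 in the richness index is part of
the definition, not a tuning parameter; it only rescales the index, and the
linear fits below are invariant to it up to slope.

## The phylogeny-based metrics

All metrics are abundance-weighted by relative cover and computed on the
species actually present in a plot ("type II": the plot's subset tree or
distance submatrix). Distinctiveness-score ("type I") indices are out of
scope.

* **Weighted Faith's PD.** The tree is pruned to the plot's species (stem
  above their common ancestor discarded; unary nodes collapsed with lengths
  summed). Each branch `i` with length `λ_i` is weighted by the mean
  relative abundance `Ā_i` of the species descending from it, and
  `PD_w = B · Σ λ_i Ā_i / Σ Ā_i` with `B` the branch count. The scaling is
  chosen so equal abundances reduce `PD_w` exactly to the unweighted sum of
  branch lengths — the one behavior the classical definition pins down —
  and the tests enforce that reduction against an independent path-sum
  oracle.
* **Weighted MPD.** `Σ_{j<k} f_j f_k d_jk / Σ_{j<k} f_j f_k` over unordered
  pairs of distinct species. Note that some implementations in circulation
  average over ordered pairs *including* `j = k`, which shrinks the value
  by the factor `1 − Σ f_j²`; the unordered-pair form reduces to the plain
  mean of pairwise distances at equal abundances, which the full-matrix
  form does not.
* **Weighted VPD.** The matching weighted *population* variance
  `Σ w_jk d_jk²/Σ w_jk − MPD²`, `w_jk = f_j f_k`. No `n−1`-style correction
  is applied: the quantity is the variance of the plot's own distance
  distribution, not an estimate of a superpopulation parameter. Two-species
  plots therefore have VPD = 0.

Plots with a single species have no pairwise structure; all three metrics
are `NA` there and such rows are dropped (with a recorded count) from every
fit. Abundance rescaling, and species with zero abundance, provably change
nothing.

## Fitting surrogates to metrics

Fit accuracy is the ordinary R² of a linear model of the metric on its
index. Faith's PD is square-root transformed and VPD log-transformed
(natural log) before fitting; MPD is fitted untransformed. The square root
tames the strong right skew PD inherits from species richness; the log does
the same for VPD while also making multiplicative scale differences
additive. Nonpositive responses under the log (VPD = 0 at `S = 2`) are
dropped with a recorded count. A quadratic term can be added
(`quadratic = TRUE`); its Wald p-value is reported, and R² from the
quadratic model is reported alongside the linear one rather than replacing
it, since which variant a given analysis keeps is a modelling choice.

The regularity fit is heteroscedastic in practice — residual spread shrinks
as the index grows — so `fit_gls_varexp()` offers generalized least squares
with the exponential variance class, `Var(ε_i) = σ² exp(2δ v_i)`, fitted by
maximum likelihood via `nlme::gls`. The variance covariate `v` defaults to
the predictor (the clade index), which is where the fanning is observed;
any covariate can be supplied. Because ordinary R² is undefined for GLS,
the squared correlation between fitted and observed values is reported and
labelled a pseudo-R². Fixing `δ = 0` reproduces OLS exactly (tested to
1e-8), and the package's tests verify that `δ` is recovered to ±0.1 from
data simulated at n = 2000 with `δ = 0.8`.

## The simulation workflow

The factorial design asks where the surrogates are reliable. Its axes:

* **phylogenetic scale** — which tree the species pool is drawn from
  (nested clades of increasing age in the motivating study; here one tree
  per scale);
* **species pool size** — 2000, 500 or 250 species drawn uniformly from the
  scale's tree (reference design);
* **species richness range** — per-site richness drawn uniformly from
  10–160, 10–80, 10–40, 10–20, 5–10 or 2–5 (reference design);
* **replicates** — 50 community matrices of 240 sites per cell, giving
  2700 matrices, 900 per scale.

Per site, `S` species are drawn uniformly without replacement and their
proportions are independent `runif` draws renormalized to sum to one. A flat
Dirichlet (uniform on the simplex) is available via
`proportions = "dirichlet"`. The choice matters more than it looks: flat
Dirichlet draws produce markedly heavier dominance at moderate richness,
which adds abundance-weighting noise to the metrics and — in our
experiments — reverses the low end of the richness-accuracy gradient (the
2–5 range fits *better* than 5–10 under Dirichlet, at every scale and seed
we examined, including a 2000-species pool). The renormalized-uniform
default is both the natural reading of "random proportions summing to one"
in this field's scripting idiom and the regime in which fit accuracy rises
monotonically along the richness gradient, as observed in real and
simulated vegetation data.

**Synthetic scales.** When no real megaphylogeny is supplied, each scale is
a pure-birth (Yule) tree rescaled to a target height, with heights 400, 180
and 120 time units by default — proportional to the crown ages of
vascular plants, angiosperms and superasterids, the nested clades the
design emulates. Clades are defined by cutting every scale tree at a single
absolute depth (80 by default), playing the role of a fixed taxonomic rank
age. A consequence worth spelling out: at shallower scales the same cut
yields fewer, species-richer clades — the same granularity ladder a fixed
rank produces on nested clades of a real phylogeny (a 2000-species
superasterid pool spans far fewer families than a 2000-species vascular
pool). The desk-scale configuration (`sim_config_demo()`) uses 3000-tip
scale trees: with much smaller trees, a single Yule draw per scale leaves
tree-level sampling variance dominating the between-scale comparison of the
(weak) regularity signal.

`stretch_tree_above()` is provided for sensitivity analysis: it rescales
only the tree above the clade cut, so one can hold clade granularity fixed
while varying deep divergence depth. Doing so collapses the divergence
surrogate's signal almost entirely — evidence that the granularity ladder,
not just deep-branch heterogeneity, carries the scale effect in this
design.

**Seeds.** A master seed plus stable label hashing gives every design cell
its own derived seed (`derive_seed`), so single cells can be regenerated in
isolation and the full run is byte-reproducible; the tests check that the
2700 reference cells have collision-free seeds.

**What the generator does not emulate.** Random species draws and random
proportions contain no community assembly: no habitat filtering, no
dominance structure, no spatial autocorrelation, and Yule trees lack the
imbalance and rate heterogeneity of real megaphylogenies. Surrogate fits on
real vegetation data are generally *tighter* than on these null communities
(non-random assembly concentrates communities along the index gradients), so
the simulated R² values are conservative; passing the simulation checks
says the machinery and the qualitative gradients are right, not that a
particular R² will be attained in field data.

## Variance components of fit accuracy

To attribute the variance of per-matrix R² to the design factors, the
factors are treated as hierarchically nested random effects
(scale / pool size / richness range) and decomposed by balanced-design
expected mean squares (method of moments): `σ²_residual = MS_E`,
`σ²_range = (MS_range − MS_E)/n`, `σ²_pool = (MS_pool − MS_range)/(cn)`,
`σ²_scale = (MS_scale − MS_pool)/(bcn)`, negative estimates truncated to
zero, then expressed as percentages of their sum. The design is balanced by
construction (equal replicates per cell), where EMS is consistent and
closed-form; on unbalanced data (e.g. after dropping degenerate cells) the
`balance = "drop"` option trims every innermost cell to the smallest
complete replicate count first, and a REML fit could give slightly
different answers. Strata with a single level contribute zero variance and
are bridged in the EMS chain. The estimator is validated generatively:
components of (50, 0, 30, 20)% injected at the reference replication are
recovered within ±5 percentage points (averaging variance-scale estimates
across simulations before normalizing — averaging the percentages directly
is biased for the top-level component, whose mean square has only two
degrees of freedom).

## Numerical choices and degenerate inputs

* Distances and depths are measured from the tips (tips at height zero);
  trees need not be ultrametric except where a depth cut is requested.
* Zero-length edges are accepted (supertree polytomies are often encoded
  this way); zero-length chains merge harmlessly in the weighted-PD branch
  bookkeeping, which groups edges by their descendant sets (equal
  descendant counts along a parent chain imply equal sets).
* Community values are accepted as raw covers; normalization to proportions
  happens inside the metric and index functions, never at read time — plot
  covers need not sum to 100.
* Species present in a community matrix but absent from the tree or clade
  map are a hard error; `allow_drop = TRUE` drops them with a logged list,
  and erroring if a site is left empty.
* A depth cut at exactly a node's height assigns the node below the cut
  (its child lineages become clades). Just below the root the partition has
  as many clades as the root has children; exactly one clade would need the
  cut at or above the root, which the precondition excludes.
* Fits with fewer than three complete pairs, or zero variance in predictor
  or response, raise a classed degenerate-fit error; the factorial runner
  records such cells as `NA` with the reason and the variance decomposition
  can drop them to balance.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run everything at desk scale: 100
random trees of at most 20 tips for the metric-oracle equivalences; a
factorial of three 3000-tip synthetic scales × pool 250 (plus 120/60 in the
acceptance script) × four richness ranges (2–5, 5–10, 10–20, 10–40) × 10–20
replicates of 240-site matrices for the qualitative gradients; and a
matrices-only instantiation of the full 2700-cell reference design for the
count checks. The reference-scale fits themselves require a user-supplied
megaphylogeny and are exercised only when such a tree is provided.

## Known limitations

* The indices need abundance data; presence/absence communities are out of
  scope by construction (all `p_i` equal would collapse the quadratic
  indices to functions of clade counts).
* Fit accuracy degrades in species-poor plots (fewer than ~10 species) and
  for divergence/regularity at very large phylogenetic scales — the
  simulation module exists precisely to map these regimes.
* Like species richness itself, the indices' attainable range contracts as
  `S` grows; null-model or rarefaction standardization is deliberately not
  implemented here.
* The clade maps are taken as given; misassignments propagate directly into
  the indices.
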