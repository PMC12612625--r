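---
title: "Partitioning trait variation and quantifying phenotypic plasticity in two-garden clonal designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variation and quantifying phenotypic plasticity in two-garden clonal designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitplast)
```

## The design and the question

`traitplast` analyses trait data from a classical two-garden clonal
design: the same set of clonally propagated varieties (genetically
identical individuals) is grown in two environmentally contrasting
plantations, alongside varieties present at only one of the sites. Because
clones are genetically identical across sites, any systematic trait
difference a *common* variety shows between the gardens is environmentally
induced — phenotypic plasticity — while differences *among* varieties
within a garden reflect genetic variation.

The reference design the package defaults emulate is an olive
(*Olea europaea*) varietal collection pair: a subhumid and a drier,
irrigated semi-arid garden, roughly 50 varieties screened per site of
which 17 are common, 2–3 adult trees per variety, and ten functional
traits covering the leaf, stem and branch carbon/water economies
(LA, LW, LL:LW, LMA, LDMC, LT, SSL, A~S~:A~L~, BWD, RBT; see
`trait_names_canon()` for units).

## Trait derivation

Traits are ratios of raw measurements: LMA = leaf dry mass / leaf area
(g m^-2^), LDMC = dry / fully hydrated fresh mass (mg g^-1^), SSL = twig
length / dry mass, A~S~:A~L~ = sapwood cross-section / twig leaf area,
RBT = 2 × mean bark thickness / mean branch diameter. Two conventions are
fixed here and worth stating:

* ratios are computed **per sample** (leaf, twig, branch) and then
  averaged to the tree, not as ratios of means — the two differ whenever
  the denominator varies among samples;
* the sapwood area uses the ellipse through the two perpendicular
  diameters, `A_S = pi/4 * d1 * d2`. A mean-diameter circle is the obvious
  alternative; the ellipse is exact when the cross-section is elliptic and
  the two agree to second order in the asymmetry.

All unit conversions are centralized in `derive_leaf_traits()`,
`derive_stem_traits()` and `derive_branch_traits()` and covered by unit
tests.

## Variance partitioning

Following standard practice for such collections, percentage contributions
are computed from one-way ANOVA sums of squares on tree-level values
(`variance_components()`):

* **genetic** share: between-variety SS / total SS, variety as factor,
  all varieties and both sites pooled;
* **plastic** share: between-site SS / total SS, site as factor, common
  varieties only;
* **residual** share: within-variety SS / total SS from the variety ANOVA.

The three shares come from *two different models* and are deliberately not
rescaled to sum to 100; every number is reported next to its parent ANOVA.
The genetic share, in particular, also absorbs site and interaction
variance contributed by the single-site varieties — it is the share of a
one-way decomposition, not a variance-component estimate from a mixed
model (REML partitioning is out of scope on purpose: the sums-of-squares
convention is what makes the shares comparable with the published
literature on these collections).

The site × variety interaction — does the *magnitude* of plasticity differ
among varieties? — is tested with `twoway_anova_site_variety()`. Tree
counts of 2–3 make the design mildly unbalanced, so Type II sums of
squares are used, computed by explicit least-squares model comparison
(each main effect against the model with the other main effect, the
interaction against the additive model). With balanced data this reduces
to the sequential decomposition exactly.

One calibration subtlety is worth recording. Under a simulated null with
genetic variance but no site effect, the p-values of the *one-way* site
ANOVA are conservative, not uniform: trees cluster by variety, and common
varieties share their genetic draw across both sites, which inflates the
within-group mean square. The exact null calibration therefore uses the
site term of the two-way model, where the variety factor absorbs the
genetic variance; the test suite verifies uniformity of those p-values by
a Kolmogorov–Smirnov check over 500 simulated replicates.

## The phenotypic dissimilarity index (PhD)

Per common variety and per trait, PhD measures cross-site dissimilarity
discounted by within-site variability. Traits are first standardized
(z-scores over all common-variety trees pooled across both sites), then,
with \(\bar B\) the mean absolute difference over all cross-site tree
pairs and \(\bar W\) the mean absolute pairwise difference pooled over
within-site pairs of both sites,

$$\mathrm{PhD} = \max\!\left(0, \frac{\bar B - \bar W}{\bar B}\right),
\qquad \mathrm{PhD} = 0 \text{ when } \bar B = 0 .$$

This form is one concrete realization of a verbally specified index family
("average pairwise dissimilarity between sites while accounting for
within-site variability", ranging 0–1); published values computed with
other members of the family are comparable only qualitatively, which is
why the package asserts the index's *properties* (range, degenerate cases,
brute-force pair-enumeration agreement, monotonicity in the simulated site
effect) rather than any published numeric value. Two alternatives ship as
named variants of `phd_index()`: `overlap` (the complement of the relative
overlap of the two sites' value ranges) and `rdpi` (the classical relative
distance plasticity index \(\mathrm{mean}\,|x_i-x_j|/(x_i+x_j)\) on raw,
positive trait values). All downstream outputs record which variant
produced them.

Trait-level plasticity is compared by `rank_traits_by_phd()`: a one-way
ANOVA on the variety-level PhD values with trait as factor, Tukey's HSD
(studentized-range p-values, Tukey–Kramer standard errors for unequal n)
and a compact letter display (insert-and-absorb algorithm; letter sharing
is equivalent to non-significance, verified by brute force up to six
groups).

## The multivariate plasticity index (MVPi)

Plasticity rarely involves one trait at a time. MVPi summarizes a
variety's whole-phenotype displacement between sites: trees are projected
on the first three principal components of a PCA, and MVPi is the mean
Euclidean distance between a variety's trees at site 1 and at site 2 in
that space.

A cross-site distance requires a *common* coordinate system, so the PCA is
fitted once on the pooled standardized tree × trait matrix of both sites
(correlation-matrix PCA, unscaled scores). Per-site PCAs — used below for
strategy scoring — cannot serve here, since scores from two different
ordinations are not commensurable. When the number of retained components
equals the number of traits, the projection is a full orthonormal basis
and MVPi equals the mean cross-site distance in the standardized trait
space itself; the test suite checks this rotation invariance to 1e-10.
Note that MVPi is a mean over tree *pairs*: it is zero only when each
tree's phenotype is identical across sites, not merely when the two
site clouds coincide as sets.

## Ordination and the fast–slow axis

`pca_site()` runs a correlation-matrix PCA per site on complete-case
trees (eigendecomposition, components ordered by eigenvalue, dominant
trait signed positive for determinism). The first three components are
varimax-rotated (`varimax_rotate()`, orthogonal rotation with Kaiser row
normalization; communalities are invariant, which the tests check at
1e-10, and a k = 2 exhaustive grid search over the single rotation angle
confirms the criterion optimum). Rotated components are re-ordered by
explained variance and re-signed deterministically.

The fast–slow (acquisitive–conservative) axis is identified as the
rotated component maximizing \(|l_{\mathrm{LMA}}| + |l_{\mathrm{LDMC}}|\),
oriented so LMA loads positive — higher scores mean denser, slower,
more conservative phenotypes. This orientation is a convention and is
stated in every output header. Variety scores are tree-score means per
site (`fast_slow_scores()`), and `plasticity_strategy_correlations()`
correlates them with each trait's PhD and with MVPi (Pearson r, two-sided
p via the t transform, Fisher-z confidence intervals; 11 tests per site,
unadjusted by default to match common reporting practice, with a Holm
option).

## The synthetic common-garden generator

Every stage is testable without field data through
`simulate_trait_table()`, which draws tree-level values under the additive
model

$$x_{vskt} = \mu_t + G_{vt} + E_{st} + I_{vst} + \varepsilon_{vskt},$$

with variety effects \(G \sim N(0, \sigma^2_G)\), a fixed two-level site
contrast of magnitude \(\sigma_E\) (sign per trait), interaction
\(I \sim N(0, \sigma^2_I)\) and residual tree noise. Component variances
are \((\mu_t \cdot CV_t)^2\) split by configurable fractions
\((f_G, f_E, f_I, f_{res})\), so the fractions are the expected variance
shares. Common varieties receive one genetic draw placed at both sites —
the clonal identity that makes the design informative. Values are drawn on
the trait's natural scale and truncated at a small positive floor in the
(vanishingly rare, at realistic CVs) event of a negative draw.

Defaults emulate the reference study: 17 common + 33 distinct varieties
per site, 2–3 trees, ten traits with means inside published olive ranges
(e.g. LMA 277 g m^-2^ within 218.6–335.4; BWD 0.75 g cm^-3^ within
0.64–0.86), CVs of 6–22% averaging ≈ 13–14%, large plastic fractions for
the density/allocation traits (LDMC 0.39, LMA and A~S~:A~L~ 0.30, BWD
0.25, RBT 0.20) and near-zero ones for leaf dimensions and thickness,
with a drier site 2 (denser tissues, lower A~S~:A~L~). These values were
fixed once from the published ranges and qualitative contrasts; they are
study conditions, not tuning knobs.

What the generator does *not* emulate — and hence what passing tests do
not establish about field data: trait–trait correlations (traits are drawn
independently, so e.g. the empirical LMA–LDMC coupling of a real leaf
economics spectrum is absent unless constructed in a fixture),
non-Gaussian trait distributions, measurement-year and plot effects, and
spatially structured microenvironments. Recovery tests
(`recover_components()`) show the plastic variance fraction is estimated
with a small upward bias (≈ 1–2 points at 17 varieties × 3 trees, because
between-site noise also enters the site SS), well within the ±5-point
band asserted over 200 replicates.

## Numerical choices and degenerate inputs

* Sample (n−1) SDs throughout; small variety groups make this the
  defensible default.
* p-values are floored at 1e-300 to keep logs finite.
* PhD is clipped at 0 when within-site spread exceeds the cross-site
  signal; `phd_index` returns 0 (not NaN) when \(\bar B = 0\).
* Ties in the fast–slow selection criterion are reported and resolved in
  favour of the first component.
* Standardization refuses zero-variance traits; PCA refuses constant
  traits and fewer complete trees than traits + 1.
* Varieties with trees missing a trait lose those trees for MVPi only
  (complete-case per analysis), never globally; PhD uses all non-missing
  trees per trait.
* Aridity classes use the standard De Martonne thresholds 10/20/30 with
  the humid class open at 30 (an index of exactly 30 is Subhumid).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data at
the reference-design scale (17 common varieties × 2–3 trees × 10 traits)
or smaller: 500 replicates for the null-calibration KS check, 200 for the
plasticity-fraction recovery, 1000 × 11 null correlations, and brute-force
oracles on fixtures of up to 5 trees per site. These sizes give the
Monte-Carlo checks standard errors comfortably inside their asserted
bands while keeping a full run in well under a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
res <- run_pipeline(cfg, "plasticity_run")

res$partition          # per-trait genetic / plastic / residual shares
res$ranking            # traits by mean PhD, with Tukey letters
sort(res$mvpi, decreasing = TRUE)
res$correlations       # fast-slow score vs plasticity, per site
```

All outputs are written as provenance-headed CSVs plus a JSON manifest
whose per-file checksums are reproducible under a fixed seed.

## Known limitations

* The PhD formula is one member of a verbally specified family; absolute
  values are not comparable across implementations (relative trait
  rankings are far more stable).
* The MVPi coordinate system (pooled-site PCA) is a documented choice;
  scores and hence absolute MVPi values change under per-site or
  eigenvalue-scaled conventions, the mean-distance structure does not.
* The sums-of-squares variance shares are descriptive, not mixed-model
  variance components.
* Only two-site designs are supported; the indices generalize to more
  sites but the design bookkeeping here does not.
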