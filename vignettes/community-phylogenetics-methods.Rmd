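---
title: "Methods: phylogenetic alpha and beta diversity along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic alpha and beta diversity along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevphylo)
```

## The problem

Communities sampled along an elevational gradient differ in which species
they contain and in how much evolutionary history those species span. Under
phylogenetic niche conservatism — close relatives being ecologically more
similar than distant ones — the phylogenetic structure of a community is a
readable signature of the processes that assembled it: environmental
filtering concentrates close relatives (clustering), interspecific
competition spreads co-occurring species across the tree (overdispersion),
and neutral assembly leaves no structure. `elevphylo` implements the full
inference chain for presence/absence assemblages on such a gradient:

1. **Trees.** Species-level phylogenies are rarely available for diverse
   arthropod groups, so a genus-level backbone is resolved to species level
   by simulating within-genus relationships, many times, to propagate the
   uncertainty.
2. **Alpha diversity.** Faith's PD, MPD and MNTD per site, standardized
   against a null model that randomizes the community matrix while holding
   site richness and species occupancy fixed.
3. **Beta diversity.** PhyloSor total dissimilarity partitioned into
   turnover and nestedness, at three resolutions (all sites jointly,
   adjacent pairs toward the summit, all pairs).
4. **Inference.** BIC comparison of candidate climate regressions for the
   SES values, and a generalized dissimilarity model (GDM) asking whether
   climate distance or geographic distance better predicts pairwise
   phylogenetic dissimilarity.
5. **Synthetic data.** A seeded generator producing complete, mutually
   consistent inputs under known assembly rules, so every stage is testable
   and the whole pipeline runs with no external downloads.

## Resolving the backbone: Yule grafting

Each backbone tip is a genus carrying `n` species. For `n = 1` the tip is
renamed; for `n >= 2` it is replaced by a random pure-birth (Yule) crown
group. Topology and relative node heights come from the Yule process
(waiting time to the next split with `k` lineages is exponential with rate
`k`; the rate cancels when heights are rescaled), so only the crown depth
must be chosen. The literature this package follows does not pin that depth
down, so it is an explicit parameter: `crown_fraction` (default 0.5) of the
genus terminal branch. The grafted subtree keeps the genus stem identity,
and the output is ultrametric with the backbone's total depth — two
invariants the test suite checks for every seed. A consequence worth knowing
is that patristic distances *between* genera are exactly the backbone
distances; only within-genus distances vary across the sample.

The maximum clade credibility (MCC) tree summarizes a sample: each tree is
scored by the sum over its non-trivial clades of the log of that clade's
sample frequency, and the best-scoring *member of the sample* is returned
(ties broken by lowest index). This is selection, not consensus: the MCC
tree is always a tree that was actually sampled.

## Alpha diversity and the independent-swap null

Faith's PD here includes the path to the root (the total branch length
joining the basal node to the community's tips); MPD and MNTD are
presence-based means over the patristic matrix. Sites with fewer than two
species have no pairwise structure, so MPD/MNTD are reported missing and
downstream regressions drop those rows.

The null model is the independent swap: repeated 2x2 checkerboard exchanges
(`[[1,0],[0,1]] <-> [[0,1],[1,0]]`) that preserve row and column sums
exactly. "Iterations" are counted as *successful* swaps, and each null
matrix is an independent chain started from the observed matrix (defaults:
1000 swaps per null matrix, 1000 null matrices, both configurable). The
kernel is compiled, draws from R's RNG stream, and is verified bitwise
against a pure-R reference under the same seed. Because the randomization
does not involve the tree, the package generates the null matrices once per
run and evaluates them on every tree of the sample; this is statistically
equivalent to fresh chains per tree and substantially faster, at the cost of
sharing Monte Carlo noise across trees (irrelevant once SES values are
summarized per tree and site).

`ses = (observed - mean(null)) / sd(null)` with the sample SD, and the
conventional two-sided `|ses| > 1.96` significance rule. On data *generated*
by the null model the SES distribution should be approximately standard
normal; the acceptance suite measures this over 500+ site-replicates
(empirical mean within 0.15 of zero, SD within [0.8, 1.2] at 199 nulls).

## PhyloSor and its partition

For two communities, branches of the union spanning subtree are classified
as shared (`a`) or exclusive (`b`, `c`) by whether they lie on root paths of
tips from both communities or one. The same root-path convention as PD is
used throughout, which buys the exact consistency `a + b = PD_1` and
`a + c = PD_2`. The Sorensen-family partition is then

* total: `sor = (b + c) / (2a + b + c)`
* turnover: `sim = min(b, c) / (a + min(b, c))`
* nestedness-resultant: `sne = sor - sim`,

with `sor = sim + sne` holding exactly (asserted to 1e-12). On a star tree
with unit branches the branch quantities collapse to set cardinalities and
the decomposition reduces to the classic species-level Sorensen/Simpson
measures — a degenerate case the tests exploit as an oracle. The
multiple-site version uses the pooled-PD core `sum_i S_i - S_T` and sums of
pairwise minima/maxima of exclusive branch lengths; with two sites it
reduces exactly to the pairwise formula. `beta_ratio = sim / sor` flags
turnover dominance (> 0.5) per pair, computed per tree and then summarized,
matching the per-tree reporting convention of the violin-plot figures this
pipeline emulates.

## Climate predictors

Inputs are already-extracted point tables (site, lon/lat, 19 bioclim-style
variables) — raster handling is deliberately out of scope, and the pixel
grid (origin + resolution, default 3 arc-second) is declared in
configuration so deduplication is reproducible without rasters. Points are
deduplicated to one per pixel, averaged per site, and each variable subset
(temperature-related bio1–bio11, precipitation-related bio12–bio19 by
default) is reduced to its first principal component after z-scoring. The
PC1 sign is fixed so that scores correlate positively with the subset mean —
warm lowland sites score high on the temperature axis regardless of
eigenvector sign conventions. Whether the PCA should run on site means or on
points (averaging scores afterwards) is genuinely ambiguous in the study
design this follows; site means are the default and the alternative sits
behind `pca_on = "points"`. Elevation–PC1 correlations are emitted in both
Pearson and Spearman forms, since the source report does not say which was
used. Geographic distance is great-circle (haversine) on a 6371-km sphere.

## Candidate regressions and BIC

Per tree and alpha metric, three specifications are fit by OLS: intercept
only, `temperature + precipitation`, and the full model with interaction.
BIC is the Gaussian-likelihood form `n ln(RSS/n) + k ln(n)` with `k`
counting coefficients plus the error variance — only differences matter, and
`delta-BIC < 2` marks equally probable models. Residuals are screened by
Shapiro–Wilk at 0.05, and a tree's fit enters the across-tree aggregate for
a given specification only if that fit passed the screen; the retained count
is reported alongside the means. The MCC tree's values are reported
separately, never averaged in.

## The generalized dissimilarity model

The GDM is authored in full here: `d_ij = 1 - exp(-eta_ij)` with

`eta_ij = b0 + sum_p sum_k a_pk |I_pk(x_pi) - I_pk(x_pj)|`, `a >= 0`,

where the `I_pk` are order-2 I-splines (integrated M-splines), three per
predictor with knots at the 0/50/100 percentiles of the observed values.
Each basis function is 0 at the range minimum and 1 at the maximum —
verified against direct numeric integration of the M-spline recursion — so
the fitted per-predictor transforms are monotone from zero. Geography
enters as the great-circle distance between site pairs passed through its
own splines. Fitting is iteratively reweighted least squares for the
negative-exponential link with a nonnegativity-constrained inner solve
(Lawson–Hanson NNLS), the binomial-type deviance with fitted values clamped
to `[1e-9, 1 - 1e-9]`, convergence when the deviance change drops below
1e-8 (100 iterations maximum, non-convergence flagged, with a damped
half-step fallback when a full IRLS step would increase the deviance).

Permutation importance permutes a predictor's *site-level* values
(coordinates jointly for geography), rebuilds the pair table, refits, and
records the percent change in deviance explained; full-model significance
permutes all predictors and reports the proportion of permutations whose
deviance explained reaches the observed one. Across a tree sample the
p-value ratio is the fraction of trees with p < 0.05. Note that a monotone
model can legitimately explain ~0% of a response that is not monotone in
any predictor difference — the turnover component of noisy gradients often
behaves this way, and the all-alpha-zero (intercept-only) fit is the honest
optimum there, not a failure.

## The synthetic generator

The generator emulates the target study design: 7 sites at 0–3000 m, 150
species in 50 genera, 20 climate points per site placed along a slope with
uneven adjacent distances. Defaults:

* backbone: pure-birth, conditioned on 50 tips, rescaled to 120 My crown
  age (the order of crown ages inferred for major ant radiations);
* thermal optima: Brownian motion, rate 0.4 degC^2/My from a root optimum
  of 17 degC — tip optima then span roughly the 8–25 degC range the lapse
  rate (5.5 degC/km from 25 degC at sea level) produces across sites;
* precipitation: Gaussian hump peaking at 1500 m (plus a seasonality term),
  so temperature is monotone in elevation while precipitation is not;
* richness targets decline 45 to 8 from base to summit;
* assembly: `filtering` admits species with probability
  `exp(-(opt - T_site)^2 / (2 tau^2))`, `tau = 2` degC, then tops
  up/thins to the target by probability-weighted sampling (so the
  `tau -> Inf` limit is exactly neutral); `competition` admits candidates in
  random order only if their patristic distance to every resident exceeds
  `delta`; `neutral` draws uniformly.

`delta` defaults to 60 My. The radius has to clear the close-relative tail
of the patristic distribution (5th percentile ~42 My under the default
tree) before the rule excludes near relatives decisively; at 60 My the
competition scenario produces clearly overdispersed communities
(mean SES.MPD around +0.9) while richness targets remain largely
attainable — smaller radii (e.g. 25 My) only shave the congeneric tail and
leave the scenario nearly indistinguishable from neutral. Where a site
cannot reach its richness target under the distance constraint the
shortfall is logged, not fatal.

Only temperature drives assembly; precipitation shapes the climate tables
but not community membership. That asymmetry is deliberate: it gives the
GDM recovery tests an unambiguous ground truth (temperature should carry
the importance) while keeping the predictor table realistic.

What the generator does *not* emulate: abundances and sampling effort,
spatially explicit dispersal, within-site heterogeneity, non-climatic
filters, and real bioclim covariance structure. Passing recovery tests
therefore demonstrate that the estimators detect the encoded processes
under niche conservatism — not that field data of this kind will separate
processes equally cleanly.

## Numerical choices and degenerate inputs

* All stochastic operations require an explicit seed; replicate seeds are
  `base + i` folded into the 32-bit range, and identical configurations
  reproduce outputs byte for byte.
* Ultrametricity is checked to 1e-8 relative tolerance; additivity of the
  beta partition to 1e-12.
* A community matrix with no checkerboard is returned unchanged from the
  swap with a warning; a degenerate null distribution (zero SD) is an
  error, not an NA.
* Quantile ties in spline knots are nudged apart by 1e-8 of the range;
  constant predictors are an error for splines and a warned drop for PCA.
* MCC ties break to the lowest tree index; BIC ties break to input order.
  Both are documented, deterministic choices.

## Problem sizes

The study-scale defaults (1000 trees, 1000 nulls, 1000 permutations) are
what the `run_config()` defaults encode. The bundled analysis scripts and
the acceptance script run the same pipeline at desk scale — 25 trees, 199
nulls, 49 GDM permutations per tree, 10–50 seeds per recovery experiment —
sizes chosen so the full workflow completes in a few minutes on one core
while keeping Monte Carlo error well below the effects being measured (the
across-tree SDs of the multisite decomposition are ~0.002 even at 25
trees). All sizes are plain arguments; nothing in the code depends on the
desk-scale values.

## Known limitations

* The within-genus crown depth is a modelling convention, not an estimate;
  conclusions that depend on within-genus branch lengths inherit it.
* SES values share null matrices across trees (see above).
* The GDM importance of correlated predictors (temperature and geography
  are nearly collinear along a transect) divides credit in a way that
  depends on the permutation scheme; the recovery tests show temperature
  wins when it is the true driver, but small geographic importances should
  not be over-interpreted.
* Real-data headline numbers (multisite decomposition of the archived ant
  dataset, summit richness, single-elevation percentage, the 2500-m
  significance pattern) are reproduced by the acceptance tests only when
  the archived dataset is placed under `data-raw/zenodo/`; the package does
  not download it.
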