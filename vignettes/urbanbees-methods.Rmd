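---
title: "Methods: urbanization gradients and wild bee communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urbanization gradients and wild bee communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanbees)
```

## The scientific problem

Multi-survey syntheses of wild bee inventories ask three linked questions
along an urbanization gradient:

1. **α diversity** — does local species richness decline as soil sealing
   (percent impervious surface within 500 m) or human population density
   (inhabitants/km² within 500 m) increases?
2. **β diversity** — do heavily urbanized communities become more similar
   to one another (taxonomic homogenization)?
3. **Trait filtering** — are the species that persist in cities a
   non-random, trait-structured subset of the regional pool?

Such syntheses pool surveys with heterogeneous protocols, so the pipeline
has to deal with three nuisances before any inference: spatial
pseudo-replication of nearby points, unequal sampling effort, and
imperfect detection. This vignette documents how each stage works, the
tunable parameters that matter, and the choices made where the design was
genuinely open.

## Site aggregation (500 m rule)

Wild bee flight distances are mostly below 500 m, so two sampling points
closer than that effectively sample one community. `aggregate_sites()`
applies complete-linkage hierarchical clustering to the Euclidean
inter-site distances and cuts the tree at `cutoff_m` (default 500 m),
which guarantees the *maximum* pairwise distance inside a group is at most
the cutoff — single-linkage would allow chains far wider than 500 m.
Groups get barycenter coordinates; effort variables are collated (days and
hours summed, the kick-net flag OR-ed); urbanization metrics are averaged
(unweighted, matching the barycenter logic — the sources are silent on
this); the region is a majority vote with ties broken by the first member,
defensible because conflicts can only occur across a < 500 m span.
Coordinates are assumed planar in meters (e.g. a national grid such as
Lambert-93); the 500 m rule is metric, so geographic coordinates must be
projected before loading.

## Sampling-scheme categories

Effort cannot be equalized across surveys, so sites are classified into
broad sampling-scheme categories used later as a random grouping factor.
Three variables describe a site's scheme: active sampling days, passive
trap hours, and a kick-net flag. `assign_sampling_categories()` z-scores
them, runs k-means (`k_kmeans`, default 3; best of 25 seeded restarts) and
complete-linkage clustering (`k_hier`, default 4), and cross-tabulates the
two labelings. Every non-empty cell of the cross-table is a candidate
category; candidates below `min_category_size` (default 5) are merged into
the candidate with the nearest standardized-effort centroid. This
consensus rule is this package's concrete reading of "combine both
clustering methods" — the original procedure behind the published five
categories is not specified, so the category count here is data-dependent,
a default expectation rather than an assertion. When a `k` is not
supplied it is chosen in 2..8 by maximum mean silhouette width, computed
in-package so the criterion is self-contained and deterministic. Sites are
internally sorted in standardized effort space before clustering, making
the partition invariant to input row order (restart-based k-means is
otherwise order-sensitive).

## Coverage screening

`sample_coverage()` uses the abundance-based closed forms: coverage
\(\hat C = 1 - (f_1/n)\,[(n-1)f_1/((n-1)f_1+2f_2)]\) and Chao1 asymptotic
richness. The percent-of-expected-richness screen (observed / Chao1) uses
these closed forms rather than full rarefaction–extrapolation curves,
because only the summary percentage feeds the workflow. Whether the
emulated surveys' "62% of expected richness" figure uses
observed/asymptotic richness or coverage at a standardized size is
ambiguous; this package fixes the former and documents it here.

## α diversity: zero-truncated NB regression

Richness is an overdispersed count that is never zero by design (no null
communities), hence a zero-truncated negative binomial with log link:

\[
P(Y=y \mid Y>0) = \frac{\mathrm{NB}(y;\mu,\theta)}{1-(\theta/(\theta+\mu))^{\theta}},
\qquad \log\mu = X\beta + u_{cat} + s.
\]

`fit_richness_model()` integrates the Gaussian category intercept
\(u_{cat}\) and the optional spatial effect \(s\) (exponential correlation
\(\exp(-d/\rho)\), i.e. Matérn smoothness 1/2) by Laplace approximation at
the joint random-effect mode (Newton inner loop with step halving;
convergence when successive log-likelihoods move < 1e−6). \(\beta\),
\(\log\theta\) and the log standard deviations are optimized in the outer
problem; \(\rho\) is profiled over a log-spaced grid of the observed
distance span rather than jointly optimized — more robust at desk scale.
Standard errors come from the numerical Hessian at the optimum with
variance parameters held fixed (the usual mixed-model convention).

Predictor scaling is a documented package choice (sources do not state
theirs): population density enters as `log1p` then z-score, impervious
percent as z-score, which puts both coefficients on comparable ~0.1
magnitudes. Both metrics enter one joint model; inference is by
likelihood-ratio tests dropping one term at a time (`lrt()`, χ² clipped at
zero). Residual spatial structure of non-spatial fits is diagnosed with
`morans_i()`; the weight default (inverse distance on a 10-nearest-neighbor
support, row-standardized) is a package choice since only the test, not
the weights, is conventionally reported.

Degenerate cases are explicit: any zero richness is a precondition error,
a dispersion parameter driven to the boundary (|log θ| > 10) is recorded
as a warning, and non-convergence flags the result rather than failing
silently.

## β diversity: gradient-binned homogenization test

`pairwise_beta()` computes presence/absence Sorensen dissimilarity
\((b+c)/(2a+b+c)\) for all site pairs (empty communities are an error —
the index is undefined for them). `bin_gradient()` splits the gradient
into half-open intervals \([kw,(k+1)w)\) anchored at 0 — defaults 0.2
log-units for `log1p` density and 2 percentage points for impervious
surface — with the global maximum closed into the last interval, so a
0–100 axis with width 2 yields exactly 50 intervals. (The emulated
surveys report 51–53 intervals for these axes, more than any single
standard convention produces; their exact break construction is unknown,
so interval counts are deliberately not an acceptance surface.) Levels
with fewer
than two sites cannot contribute a pairwise mean and are excluded.

`homogenization_trend()` regresses the within-level mean dissimilarity on
the interval *midpoint* (not the level index — midpoints make slopes
unit-interpretable) by unweighted OLS with Gaussian errors, reporting the
slope, a Shapiro–Wilk residual-normality diagnostic, and a confounder
screen: Pearson tests of midpoint against the per-level site count and
mean within-level geographic distance. The screen is reported, never used
to adjust the trend. A pair-count-weighted variant exists behind
`weighted = TRUE`, off by default.

## Trait filtering: pool-wide occurrence GLMM

`expand_occurrence()` assigns every species of the filtered global pool
(honeybee and parasitic species removed — the former tracks beekeeping,
the latter track their hosts) a 0/1 record at every site, so absences of
pool members are data. `fit_trait_glmm()` then fits a binomial logit
mixed model: one urbanization metric, four trait factors (nesting,
sociality, diet, size; treatment coding with references *below*, *social*,
*generalist*, *small* — the profile of the most abundant species in the
emulated surveys), all trait×metric interactions, region, with random
intercepts for site nested in sampling category plus a crossed species
intercept. A significant interaction means the urbanization response
differs between modalities — the ecological-filter signature.

The fit is delegated to `lme4::glmer` (Laplace family; crossed random
effects make quadrature infeasible). The default `nAGQ = 0` evaluates
fixed effects at the penalized-likelihood joint optimum: on a
400-site × 120-species table it is ~19× faster than `nAGQ = 1` and its
estimates and standard errors are indistinguishable at the accuracy the
recovery suite demands; `nAGQ = 1` remains available. Missing trait
values form an explicit third `no_information` modality so no species is
dropped; those coefficients are estimated but excluded from the BH family
and the prediction figures. The BH false-discovery-rate family is the 8
informative trait tests (4 main effects + 4 interactions) per model,
mirroring the two-fits-per-metric reporting scheme; the metric main effect
and the region LRT are outside the family (configurable via
`fdr_family = "all"`). Whether the density covariate should be
log-transformed in this model is unstated in the sources; the package
applies the same `log1p` + z-score convention as the richness model for
consistency.

`trait_occurrence_curves()` returns fixed-effect predictions (random
effects at zero) for the reference profile and each single-modality
switch, with delta-method bands.

## The synthetic world

`scenario_config()` fixes the generator's stated world; these values are
chosen once, not tuned:

* **Sites** (`generate_sites`): uniform on a 50 km square; a latent
  urbanization field from a coarse 8×8 Gaussian grid, bilinearly
  interpolated plus a nugget — enough qualitative spatial autocorrelation
  to exercise Moran's I and the spatial random effect without exact GP
  simulation. Impervious surface is a logistic transform of the field
  (0–100%, U-shaped like real soil-sealing distributions); density is
  log-linear in a correlated copy, clipped to the observed 0–10.2 `log1p`
  range (max ≈ 27,000/km²), with the latent correlation nudged by a
  bounded retry loop until the *sample* r between impervious and `log1p`
  density is within 0.1 of the 0.62 target.
* **Pool** (`generate_pool`): independent trait draws; modality and
  missingness frequencies follow the emulated surveys where stated
  (missing: size 18%, diet 7%, nesting 6.6%, sociality 6%; parasitic
  fraction 111/580) and field-realistic judgment otherwise (below-ground
  nesters ≈ 65%, solitary ≈ 75%, generalists ≈ 65%, small ≈ 45% — wild
  bee faunas of temperate Europe are dominated by below-ground-nesting,
  solitary, polylectic halictids and andrenids).
* **Communities** (`generate_communities`): the trait GLMM run forwards —
  occurrence logit = intercept (−2, giving realistic per-site occupancy
  ≈ 10–15% of the pool) + metric main effect + trait effects + Gaussian
  site/category/species/spatial effects; conditional abundance is
  zero-truncated NB with mean scaled by an effort composite.
  `no_information` species sit halfway between the two modalities on each
  trait axis. Empty sites are redrawn up to 100 times, then error.
* **Presets**: `filter_paper_like` (400 sites × 120 species, nesting
  interaction +0.31, other interactions 0, main effects at the anchor
  magnitudes 0.02/−0.96/−0.54/−0.17, metric −0.2), `null` (all effects
  except the intercept 0, no spatial variance), `tiny` (12 × 15, for
  examples). The recovery presets set the parasitic fraction to 0 so the
  analyzed post-filter pool is exactly 120 species.

What a green test establishes — and what it does not: the generator
matches the fitted models' own functional form (a conjugate pair), so
recovery tests validate the estimation machinery, not the models'
adequacy for real communities. Real data add phenology, detection
covariances, spatially structured trait syndromes and taxonomic error,
none of which are simulated.

## Numerical choices

* ZTNB inner Newton uses observed information obtained by central finite
  differences of the analytic score (floored at 1e−8) — robust where the
  truncation term makes the analytic Hessian delicate.
* LRT χ² is clipped at 0; identical fits give p = 1.
* BH adjustment follows the classic step-up formula. It is *not*
  idempotent on its own output (the min over tail ratios re-scales ties),
  so the tests assert exact agreement with `stats::p.adjust`, weak order
  preservation and `adj ≥ raw` instead.
* Coverage edge cases: no singletons ⇒ \(\hat C = 1\); a single specimen
  ⇒ \(\hat C = 0\); `f2 = 0` switches Chao1 to its bias-corrected form.
* `bin_gradient` with an all-zero axis returns a single level; a maximum
  that is an exact multiple of the width closes into the preceding
  interval rather than opening a degenerate one.
* All generator randomness flows through one seed, with per-operation
  substreams derived deterministically (`seed * 7919 + op * 104729` mod
  2³¹−1), so every artifact is byte-reproducible.

## Known limitations

* The spatial range ρ is profiled on a grid, not estimated with
  uncertainty; spatial fits scale as O(n³) per evaluation and are
  intended for a few hundred sites.
* No turnover/nestedness partition of β diversity and no
  abundance-weighted indices; homogenization is tested on Sorensen means
  only.
* The consensus categorization reproduces the *spirit* of combining two
  clusterings; the original five-category construction is unrecoverable
  from its description.
* Trait GLMM p-values are Wald (plus one LRT for region); no parametric
  bootstrap.
* GIS extraction of land cover and population rasters is out of scope:
  urbanization metrics are inputs.
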