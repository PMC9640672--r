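# urbanbees

Analysis pipeline for the effects of urbanization on wild bee
communities. Given multi-survey specimen records, site metadata with two
urbanization metrics (percent impervious surface and human population
density, both within a 500 m radius) and a species trait table, the
package answers three questions:

1. **α diversity** — does local species richness change along the
   urbanization gradient? Modeled with a zero-truncated negative binomial
   regression (richness is never 0 by design), a random intercept per
   sampling-scheme category, an optional spatial random effect with
   exponential correlation, and likelihood-ratio tests per predictor.
2. **β diversity** — do urban communities homogenize taxonomically? Mean
   pairwise Sorensen dissimilarity `(b + c) / (2a + b + c)` within
   gradient intervals (0.2 log-units of density, 2 points of impervious
   surface), regressed on the interval midpoint by OLS.
3. **Trait filtering** — is urban occurrence trait-structured? Every
   species of the global pool gets a presence/absence record at every
   site, and a binomial GLMM with trait × metric interactions (random
   intercepts: site nested in sampling category, crossed species) tests
   whether responses differ between trait modalities (nesting above/below
   ground, sociality, diet breadth, body size at the 2 mm inter-tegular
   cut), with Benjamini–Hochberg adjustment over the 8 informative trait
   tests.

Supporting stages: complete-linkage aggregation of sites closer than
500 m (barycenter coordinates, collated effort), consensus clustering of
sampling-effort metadata into sampling-scheme categories, Chao1-based
sample-coverage screening, Moran's I residual diagnostics, and a
synthetic community generator with known ecological-filter structure so
the whole chain is testable without access to raw survey data (which, for
the surveys this emulates, is available only on request).

For the models, their assumptions and every tunable default, see the
methods vignette: `vignettes/urbanbees-methods.Rmd`.

## Worked example

A survey-calibrated synthetic scenario: 400 sites, a 120-species pool, a
nesting × urbanization interaction of +0.31 and all other interactions 0.

```r
library(urbanbees)

dir <- tempfile()
make_fixture("filter_paper_like", dir, seed = 42)
d <- load_dataset(file.path(dir, "records.csv"), file.path(dir, "sites.csv"),
                  file.path(dir, "traits.csv"))
rec <- filter_taxa(d$records, d$traits)       # drop honeybee + parasitics
agg <- aggregate_sites(d$sites, rec, cutoff_m = 500)
agg$sites$sampling_category <- assign_sampling_categories(agg$sites)
ct <- build_community_table(agg$records, agg$sites)
ct
#> community_table: 375 sites x 120 species; 10213 specimens, 3925 occurrences
```

400 raw sites collapse to 375 groups (≤ 500 m complete linkage) in 5
sampling categories. Coverage screening and the metric collinearity
check:

```r
cov <- coverage_table(ct)
mean(cov$C_hat)                      # 0.82  (mean sample coverage)
mean(cov$pct_of_expected)            # 77.3  (% of Chao1-expected richness)
check_collinearity(log1p(agg$sites$pop_density), agg$sites$impervious_pct)
#> $r 0.621  $VIF 1.628
```

The richness model with per-term likelihood-ratio tests:

```r
s <- agg$sites[match(ct$site_ids, agg$sites$site_id), ]
fit_richness_model(s, richness(ct), spatial = FALSE, lrt_terms = TRUE)
#>             term  chi2 df        p
#> 1    pop_density  2.53  1 1.12e-01
#> 2 impervious_pct 37.74  1 8.09e-10
#> 3         region  3.30  3 3.48e-01
```

(In this preset the impervious effect on richness is *positive*: the
+0.31 nesting interaction raises above-ground-nester occupancy faster
than the −0.2 occurrence main effect lowers the rest, so net richness
rises along the gradient — an emergent property of the generating model,
not an error.)

The homogenization test and the trait-filter GLMM:

```r
bm <- pairwise_beta(ct)
b <- bin_gradient(s$pop_density, width = 0.2, transform = "log1p")
homogenization_trend(summarize_levels(b, bm, cbind(s$x, s$y)))
#> Homogenization trend over 40 urbanization levels
#>   slope = -0.01149 +/- 0.003601 (t = -3.19, p = 0.00284)

occ <- expand_occurrence(ct, d$traits, agg$sites)
fit <- fit_trait_glmm(occ, "impervious_pct")
subset(fit$coefficients, in_fdr_family, c(term, estimate, se, p_adj))
#>                          term estimate     se    p_adj
#> 14      metric_z:nestingabove  0.28952 0.0413 1.99e-11
#> 16 metric_z:socialitysolitary -0.01769 0.0427 7.76e-01
#> 18    metric_z:dietspecialist -0.02443 0.0452 7.76e-01
#> 20         metric_z:sizelarge -0.00654 0.0459 8.87e-01
```

The fitted nesting interaction (0.290 ± 0.041) recovers the generating
+0.31 and survives FDR adjustment; the three null interactions do not —
the ecological-filter signature, detected where and only where it was
simulated. `trait_occurrence_curves(fit)` returns the per-modality
predicted occurrence curves with delta-method bands.

## Command line

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/urbanbees simulate --scenario tiny --seed 4 --out demo/
Rscript inst/cli/urbanbees validate --records demo/records.csv \
    --sites demo/sites.csv --traits demo/traits.csv
Rscript inst/cli/urbanbees traits --records demo/records.csv \
    --sites demo/sites.csv --traits demo/traits.csv --out out/
```

Subcommands: `validate`, `aggregate`, `categorize`, `diversity`, `alpha`,
`beta`, `traits`, `simulate`; `--config` accepts a YAML file (keys such as
`cutoff_m`, `k_kmeans`, `k_hier`, `min_category_size`, `seed`, widths per
metric).

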