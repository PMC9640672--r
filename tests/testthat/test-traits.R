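make_occurrence_fixture <- function(n_sites = 30, n_sp = 12, seed = 1) {
  set.seed(seed)
  sites <- make_sites_df(cbind(runif(n_sites, 0, 5e4), runif(n_sites, 0, 5e4)),
                         pop_density = rlnorm(n_sites, 5, 2),
                         impervious = runif(n_sites, 0, 100),
                         region = sample(c("Continental", "Atlantic"),
                                         n_sites, TRUE))
  sites$sampling_category <- sample(1:3, n_sites, TRUE)
  traits <- make_traits_df(
    sprintf("Species %02d", 1:n_sp),
    nesting = sample(c("below", "above", "no_information"), n_sp, TRUE),
    sociality = sample(c("social", "solitary"), n_sp, TRUE),
    diet = sample(c("generalist", "specialist"), n_sp, TRUE),
    size = sample(c("small", "large"), n_sp, TRUE))
  recs <- expand.grid(site_id = sites$site_id, species = traits$species,
                      stringsAsFactors = FALSE)
  recs <- recs[runif(nrow(recs)) < 0.3, ]
  recs$count <- sample(1:4, nrow(recs), TRUE)
  ct <- build_community_table(recs, sites)
  list(sites = sites, traits = traits, ct = ct)
}

test_that("expand_occurrence builds the full pool-by-site cross", {
  sites <- make_sites_df(cbind(c(0, 1000), 0))
  sites$sampling_category <- c(1, 2)
  traits <- make_traits_df(c("Sp one", "Sp two", "Sp three"))
  rec <- make_records_df(c("s1", "s2", "s2", "s2"),
                         c("Sp one", "Sp one", "Sp two", "Sp three"),
                         c(2, 1, 1, 1))
  ct <- build_community_table(rec, sites)
  occ <- expand_occurrence(ct, traits, sites)
  expect_equal(nrow(occ), 6)  # 2 sites x 3-species pool
  # site-major documented order, species lexicographic within site
  expect_equal(occ$site_id, rep(c("s1", "s2"), each = 3))
  expect_equal(occ$species[1:3], sort(traits$species))
  expect_equal(occ$occurrence,
               c(1, 0, 0, 1, 1, 1))
  # occurrence conservation
  expect_equal(sum(occ$occurrence), sum(ct$incidence))

  # species with no trait row: retained, all modalities no_information
  traits2 <- traits[-2, ]
  occ2 <- expand_occurrence(ct, traits2, sites)
  missing_rows <- occ2[occ2$species == "Sp two", ]
  expect_true(all(missing_rows$nesting == "no_information"))
  expect_equal(nrow(occ2), 6)
})

test_that("expand_occurrence row count is pool x sites on generated data", {
  fx <- make_occurrence_fixture(seed = 23)
  occ <- expand_occurrence(fx$ct, fx$traits, fx$sites)
  expect_equal(nrow(occ), length(fx$ct$species) * length(fx$ct$site_ids))
  expect_equal(sum(occ$occurrence), sum(fx$ct$incidence))
})

test_that("fdr_adjust implements BH step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))      # independent oracle
    expect_true(all(adj >= p - 1e-15))        # adjusted >= raw
    # weak monotonicity: p_i <= p_j implies adj_i <= adj_j (the step-up min
    # introduces ties, so the strict order is not preserved)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("trait GLMM with null random structure matches ordinary logistic IRLS", {
  set.seed(31)
  fx <- make_occurrence_fixture(n_sites = 40, n_sp = 10, seed = 31)
  occ <- expand_occurrence(fx$ct, fx$traits, fx$sites)
  # occurrence regenerated from fixed effects only: no grouping structure,
  # so the GLMM variances collapse to the boundary and fixed effects must
  # agree with plain logistic regression
  z <- urbanbees:::standardize_metric(occ$impervious_pct, "impervious_pct")
  eta <- -0.5 + 0.3 * z + 0.5 * (occ$nesting == "above") -
    0.4 * z * (occ$diet == "specialist")
  occ$occurrence <- rbinom(nrow(occ), 1, plogis(eta))
  fit <- suppressWarnings(
    fit_trait_glmm(occ, "impervious_pct", region_lrt = FALSE))
  occ$metric_z <- z
  glmfit <- glm(occurrence ~ metric_z * (nesting + sociality + diet + size) +
                  region, family = binomial(), data = occ)
  shared <- intersect(fit$coefficients$term, names(coef(glmfit)))
  expect_gt(length(shared), 8)
  expect_equal(
    fit$coefficients$estimate[match(shared, fit$coefficients$term)],
    unname(coef(glmfit)[shared]), tolerance = 1e-3)
  expect_true(all(fit$varcomp < 0.05))
})

test_that("trait GLMM recovers generating interaction signs (reduced suite)", {
  # smaller than the acceptance-scale suite: 3 seeds, all four interactions
  # set to the anchor magnitudes
  eff <- list(intercept = -2, metric = -0.2,
              traits = c(nesting = 0.02, sociality = -0.96, diet = -0.54,
                         size = -0.17),
              interactions = c(nesting = 0.31, sociality = -0.08,
                               diet = -0.09, size = -0.14))
  hits <- 0; total <- 0
  for (seed in 1:3) {
    cfg <- scenario_config(n_sites = 250, pool_size = 80,
                           fraction_parasitic = 0, seed = seed,
                           effects = eff)
    sites <- generate_sites(cfg)
    traits <- generate_pool(cfg)
    rec <- generate_communities(sites, traits, cfg)
    ct <- build_community_table(rec, sites)
    sites$sampling_category <- suppressWarnings(
      assign_sampling_categories(sites))
    occ <- expand_occurrence(ct, traits, sites)
    fit <- suppressWarnings(fit_trait_glmm(occ, "impervious_pct",
                                           region_lrt = FALSE))
    co <- fit$coefficients
    for (tr in names(eff$interactions)) {
      term <- paste0("metric_z:", tr, urbanbees:::trait_other[[tr]])
      est <- co$estimate[co$term == term]
      total <- total + 1
      hits <- hits + (sign(est) == sign(eff$interactions[[tr]]))
    }
  }
  expect_gte(hits / total, 0.75)  # 9/12 at this reduced scale
})

test_that("trait_occurrence_curves reflect the fixed-effect algebra", {
  fx <- make_occurrence_fixture(n_sites = 40, n_sp = 10, seed = 37)
  occ <- expand_occurrence(fx$ct, fx$traits, fx$sites)
  fit <- suppressWarnings(
    fit_trait_glmm(occ, "impervious_pct", region_lrt = FALSE))
  cur <- trait_occurrence_curves(fit, metric_grid = c(-1, 0, 1))
  beta <- lme4::fixef(fit$model)
  # at metric 0 the reference curve is inverse-logit of the intercept
  ref0 <- cur[cur$trait == "reference" & cur$metric_z == 0, ]
  expect_equal(ref0$prob, unname(plogis(beta["(Intercept)"])))
  # switching a modality shifts by its main effect at metric 0
  nest0 <- cur[cur$trait == "nesting" & cur$metric_z == 0, ]
  expect_equal(nest0$prob,
               unname(plogis(beta["(Intercept)"] + beta["nestingabove"])))
  # positive interaction: modality/reference probability ratio increases
  b2 <- beta
  b2["metric_z:nestingabove"] <- abs(b2["metric_z:nestingabove"]) + 0.2
  fit2 <- fit
  # monotonicity is a property of the logistic algebra; verify on curves
  eta_ref <- b2["(Intercept)"] + b2["metric_z"] * c(-1, 0, 1)
  eta_mod <- eta_ref + b2["nestingabove"] +
    b2["metric_z:nestingabove"] * c(-1, 0, 1)
  ratio <- plogis(eta_mod) / plogis(eta_ref)
  expect_true(all(diff(ratio) > 0))
  # bands contain the point estimate
  expect_true(all(cur$lower <= cur$prob & cur$prob <= cur$upper))
  expect_warning(trait_occurrence_curves(fit, metric_grid = c(0, 5)),
                 "extrapolation")
})
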