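test_that("load_dataset round-trips a toy fixture and rejects bad rows", {
  dir <- withr::local_tempdir()
  writeLines(c("site_id,species,count",
               "s1,Bombus pascuorum,3",
               "s1,Apis mellifera,2",
               "s2,Bombus pascuorum,1"),
             file.path(dir, "records.csv"))
  writeLines(c("site_id,x,y,pop_density,impervious_pct,region,active_days,passive_hours,kick_net",
               "s1,0,0,100,10,Continental,2,0,0",
               "s2,1000,0,5000,80,Continental,1,40,0"),
             file.path(dir, "sites.csv"))
  writeLines(c("species,nesting,sociality,diet,size,itd_mm,parasitic",
               "Bombus pascuorum,below,social,generalist,large,3.5,FALSE",
               "Apis mellifera,above,social,generalist,large,3.1,FALSE"),
             file.path(dir, "traits.csv"))
  d <- load_dataset(file.path(dir, "records.csv"), file.path(dir, "sites.csv"),
                    file.path(dir, "traits.csv"))
  expect_equal(nrow(d$records), 3)
  expect_equal(nrow(d$sites), 2)
  expect_equal(nrow(d$traits), 2)

  # bound violation names the invariant
  writeLines(c("site_id,x,y,pop_density,impervious_pct,region,active_days,passive_hours,kick_net",
               "s1,0,0,100,130,Continental,2,0,0"),
             file.path(dir, "bad_sites.csv"))
  expect_error(
    load_dataset(file.path(dir, "records.csv"), file.path(dir, "bad_sites.csv"),
                 file.path(dir, "traits.csv")),
    "impervious_pct outside \\[0, 100\\]")

  # referential error lists the orphan id
  writeLines(c("site_id,species,count", "ghost,Bombus pascuorum,1"),
             file.path(dir, "orphan.csv"))
  expect_error(
    load_dataset(file.path(dir, "orphan.csv"), file.path(dir, "sites.csv"),
                 file.path(dir, "traits.csv")),
    "ghost")

  # missing mandatory column
  writeLines(c("site_id,species", "s1,Bombus pascuorum"),
             file.path(dir, "nocount.csv"))
  expect_error(
    load_dataset(file.path(dir, "nocount.csv"), file.path(dir, "sites.csv"),
                 file.path(dir, "traits.csv")),
    "missing mandatory column")
})

test_that("species names are whitespace/case normalized; ITD consistency enforced", {
  rec <- make_records_df("s1", c("  bombus   pascuorum ", "Bombus pascuorum"),
                         c(1, 2))
  sites <- make_sites_df(cbind(0, 0))
  rec <- validate_records(rec, sites)
  expect_equal(unique(rec$species), "Bombus pascuorum")

  bad <- data.frame(species = "A b", nesting = "below", sociality = "social",
                    diet = "generalist", size = "small", itd_mm = 3,
                    parasitic = FALSE)
  expect_error(validate_traits(bad), "inconsistent with itd_mm")
})

test_that("filter_taxa applies the honeybee and parasitic rules", {
  rec <- make_records_df(rep("s1", 3),
                         c("Apis mellifera", "Bombus pascuorum", "Nomada flava"),
                         c(10, 5, 2))
  traits <- make_traits_df(c("Bombus pascuorum", "Nomada flava"),
                           parasitic = c(FALSE, TRUE))
  out <- filter_taxa(rec, traits, drop_honeybee = TRUE, drop_parasitic = FALSE)
  expect_setequal(out$species, c("Bombus pascuorum", "Nomada flava"))
  out <- filter_taxa(rec, traits, drop_honeybee = TRUE, drop_parasitic = TRUE)
  expect_equal(out$species, "Bombus pascuorum")
  expect_equal(unname(attr(out, "removed")), c(1L, 1L))

  # both flags off: identity
  out <- filter_taxa(rec, traits, FALSE, FALSE)
  expect_equal(out$species, rec$species)

  # idempotent and flag-order independent
  once <- filter_taxa(rec, traits)
  expect_equal(filter_taxa(once, traits)$species, once$species)
  ab <- suppressWarnings(
    filter_taxa(filter_taxa(rec, traits, TRUE, FALSE), traits, FALSE, TRUE))
  ba <- suppressWarnings(
    filter_taxa(filter_taxa(rec, traits, FALSE, TRUE), traits, TRUE, FALSE))
  expect_equal(ab$species, ba$species)

  # unknown species: warning, treated non-parasitic
  rec2 <- make_records_df("s1", "Mystery bee", 1)
  expect_warning(out2 <- filter_taxa(rec2, traits), "non-parasitic")
  expect_equal(nrow(out2), 1)

  # empty input flows through
  expect_equal(nrow(filter_taxa(rec[0, ], traits)), 0)
})

test_that("build_community_table sums counts and conserves specimens", {
  sites <- make_sites_df(cbind(c(0, 1000), c(0, 0)))
  rec <- make_records_df(c("s1", "s1", "s1", "s2", "s2"),
                         c("Sp a", "Sp a", "Sp b", "Sp b", "Sp c"),
                         c(2, 1, 4, 1, 1))
  ct <- build_community_table(rec, sites)
  expect_equal(ct$abundance["s1", "Sp a"], 3)
  expect_equal(ct$incidence["s1", "Sp c"], 0)
  expect_equal(sum(ct$incidence), 4)
  expect_equal(sum(ct$abundance), sum(rec$count))
  expect_identical(ct$incidence, (ct$abundance >= 1) * 1L)
  # 2 sites x 3 species with one absent pair: hand enumeration
  expect_equal(as.vector(ct$incidence),
               c(1, 0, 1, 1, 0, 1))  # column-major: Sp a(s1,s2), Sp b, Sp c
  expect_error(build_community_table(rec[0, ], sites), "no records")
})

test_that("write_results/read_results round-trip results and refuse overwrite", {
  dir <- withr::local_tempdir()
  fr <- structure(list(
    label = "toy", coefficients = data.frame(
      term = c("(Intercept)", "impervious_pct"), estimate = c(1.5, -0.09),
      se = c(0.1, 0.05), z = c(15, -1.8), p = c(1e-10, 0.07)),
    varcomp = list(theta = 2.3, sigma_cat = 0.4,
                   sigma_spatial = NA_real_, rho = NA_real_),
    loglik = -123.456, n = 50L, n_fixed = 2L, converged = TRUE,
    warnings = character(0)), class = "fit_result")
  p <- file.path(dir, "fit.csv")
  write_results(fr, p, seed = 42)
  back <- read_results(p)
  expect_s3_class(back, "fit_result")
  expect_equal(back$coefficients$estimate, fr$coefficients$estimate)
  expect_equal(back$loglik, fr$loglik)
  expect_equal(attr(back, "metadata")$seed, 42)
  expect_error(write_results(fr, p), "refusing to overwrite")
  expect_silent(write_results(fr, p, force = TRUE, seed = 42))

  # beta level summaries round-trip
  lv <- structure(lapply(1:3, function(i) {
    structure(list(level = i, lower = i * 2, upper = (i + 1) * 2,
                   midpoint = i * 2 + 1, n_sites = 4L, n_pairs = 6L,
                   mean_dissimilarity = 0.1 * i, mean_distance_m = 100 * i),
              class = "beta_level_summary")
  }), class = "beta_level_list")
  p2 <- file.path(dir, "levels.csv")
  write_results(lv, p2)
  back2 <- read_results(p2)
  expect_equal(as.data.frame(back2), as.data.frame(lv))
})
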