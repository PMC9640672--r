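trait_reference <- c(nesting = "below", diet = "generalist",
                     sociality = "social", size = "small")
trait_other <- c(nesting = "above", diet = "specialist",
                 sociality = "solitary", size = "large")

#' Expand a community table to global-pool occurrences
#'
#' Assigns every species of the global (non-parasitic, honeybee-free)
#' species pool a presence/absence record at every site: the ecological
#' filter test asks whether species found along the urbanization gradient
#' are a random draw from this pool, so absences of pool members are data.
#' Rows are ordered site-major (sites, then species, both lexicographic).
#'
#' @param community a `community_table` built from the filtered records.
#' @param traits validated trait table; species missing from it get all
#'   modalities `"no_information"`.
#' @param sites grouped site table with urbanization metrics, `region` and
#'   `sampling_category`.
#' @return a data frame with one row per (site, species) pair: `site_id`,
#'   `species`, `occurrence` (0/1), site covariates, and the four trait
#'   modality columns.
#' @export
expand_occurrence <- function(community, traits, sites) {
  site_ids <- community$site_ids
  pool <- community$species
  if (is.null(sites$sampling_category)) {
    stop("sites$sampling_category missing: run assign_sampling_categories()",
         call. = FALSE)
  }
  si <- match(site_ids, sites$site_id)
  if (anyNA(si)) stop("community sites absent from site table", call. = FALSE)

  grid <- expand.grid(species = pool, site_id = site_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("site_id", "species")]
  occ <- as.vector(t(community$incidence[site_ids, pool, drop = FALSE]))
  grid$occurrence <- occ

  ssel <- sites[match(grid$site_id, sites$site_id), ]
  grid$pop_density <- ssel$pop_density
  grid$impervious_pct <- ssel$impervious_pct
  grid$region <- ssel$region
  grid$sampling_category <- ssel$sampling_category

  ti <- match(grid$species, traits$species)
  for (tr in names(trait_reference)) {
    v <- traits[[tr]][ti]
    v[is.na(v)] <- "no_information"
    grid[[tr]] <- factor(v, levels = c(trait_reference[[tr]],
                                       trait_other[[tr]], "no_information"))
  }
  rownames(grid) <- NULL
  grid
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: sort the m p-values ascending, set
#' \eqn{p^{adj}_{(i)} = \min_{j \ge i} m\, p_{(j)} / j} capped at 1, and
#' restore the original order.
#'
#' @param p_values p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Fit the trait-by-urbanization occurrence GLMM
#'
#' Binomial (logit) mixed model for pool-wide occurrence: fixed effects
#' are one urbanization metric, the four trait factors (treatment coding;
#' reference modalities `below`, `generalist`, `social`, `small` — the
#' profile of the most abundant species), all trait-by-metric two-way
#' interactions, and biogeographical region; random intercepts are
#' sampling site nested in sampling-scheme category, plus a crossed
#' species intercept. Fitted by Laplace-type approximation via
#' [lme4::glmer()]. A significant trait-by-metric interaction means the
#' urbanization response differs between trait modalities — the signature
#' of an ecological filter.
#'
#' The metric is standardized as in [fit_richness_model()] (`pop_density`:
#' `log1p` then z-score; `impervious_pct`: z-score). Wald z p-values of
#' the 8 informative trait coefficients (4 main effects + 4 interactions,
#' `no_information` contrasts excluded) form the BH adjustment family;
#' region is tested by likelihood-ratio test. Complete separation of a
#' trait modality (all-0 or all-1 occurrence) is flagged with a warning.
#'
#' @param occurrence_table output of [expand_occurrence()].
#' @param metric `"pop_density"` or `"impervious_pct"`.
#' @param nAGQ passed to [lme4::glmer()]; the default 0 (random effects
#'   and fixed effects jointly at the penalized-likelihood optimum) is
#'   markedly faster on pool-expanded tables and accurate for this design;
#'   use 1 for full Laplace.
#' @param region_lrt test the region factor by LRT (one refit)? Default
#'   `TRUE`.
#' @param fdr_family which p-values form the BH family: `"traits"`
#'   (default, the 8 informative trait tests) or `"all"` (adds the metric
#'   main effect).
#' @return a `trait_fit_result` (also `fit_result`): coefficient table
#'   with raw and BH-adjusted p, variance components, log-likelihood,
#'   reference-modality map, the region LRT, and the fitted `merMod`.
#' @export
fit_trait_glmm <- function(occurrence_table, metric = c("impervious_pct",
                                                        "pop_density"),
                           nAGQ = 0, region_lrt = TRUE,
                           fdr_family = c("traits", "all")) {
  metric <- match.arg(metric)
  fdr_family <- match.arg(fdr_family)
  d <- occurrence_table
  d$metric_z <- standardize_metric(d[[metric]], metric)
  d$site_id <- factor(d$site_id)
  d$species <- factor(d$species)
  d$sampling_category <- factor(d$sampling_category)
  d$region <- factor(d$region)
  for (tr in names(trait_reference)) {
    sep <- tapply(d$occurrence, d[[tr]], mean)
    if (any(sep %in% c(0, 1))) {
      warning("complete separation for ", tr, " modality ",
              names(sep)[sep %in% c(0, 1)], call. = FALSE)
    }
  }

  fixed <- "occurrence ~ metric_z * (nesting + sociality + diet + size)"
  if (nlevels(d$region) > 1) fixed <- paste(fixed, "+ region")
  form <- stats::as.formula(paste(
    fixed, "+ (1 | sampling_category/site_id) + (1 | species)"))
  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  fit <- lme4::glmer(form, data = d, family = stats::binomial(),
                     nAGQ = nAGQ, control = ctrl)

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)

  info_terms <- c(
    paste0(names(trait_other), trait_other),
    paste0("metric_z:", names(trait_other), trait_other))
  fam <- coefs$term %in% info_terms
  if (fdr_family == "all") fam <- fam | coefs$term == "metric_z"
  coefs$in_fdr_family <- fam
  coefs$p_adj <- NA_real_
  coefs$p_adj[fam] <- fdr_adjust(coefs$p[fam])

  lrt_df <- NULL
  if (region_lrt && nlevels(d$region) > 1) {
    form0 <- stats::as.formula(paste(
      "occurrence ~ metric_z * (nesting + sociality + diet + size)",
      "+ (1 | sampling_category/site_id) + (1 | species)"))
    fit0 <- lme4::glmer(form0, data = d, family = stats::binomial(),
                        nAGQ = nAGQ, control = ctrl)
    chi2 <- max(0, 2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit0))))
    df <- nlevels(d$region) - 1
    lrt_df <- data.frame(term = "region", chi2 = chi2, df = df,
                         p = pchisq(chi2, df, lower.tail = FALSE))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- is.null(fit@optinfo$conv$lme4$messages)
  structure(list(
    label = paste("occurrence ~", metric, "x traits"),
    metric = metric,
    coefficients = coefs,
    reference_modalities = as.list(trait_reference),
    varcomp = setNames(vc$vcov, vc$grp),
    loglik = as.numeric(logLik(fit)),
    n = nrow(d), n_fixed = nrow(coefs),
    converged = conv, warnings = character(0),
    lrt = lrt_df,
    metric_center = attr(d$metric_z, "center"),
    metric_scale = attr(d$metric_z, "scale"),
    model = fit), class = c("trait_fit_result", "fit_result"))
}

standardize_metric <- function(x, metric) {
  v <- if (metric == "pop_density") log1p(x) else x
  z <- scale(v)
  structure(drop(z), center = attr(z, "scaled:center"),
            scale = attr(z, "scaled:scale"))
}

#' Predicted occurrence curves by trait modality
#'
#' Fixed-effect predictions (random effects at zero) of occurrence
#' probability over a grid of the standardized urbanization metric, for
#' the reference trait profile and for each single-modality switch away
#' from it, with delta-method confidence bands.
#'
#' @param fit a converged `trait_fit_result`.
#' @param metric_grid values of the standardized metric (default: 21
#'   points over \[-2, 2\]); values beyond that range trigger an
#'   extrapolation warning.
#' @param level confidence level for the bands (default 0.95).
#' @return a data frame with `trait` (`"reference"` or the switched
#'   trait), `modality`, `metric_z`, `prob`, `lower`, `upper`.
#' @export
trait_occurrence_curves <- function(fit, metric_grid = seq(-2, 2, 0.2),
                                    level = 0.95) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (any(abs(metric_grid) > 2.5)) {
    warning("metric grid extends beyond the fitted range (extrapolation)",
            call. = FALSE)
  }
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  zq <- qnorm(1 - (1 - level) / 2)
  curve_for <- function(trait, modality) {
    rows <- lapply(metric_grid, function(m) {
      x <- setNames(numeric(length(beta)), names(beta))
      x["(Intercept)"] <- 1
      x["metric_z"] <- m
      if (!is.null(trait)) {
        main <- paste0(trait, modality)
        x[main] <- 1
        x[paste0("metric_z:", main)] <- m
      }
      eta <- sum(x * beta)
      se <- sqrt(drop(t(x) %*% V %*% x))
      data.frame(
        trait = if (is.null(trait)) "reference" else trait,
        modality = if (is.null(trait)) "reference" else modality,
        metric_z = m, prob = plogis(eta),
        lower = plogis(eta - zq * se), upper = plogis(eta + zq * se))
    })
    do.call(rbind, rows)
  }
  out <- curve_for(NULL, NULL)
  for (tr in names(trait_other)) {
    out <- rbind(out, curve_for(tr, trait_other[[tr]]))
  }
  rownames(out) <- NULL
  out
}
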