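#' Bin sites along an urbanization gradient
#'
#' Assigns each site to a half-open interval \eqn{[kw, (k+1)w)} of width
#' `w` anchored at 0, on the (optionally `log1p`-transformed) urbanization
#' axis. The global maximum is assigned to the last interval (closed on
#' the right), so an axis spanning \[0, 100\] with width 2 yields 50
#' intervals. Default widths used for the two metrics are 0.2 log-units
#' (population density, after `log1p`) and 2 percentage points
#' (impervious surface).
#'
#' @param values non-negative metric values, one per site.
#' @param width interval width (> 0).
#' @param transform `"identity"` or `"log1p"`.
#' @return list with `level` (0-based interval index per site) and
#'   `intervals`, a data frame of all intervals in range (`level`,
#'   `lower`, `upper`, `midpoint`, `n_sites`; empty interior intervals are
#'   reported with `n_sites = 0`).
#' @export
bin_gradient <- function(values, width, transform = c("identity", "log1p")) {
  transform <- match.arg(transform)
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0", call. = FALSE)
  v <- if (transform == "log1p") log1p(values) else values
  vmax <- max(v)
  lev <- floor(v / width)
  if (vmax > 0) {
    last <- ceiling(vmax / width) - 1
    lev <- pmin(lev, last)
  } else {
    last <- 0
  }
  counts <- tabulate(lev + 1L, nbins = last + 1L)
  intervals <- data.frame(
    level = 0:last,
    lower = (0:last) * width,
    upper = (1:(last + 1)) * width,
    n_sites = counts)
  intervals$midpoint <- (intervals$lower + intervals$upper) / 2
  list(level = lev, intervals = intervals, width = width,
       transform = transform)
}

#' Mean pairwise dissimilarity per urbanization level
#'
#' For every gradient interval holding at least `min_sites` sites (default
#' 2; levels with fewer sites cannot contribute a pairwise mean and are
#' excluded), computes the mean over all unordered within-level site pairs
#' of (i) Sorensen dissimilarity and (ii) Euclidean geographic distance.
#'
#' @param binning result of [bin_gradient()].
#' @param beta_matrix pairwise dissimilarity matrix from [pairwise_beta()]
#'   covering all binned sites (same order).
#' @param coordinates two-column matrix of site coordinates (meters).
#' @param min_sites smallest level size retained (default 2).
#' @return a `beta_level_list`: one `beta_level_summary` per retained
#'   level with fields `level`, `lower`, `upper`, `midpoint`, `n_sites`,
#'   `n_pairs`, `mean_dissimilarity`, `mean_distance_m`. Excluded levels
#'   are recorded in attribute `"excluded"`.
#' @export
summarize_levels <- function(binning, beta_matrix, coordinates,
                             min_sites = 2) {
  lev <- binning$level
  if (nrow(beta_matrix) != length(lev)) {
    stop("beta matrix does not cover all binned sites", call. = FALSE)
  }
  dmat <- as.matrix(dist(coordinates))
  iv <- binning$intervals
  out <- list()
  excluded <- integer(0)
  for (r in seq_len(nrow(iv))) {
    l <- iv$level[r]
    idx <- which(lev == l)
    if (length(idx) < min_sites) {
      if (length(idx) > 0) excluded <- c(excluded, l)
      next
    }
    pairs <- utils::combn(idx, 2)
    bvals <- beta_matrix[cbind(pairs[1, ], pairs[2, ])]
    gvals <- dmat[cbind(pairs[1, ], pairs[2, ])]
    out[[length(out) + 1]] <- structure(list(
      level = l, lower = iv$lower[r], upper = iv$upper[r],
      midpoint = iv$midpoint[r], n_sites = length(idx),
      n_pairs = ncol(pairs),
      mean_dissimilarity = mean(bvals),
      mean_distance_m = mean(gvals)), class = "beta_level_summary")
  }
  if (!length(out)) stop("no gradient level retains >= ", min_sites, " sites",
                         call. = FALSE)
  structure(out, class = "beta_level_list", excluded = excluded)
}

#' @export
as.data.frame.beta_level_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
as.data.frame.beta_level_list <- function(x, ...) {
  do.call(rbind, lapply(x, as.data.frame))
}

#' Test the taxonomic homogenization hypothesis
#'
#' Under taxonomic homogenization, within-level mean beta-diversity should
#' steadily decrease as urbanization increases. The test is an ordinary
#' least squares regression of the mean within-interval Sorensen
#' dissimilarity on the interval midpoint, with Gaussian errors; the
#' slope, its standard error, t and p are reported along with a
#' Shapiro-Wilk residual-normality diagnostic and a confounder screen
#' (Pearson correlation tests of the midpoint against the number of sites
#' per level and against the mean within-level geographic distance). The
#' confounder correlations are reported, never used to adjust the trend.
#'
#' @param level_summaries a `beta_level_list` from [summarize_levels()]
#'   with at least 3 levels.
#' @param weighted weight levels by their pair counts? Off by default (the
#'   trend is fitted on level means, unweighted).
#' @return list of class `homogenization_trend` with `slope`, `se`, `t`,
#'   `p`, `intercept`, `n_levels`, `shapiro_p`, `confounders` (data frame)
#'   and the fitted `lm` object.
#' @export
homogenization_trend <- function(level_summaries, weighted = FALSE) {
  df <- as.data.frame(level_summaries)
  if (nrow(df) < 3) stop("need at least 3 retained levels", call. = FALSE)
  degenerate <- sd(df$mean_dissimilarity) == 0
  if (degenerate) {
    warning("degenerate fit: zero-variance level means", call. = FALSE)
  }
  fit <- if (weighted) {
    lm(mean_dissimilarity ~ midpoint, data = df, weights = df$n_pairs)
  } else {
    lm(mean_dissimilarity ~ midpoint, data = df)
  }
  sm <- summary(fit)$coefficients
  slope <- sm["midpoint", "Estimate"]
  se <- sm["midpoint", "Std. Error"]
  shapiro_p <- if (!degenerate && nrow(df) >= 3 && nrow(df) <= 5000) {
    tryCatch(shapiro.test(residuals(fit))$p.value, error = function(e) NA_real_)
  } else NA_real_
  conf <- do.call(rbind, lapply(
    c(n_sites = "n_sites", mean_distance_m = "mean_distance_m"),
    function(col) {
      ct <- tryCatch(cor.test(df$midpoint, df[[col]]), error = function(e) NULL)
      data.frame(variable = col,
                 r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p = if (is.null(ct)) NA_real_ else ct$p.value)
    }))
  rownames(conf) <- NULL
  structure(list(
    slope = if (degenerate) 0 else slope, se = se,
    t = sm["midpoint", "t value"], p = sm["midpoint", "Pr(>|t|)"],
    intercept = sm["(Intercept)", "Estimate"],
    n_levels = nrow(df), weighted = weighted, degenerate = degenerate,
    shapiro_p = shapiro_p, confounders = conf, fit = fit),
    class = "homogenization_trend")
}

#' @export
print.homogenization_trend <- function(x, ...) {
  cat("Homogenization trend over", x$n_levels, "urbanization levels\n")
  cat(sprintf("  slope = %.4g +/- %.4g (t = %.3g, p = %.3g)\n",
              x$slope, x$se, x$t, x$p))
  cat(sprintf("  residual normality (Shapiro): p = %.3g\n", x$shapiro_p))
  cat("  confounder screen (midpoint vs):\n")
  print(x$confounders, digits = 3)
  invisible(x)
}
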