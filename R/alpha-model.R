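# Zero-truncated negative binomial (ZTNB) machinery.
#
# Site richness is an overdispersed count that is never 0 by design (no
# null community sample), hence NB conditioned on positivity:
#   P(Y = y | Y > 0) = NB(y; mu, theta) / (1 - p0),  p0 = (theta/(theta+mu))^theta
# with log link.  Random effects (Gaussian intercept per sampling-scheme
# category; optional spatial effect with exponential correlation) are
# integrated out by Laplace approximation at the joint mode.

ztnb_p0 <- function(eta, theta) {
  exp(theta * (log(theta) - log(theta + exp(eta))))
}

# per-observation log-likelihood
ztnb_ll <- function(y, eta, theta) {
  mu <- exp(eta)
  p0 <- ztnb_p0(eta, theta)
  dnbinom(y, size = theta, mu = mu, log = TRUE) - log1p(-p0)
}

# d loglik / d eta
ztnb_grad_eta <- function(y, eta, theta) {
  mu <- exp(eta)
  p0 <- ztnb_p0(eta, theta)
  y - mu * (y + theta) / (mu + theta) -
    theta * mu * p0 / ((1 - p0) * (theta + mu))
}

# observed information w.r.t. eta (central finite difference of the
# analytic gradient; floored for Newton stability)
ztnb_weight_eta <- function(y, eta, theta, h = 1e-4) {
  w <- -(ztnb_grad_eta(y, eta + h, theta) -
         ztnb_grad_eta(y, eta - h, theta)) / (2 * h)
  pmax(w, 1e-8)
}

# Find the joint mode of the random effects b given beta, theta and the
# precision of b; returns mode, penalized loglik and Laplace correction.
laplace_inner <- function(y, Xbeta, Z, Qb, b0 = NULL, theta,
                          tol = 1e-8, maxit = 50L) {
  q <- ncol(Z)
  b <- if (is.null(b0)) numeric(q) else b0
  pen_ll <- function(b) {
    sum(ztnb_ll(y, Xbeta + drop(Z %*% b), theta)) -
      0.5 * drop(crossprod(b, Qb %*% b))
  }
  f <- pen_ll(b)
  for (it in seq_len(maxit)) {
    eta <- Xbeta + drop(Z %*% b)
    g <- drop(crossprod(Z, ztnb_grad_eta(y, eta, theta))) - drop(Qb %*% b)
    W <- ztnb_weight_eta(y, eta, theta)
    H <- crossprod(Z * W, Z) + Qb
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    sz <- 1
    repeat {
      bn <- b + sz * step
      fn <- pen_ll(bn)
      if (is.finite(fn) && fn >= f - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { bn <- b; fn <- f; break }
    }
    conv <- abs(fn - f) < tol
    b <- bn; f <- fn
    if (conv) break
  }
  eta <- Xbeta + drop(Z %*% b)
  W <- ztnb_weight_eta(y, eta, theta)
  H <- crossprod(Z * W, Z) + Qb
  ch <- tryCatch(chol(H), error = function(e) NULL)
  logdetH <- if (is.null(ch)) {
    determinant(H, logarithm = TRUE)$modulus
  } else 2 * sum(log(diag(ch)))
  list(b = b, pen_ll = f, logdetH = as.numeric(logdetH))
}

#' Fit the richness-urbanization model
#'
#' Regresses site species richness on urbanization metrics and
#' biogeographical region with a zero-truncated negative binomial
#' likelihood (log link), a Gaussian random intercept per sampling-scheme
#' category, and (optionally) a Gaussian spatial random effect with
#' exponential correlation \eqn{\exp(-d/\rho)} between sites. Random
#' effects are integrated out by Laplace approximation; the spatial range
#' \eqn{\rho} is profiled over a log-spaced grid of distances.
#'
#' Continuous predictors are standardized internally: `pop_density` enters
#' as `log(x + 1)` then z-scored; `impervious_pct` is z-scored. This makes
#' the two urbanization coefficients directly comparable.
#'
#' @param sites site (or site-group) table; needs the predictor columns,
#'   `x`/`y` when `spatial = TRUE`, and a `sampling_category` column
#'   unless `random_category = FALSE`.
#' @param richness per-site species richness (all values >= 1).
#' @param terms character vector of fixed-effect terms among
#'   `"pop_density"`, `"impervious_pct"`, `"region"`; `character(0)` fits
#'   an intercept-only model.
#' @param spatial include the spatial random effect?
#' @param random_category include the per-category random intercept?
#' @param rho_grid candidate spatial ranges in meters (default: 8
#'   log-spaced values spanning the observed inter-site distances).
#' @param lrt_terms if `TRUE`, each term in `terms` is dropped in turn and
#'   tested against the full model by likelihood-ratio test ([lrt()]).
#' @param label model label stored in the result.
#' @return an object of class `fit_result`: coefficient table (term,
#'   estimate, se, z, p), variance components (`theta`, `sigma_cat`,
#'   `sigma_spatial`, `rho`), log-likelihood, convergence flag, residuals
#'   (response scale, conditional on the random-effect mode), and LRT
#'   records when requested.
#' @export
fit_richness_model <- function(sites, richness,
                               terms = c("pop_density", "impervious_pct",
                                         "region"),
                               spatial = TRUE, random_category = TRUE,
                               rho_grid = NULL, lrt_terms = FALSE,
                               label = "richness ~ urbanization") {
  y <- as.numeric(richness)
  if (any(y < 1)) stop("zero-truncated model requires richness >= 1 everywhere",
                       call. = FALSE)
  n <- length(y)
  if (nrow(sites) != n) stop("sites and richness lengths differ", call. = FALSE)

  X <- richness_design(sites, terms)
  cat_f <- NULL
  if (random_category) {
    if (is.null(sites$sampling_category)) {
      stop("sites$sampling_category missing (or set random_category = FALSE)",
           call. = FALSE)
    }
    cat_f <- factor(sites$sampling_category)
    if (nlevels(cat_f) < 2) {
      stop("need >= 2 sampling categories for the random intercept",
           call. = FALSE)
    }
  }

  if (spatial) {
    d <- as.matrix(dist(cbind(sites$x, sites$y)))
    if (is.null(rho_grid)) {
      pos <- d[upper.tri(d)][d[upper.tri(d)] > 0]
      if (!length(pos)) stop("all sites coincide: spatial effect undefined",
                             call. = FALSE)
      rho_grid <- exp(seq(log(max(quantile(pos, 0.05), 1e-3)),
                          log(max(pos)), length.out = 8))
    }
    fits <- lapply(rho_grid, function(rho) {
      ztnb_laplace_fit(y, X, cat_f, corr = exp(-d / rho))
    })
    best <- which.max(vapply(fits, function(f) f$loglik, 0))
    fit <- fits[[best]]
    fit$rho <- rho_grid[best]
  } else {
    fit <- ztnb_laplace_fit(y, X, cat_f, corr = NULL)
    fit$rho <- NA_real_
  }

  p <- ncol(X)
  coefs <- data.frame(
    term = colnames(X), estimate = fit$beta, se = fit$se,
    z = fit$beta / fit$se,
    p = 2 * pnorm(-abs(fit$beta / fit$se)),
    row.names = NULL)
  out <- structure(list(
    label = label,
    coefficients = coefs,
    varcomp = list(theta = fit$theta, sigma_cat = fit$sigma_cat,
                   sigma_spatial = fit$sigma_spatial, rho = fit$rho),
    loglik = fit$loglik,
    n = n, n_fixed = p,
    converged = fit$converged,
    warnings = fit$warnings,
    terms = terms, spatial = spatial, random_category = random_category,
    residuals = fit$residuals, fitted = fit$fitted),
    class = "fit_result")

  if (lrt_terms && length(terms)) {
    out$lrt <- do.call(rbind, lapply(terms, function(tm) {
      red <- fit_richness_model(sites, richness, terms = setdiff(terms, tm),
                                spatial = spatial,
                                random_category = random_category,
                                rho_grid = rho_grid, lrt_terms = FALSE,
                                label = paste("without", tm))
      l <- lrt(out, red)
      data.frame(term = tm, chi2 = l$chi2, df = l$df, p = l$p)
    }))
  }
  out
}

richness_design <- function(sites, terms) {
  cols <- list("(Intercept)" = rep(1, nrow(sites)))
  if ("pop_density" %in% terms) {
    cols$pop_density <- drop(scale(log1p(sites$pop_density)))
  }
  if ("impervious_pct" %in% terms) {
    cols$impervious_pct <- drop(scale(sites$impervious_pct))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if ("region" %in% terms) {
    rf <- factor(sites$region, levels = intersect(regions, unique(sites$region)))
    if (nlevels(rf) > 1) {
      R <- model.matrix(~rf)[, -1, drop = FALSE]
      colnames(R) <- paste0("region", levels(rf)[-1])
      X <- cbind(X, R)
    }
  }
  X
}

# Laplace ML over (beta, log theta, log sigma_cat, log sigma_spatial);
# corr is the fixed spatial correlation matrix for the current rho (or NULL)
ztnb_laplace_fit <- function(y, X, cat_f = NULL, corr = NULL) {
  n <- length(y)
  p <- ncol(X)
  Zc <- if (!is.null(cat_f)) {
    model.matrix(~ 0 + cat_f)
  }
  Zs <- if (!is.null(corr)) diag(n)
  Z <- cbind(Zc, Zs)
  has_re <- !is.null(Z)
  Rinv <- logdetR <- NULL
  if (!is.null(corr)) {
    chR <- chol(corr + diag(1e-8, n))
    Rinv <- chol2inv(chR)
    logdetR <- 2 * sum(log(diag(chR)))
  }
  qc <- if (is.null(Zc)) 0L else ncol(Zc)
  qs <- if (is.null(Zs)) 0L else n

  n_var <- (qc > 0) + (qs > 0)
  warm <- new.env()
  warm$b <- NULL

  negloglik <- function(par) {
    beta <- par[seq_len(p)]
    theta <- exp(par[p + 1])
    Xbeta <- drop(X %*% beta)
    if (!has_re) {
      ll <- sum(ztnb_ll(y, Xbeta, theta))
      return(if (is.finite(ll)) -ll else 1e10)
    }
    iv <- p + 1
    blocks <- list(); logdetS <- 0
    if (qc > 0) {
      s2 <- exp(2 * par[iv <- iv + 1])
      blocks <- c(blocks, list(diag(1 / s2, qc)))
      logdetS <- logdetS + qc * log(s2)
    }
    if (qs > 0) {
      s2 <- exp(2 * par[iv <- iv + 1])
      blocks <- c(blocks, list(Rinv / s2))
      logdetS <- logdetS + n * log(s2) + logdetR
    }
    Qb <- as.matrix(Matrix::bdiag(blocks))
    inner <- laplace_inner(y, Xbeta, Z, Qb, b0 = warm$b, theta = theta)
    warm$b <- inner$b
    ll <- inner$pen_ll - 0.5 * logdetS - 0.5 * inner$logdetH
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start <- c(solve(crossprod(X) + diag(1e-8, p),
                   crossprod(X, log(pmax(y, 1)))),
             log(2), rep(log(0.3), n_var))
  opt <- nlminb(start, negloglik,
                control = list(rel.tol = 1e-9, iter.max = 400, eval.max = 800))
  est <- opt$par
  warnings <- character(0)
  if (abs(est[p + 1]) > 10) {
    warnings <- c(warnings, "dispersion parameter theta at boundary")
  }
  H <- tryCatch(optimHess(est, negloglik), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    Vb <- tryCatch(solve(H)[seq_len(p), seq_len(p), drop = FALSE],
                   error = function(e) NULL)
    if (!is.null(Vb) && all(diag(Vb) > 0)) se <- sqrt(diag(Vb))
  }
  converged <- opt$convergence == 0 && all(is.finite(se))

  beta <- est[seq_len(p)]
  theta <- exp(est[p + 1])
  iv <- p + 1
  sigma_cat <- if (qc > 0) exp(est[iv <- iv + 1]) else NA_real_
  sigma_spatial <- if (qs > 0) exp(est[iv <- iv + 1]) else NA_real_

  eta <- drop(X %*% beta)
  if (has_re && !is.null(warm$b)) eta <- eta + drop(Z %*% warm$b)
  mu <- exp(eta)
  p0 <- ztnb_p0(eta, theta)
  fitted <- mu / (1 - p0)  # E[Y | Y > 0]
  list(beta = beta, se = se, theta = theta, sigma_cat = sigma_cat,
       sigma_spatial = sigma_spatial, loglik = -opt$objective,
       converged = converged, warnings = warnings,
       fitted = fitted, residuals = y - fitted)
}

#' Likelihood-ratio test between nested fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} (clipped at zero), with
#' degrees of freedom equal to the difference in fixed-effect parameter
#' counts and the p-value from the upper \eqn{\chi^2} tail.
#'
#' @param full,reduced converged `fit_result` objects; `reduced`'s terms
#'   must be a subset of `full`'s.
#' @return list with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$coefficients$term %in% full$coefficients$term)) {
    stop("models are not nested (reduced has terms absent from full)",
         call. = FALSE)
  }
  df <- full$n_fixed - reduced$n_fixed
  if (df < 1) stop("models are not nested (no dropped parameter)",
                   call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(x$label, if (!x$converged) "[NOT CONVERGED]", "\n")
  cat("  logLik:", format(x$loglik, digits = 6), " n:", x$n, "\n")
  print(x$coefficients, digits = 3)
  vc <- x$varcomp
  cat("  theta:", format(vc$theta, digits = 3))
  if (!is.na(vc$sigma_cat)) cat("  sigma_cat:", format(vc$sigma_cat, digits = 3))
  if (!is.na(vc$sigma_spatial)) {
    cat("  sigma_spatial:", format(vc$sigma_spatial, digits = 3),
        " rho:", format(vc$rho, digits = 3))
  }
  cat("\n")
  if (!is.null(x$lrt)) {
    cat("  Likelihood-ratio tests (drop one term):\n")
    print(x$lrt, digits = 3)
  }
  invisible(x)
}
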