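#' Moran's I spatial autocorrelation test
#'
#' Computes Moran's \eqn{I = (n/S_0)\, \sum_{ij} w_{ij} z_i z_j / \sum_i
#' z_i^2} on centered residuals \eqn{z}, with the expectation
#' \eqn{E[I] = -1/(n-1)} and the normal-approximation variance, used to
#' diagnose residual spatial structure of non-spatial richness models.
#'
#' The default weights are inverse distance restricted to the `k` nearest
#' neighbors of each point, row-standardized.
#'
#' @param residuals numeric residual vector (non-constant, length >= 3).
#' @param coordinates two-column matrix of planar coordinates (meters).
#' @param k neighbor support for the default weights (default 10).
#' @param weights optional pre-built n x n weight matrix (zero diagonal);
#'   overrides `k`.
#' @param row_standardize divide each row by its sum? Default `TRUE`.
#' @return list with `I`, `E_I`, `var_I`, `z`, `p` (two-sided).
#' @export
morans_i <- function(residuals, coordinates, k = 10, weights = NULL,
                     row_standardize = TRUE) {
  n <- length(residuals)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(residuals) == 0) {
    stop("Moran's I is undefined for constant residuals", call. = FALSE)
  }
  if (is.null(weights)) {
    d <- as.matrix(dist(coordinates))
    weights <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, -i])[seq_len(min(k, n - 1))]
      nb <- setdiff(seq_len(n), i)[nb]
      weights[i, nb] <- 1 / pmax(d[i, nb], 1e-10)
    }
  }
  diag(weights) <- 0
  if (all(weights == 0)) stop("all-zero spatial weights", call. = FALSE)
  if (row_standardize) {
    rs <- rowSums(weights)
    weights[rs > 0, ] <- weights[rs > 0, ] / rs[rs > 0]
  }
  z <- residuals - mean(residuals)
  S0 <- sum(weights)
  I <- (n / S0) * drop(crossprod(z, weights %*% z)) / sum(z^2)
  E_I <- -1 / (n - 1)
  S1 <- 0.5 * sum((weights + t(weights))^2)
  S2 <- sum((rowSums(weights) + colSums(weights))^2)
  var_I <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E_I^2
  zstat <- (I - E_I) / sqrt(var_I)
  list(I = I, E_I = E_I, var_I = var_I, z = zstat,
       p = 2 * pnorm(-abs(zstat)))
}

#' Collinearity check for the two urbanization metrics
#'
#' Pearson correlation and the two-variable variance inflation factor
#' \eqn{VIF = 1/(1 - r^2)}. A VIF below 5 is conventionally not considered
#' a problem; a warning is raised above that.
#'
#' @param pop_density,impervious_pct numeric vectors of equal length >= 3.
#' @return list with `r` and `VIF`.
#' @export
check_collinearity <- function(pop_density, impervious_pct) {
  if (length(pop_density) != length(impervious_pct) || length(pop_density) < 3) {
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  }
  if (sd(pop_density) == 0 || sd(impervious_pct) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r <- cor(pop_density, impervious_pct)
  vif <- 1 / (1 - r^2)
  if (!is.finite(vif) || vif > 5) {
    warning(sprintf("VIF = %.3g exceeds 5: metrics too collinear", vif),
            call. = FALSE)
  }
  list(r = r, VIF = vif)
}
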