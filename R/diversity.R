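#' Sorensen dissimilarity between two species sets
#'
#' The presence/absence Sorensen index \eqn{\beta_w = (b + c) / (2a + b +
#' c)} with \eqn{a} the number of shared species and \eqn{b}, \eqn{c} the
#' numbers unique to each community. 0 for identical composition, 1 for
#' fully disjoint communities.
#'
#' @param set_a,set_b character vectors of species names (non-empty).
#' @return dissimilarity in \[0, 1\].
#' @export
#' @examples
#' sorensen(c("x", "y"), c("y", "z"))  # 0.5
sorensen <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) {
    stop("Sorensen dissimilarity is undefined for an empty community",
         call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  (b + c_) / (2 * a + b + c_)
}

#' Pairwise Sorensen dissimilarity matrix
#'
#' Computes the symmetric matrix of Sorensen dissimilarities over all site
#' pairs of a community table, via incidence-matrix cross products.
#'
#' @param community a `community_table` (or a binary incidence matrix with
#'   site row names).
#' @return a symmetric matrix (class `beta_matrix`) with zero diagonal.
#' @export
pairwise_beta <- function(community) {
  inc <- if (inherits(community, "community_table")) community$incidence else
    as.matrix(community)
  if (nrow(inc) < 2) stop("need at least two sites", call. = FALSE)
  rich <- rowSums(inc)
  if (any(rich == 0)) {
    stop("empty community row(s): ",
         paste(rownames(inc)[rich == 0], collapse = ", "), call. = FALSE)
  }
  shared <- tcrossprod(inc)          # a for every pair
  tot <- outer(rich, rich, "+")      # 2a + b + c
  beta <- (tot - 2 * shared) / tot
  diag(beta) <- 0
  class(beta) <- c("beta_matrix", class(beta))
  beta
}

#' Sample coverage and asymptotic richness for one site
#'
#' Abundance-based sample coverage
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' and the Chao1 asymptotic richness estimate
#' \eqn{\hat S = S_{obs} + f_1^2 / (2 f_2)} (or
#' \eqn{S_{obs} + f_1 (f_1 - 1) / 2} when \eqn{f_2 = 0}), where \eqn{f_1}
#' and \eqn{f_2} count singleton and doubleton species and \eqn{n} is the
#' number of specimens. `pct_of_expected` = \eqn{100\, S_{obs} / \hat S}
#' screens sites for how completely the local community was sampled.
#'
#' @param abundance_vector positive integer abundances, one per observed
#'   species.
#' @param site_id optional identifier carried through to the output.
#' @return a one-row data frame with `n`, `S_obs`, `f1`, `f2`, `C_hat`,
#'   `S_est`, `pct_of_expected`.
#' @export
#' @examples
#' sample_coverage(c(1, 1, 2, 3))  # C_hat ~ 0.755
sample_coverage <- function(abundance_vector, site_id = NA_character_) {
  x <- abundance_vector[!is.na(abundance_vector)]
  if (!length(x)) stop("empty abundance vector", call. = FALSE)
  if (any(x < 1)) stop("abundances must be >= 1", call. = FALSE)
  n <- sum(x)
  S_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  C_hat <- if (f1 == 0) {
    1
  } else if (n == 1) {
    0  # a single singleton: no evidence of coverage
  } else {
    1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  }
  S_est <- if (f2 > 0) S_obs + f1^2 / (2 * f2) else S_obs + f1 * (f1 - 1) / 2
  data.frame(site_id = site_id, n = n, S_obs = S_obs, f1 = f1, f2 = f2,
             C_hat = C_hat, S_est = S_est,
             pct_of_expected = 100 * S_obs / S_est)
}

#' Per-site coverage table for a community table
#'
#' @param community a `community_table`.
#' @return a data frame with one [sample_coverage()] row per site.
#' @export
coverage_table <- function(community) {
  out <- do.call(rbind, lapply(seq_along(community$site_ids), function(i) {
    ab <- community$abundance[i, ]
    sample_coverage(ab[ab > 0], site_id = community$site_ids[i])
  }))
  rownames(out) <- NULL
  out
}

#' Species richness of an incidence row
#'
#' The number of species inventoried in a site: the count of 1-cells of
#' its presence/absence row.
#'
#' @param incidence_row binary vector (or a `community_table`, in which
#'   case per-site richness is returned).
#' @return integer richness.
#' @export
richness <- function(incidence_row) {
  if (inherits(incidence_row, "community_table")) {
    return(rowSums(incidence_row$incidence))
  }
  sum(incidence_row >= 1)
}
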