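# Shared fixtures and independent brute-force oracles.

make_sites_df <- function(coords, pop_density = NULL, impervious = NULL,
                          region = "Continental", active_days = 1,
                          passive_hours = 0, kick_net = 0) {
  n <- nrow(coords)
  validate_sites(data.frame(
    site_id = sprintf("s%d", seq_len(n)),
    x = coords[, 1], y = coords[, 2],
    pop_density = pop_density %||% rep(100, n),
    impervious_pct = impervious %||% rep(10, n),
    region = rep(region, length.out = n),
    active_days = rep(active_days, length.out = n),
    passive_hours = rep(passive_hours, length.out = n),
    kick_net = rep(kick_net, length.out = n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_records_df <- function(site_id, species, count) {
  data.frame(site_id = site_id, species = species, count = count,
             stringsAsFactors = FALSE)
}

make_traits_df <- function(species, nesting = "below", sociality = "social",
                           diet = "generalist", size = "small",
                           parasitic = FALSE) {
  n <- length(species)
  validate_traits(data.frame(
    species = species,
    nesting = rep(nesting, length.out = n),
    sociality = rep(sociality, length.out = n),
    diet = rep(diet, length.out = n),
    size = rep(size, length.out = n),
    parasitic = rep(parasitic, length.out = n),
    stringsAsFactors = FALSE))
}

# --- independent oracles ----------------------------------------------------

# Sorensen by direct set arithmetic
oracle_sorensen <- function(a, b) {
  sh <- length(intersect(a, b))
  (length(setdiff(a, b)) + length(setdiff(b, a))) /
    (2 * sh + length(setdiff(a, b)) + length(setdiff(b, a)))
}

# sample coverage / Chao1 written out afresh
oracle_coverage <- function(x) {
  n <- sum(x); f1 <- sum(x == 1); f2 <- sum(x == 2); S <- length(x)
  C <- if (f1 == 0) 1 else 1 - f1 / n * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  Sest <- if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
  list(C_hat = C, S_est = Sest)
}

# zero-truncated NB loglik by explicit renormalization through dnbinom(0)
oracle_ztnb_ll <- function(y, mu, theta) {
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE) -
        log(1 - dnbinom(0, size = theta, mu = mu)))
}

# Moran's I by the double loop
oracle_moran <- function(res, W) {
  n <- length(res)
  z <- res - mean(res)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# naive complete-linkage agglomeration with distance cutoff
oracle_complete_linkage <- function(coords, cutoff) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  groups <- as.list(seq_len(n))
  repeat {
    best <- c(NA, NA); bestd <- Inf
    if (length(groups) < 2) break
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        dij <- max(d[groups[[i]], groups[[j]]])
        if (dij < bestd) { bestd <- dij; best <- c(i, j) }
      }
    }
    if (bestd > cutoff) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

same_partition <- function(a, b) {
  identical(as.integer(factor(paste(a))), as.integer(factor(paste(b)))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}
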