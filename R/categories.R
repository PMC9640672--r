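#' Assign sampling-scheme categories from effort metadata
#'
#' Multi-survey syntheses cannot equalize sampling effort across sites, so
#' sites are instead classified into broad sampling-scheme categories that
#' later enter the models as a random grouping factor. Three effort
#' variables describe each site: `active_days` (days of active netting /
#' direct observation), `passive_hours` (total pan/malaise trap duration)
#' and `kick_net` (0/1).
#'
#' The variables are z-scored, then two partitions are computed: k-means
#' (fixed seed, best of 25 restarts) with `k_kmeans` clusters and
#' complete-linkage hierarchical clustering with `k_hier` clusters. The two
#' labelings are cross-tabulated; every non-empty (k-means, hierarchical)
#' cell is a candidate category, and candidates smaller than
#' `min_category_size` are merged into the candidate with the nearest
#' effort centroid (Euclidean, standardized space). When a `k` is `NULL`
#' it is chosen in `2..8` by maximum mean silhouette width.
#'
#' Zero-variance effort variables are dropped from standardization with a
#' warning; if all three are constant every site falls in one category.
#'
#' @param sites grouped site table with the three effort columns.
#' @param k_kmeans,k_hier number of clusters per method (default 3 and 4;
#'   `NULL` = automatic silhouette selection).
#' @param min_category_size smallest category kept before merging
#'   (default 5).
#' @param seed seed for the k-means restarts.
#' @return integer category labels (1-based, relabeled consecutively), with
#'   attribute `"crosstab"` giving the k-means x hierarchical table.
#' @export
assign_sampling_categories <- function(sites, k_kmeans = 3, k_hier = 4,
                                       min_category_size = 5, seed = 1L) {
  effort <- as.matrix(sites[, c("active_days", "passive_hours", "kick_net")])
  n <- nrow(effort)
  if (n < 2) stop("need at least two sites to categorize", call. = FALSE)
  if (n < max(k_kmeans %||% 2, k_hier %||% 2)) {
    stop("fewer sites than requested number of clusters", call. = FALSE)
  }
  sds <- apply(effort, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("zero-variance effort variable(s) dropped: ",
            paste(colnames(effort)[!keep], collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) {
    return(structure(rep(1L, n), crosstab = table(1L, 1L)))
  }
  z <- scale(effort[, keep, drop = FALSE])

  # canonical internal ordering (lexicographic in standardized effort space)
  # makes both partitions independent of the input row order
  ord <- do.call(order, as.data.frame(z))
  zo <- z[ord, , drop = FALSE]

  n_distinct <- nrow(unique(zo))
  cap <- min(8L, n_distinct)
  if (is.null(k_kmeans)) k_kmeans <- pick_k_silhouette(zo, cap, seed, "kmeans")
  if (is.null(k_hier))  k_hier  <- pick_k_silhouette(zo, cap, seed, "hclust")
  k_kmeans <- min(k_kmeans, n_distinct)
  k_hier <- min(k_hier, n_distinct)

  km <- hc <- integer(n)
  km[ord] <- with_seed(seed, kmeans(zo, centers = k_kmeans, nstart = 25,
                                    iter.max = 100))$cluster
  hc[ord] <- cutree(hclust(dist(zo), method = "complete"), k = k_hier)

  cand <- as.integer(factor(paste(km, hc, sep = ":")))
  crosstab <- table(kmeans = km, hier = hc)

  # merge undersized candidate categories into the nearest centroid
  repeat {
    sizes <- table(cand)
    small <- names(sizes)[sizes < min_category_size]
    if (!length(small) || length(sizes) <= 1) break
    victim <- small[which.min(sizes[small])]
    centroids <- do.call(rbind, lapply(split(seq_len(n), cand),
                                       function(i) colMeans(z[i, , drop = FALSE])))
    others <- setdiff(rownames(centroids), victim)
    dists <- sqrt(rowSums((centroids[others, , drop = FALSE] -
      matrix(centroids[victim, ], length(others), ncol(z), byrow = TRUE))^2))
    target <- others[which.min(dists)]
    cand[cand == as.integer(victim)] <- as.integer(target)
  }
  structure(as.integer(factor(cand)), crosstab = crosstab)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# mean silhouette width, computed directly (no cluster-package dependency)
mean_silhouette <- function(dmat, labels) {
  n <- nrow(dmat)
  ulab <- unique(labels)
  if (length(ulab) < 2) return(-Inf)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(dmat[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(ulab[ulab != labels[i]], function(l) {
      mean(dmat[i, labels == l])
    }, 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

pick_k_silhouette <- function(z, cap, seed, method) {
  dmat <- as.matrix(dist(z))
  ks <- seq(2L, max(2L, cap))
  hc_tree <- if (method == "hclust") hclust(as.dist(dmat), method = "complete")
  widths <- vapply(ks, function(k) {
    lab <- if (method == "kmeans") {
      with_seed(seed, kmeans(z, centers = k, nstart = 25, iter.max = 100))$cluster
    } else {
      cutree(hc_tree, k = k)
    }
    mean_silhouette(dmat, lab)
  }, 0)
  ks[which.max(widths)]
}

#' Log-transform a population density
#'
#' `log(x + 1)` (natural log), the transformation applied to human
#' population density to tame its orders of magnitude before binning or
#' modeling: densities of 0 to ~27,000 inhabitants/km2 map to roughly
#' 0 to 10.2 log-units.
#'
#' @param pop_density non-negative density value(s).
#' @return the transformed values.
#' @export
#' @examples
#' log_density(c(0, exp(1) - 1, 27076))
log_density <- function(pop_density) {
  if (any(pop_density < 0, na.rm = TRUE)) {
    stop("pop_density must be >= 0", call. = FALSE)
  }
  log1p(pop_density)
}
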