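#' Aggregate sampling sites closer than a distance cutoff
#'
#' Groups sites located less than `cutoff_m` apart (complete-linkage
#' hierarchical clustering on Euclidean distances, tree cut at height
#' `cutoff_m`), so that grouped sites are at most `cutoff_m` from every
#' other member. 500 m is the default because it encompasses the majority
#' of wild bee flight distances, making grouped points spatially
#' non-independent samples of the same community.
#'
#' Each group gets barycenter coordinates (unweighted mean of member
#' coordinates), summed `active_days` and `passive_hours`, `kick_net =`
#' max over members, urbanization metrics averaged (unweighted), and the
#' majority-vote region (ties broken by the first member in input order).
#' Records are re-keyed to the group ids, so the species set of a group is
#' the union over its members.
#'
#' @param sites validated site table.
#' @param records validated specimen records (re-keyed in the output).
#' @param cutoff_m complete-linkage cut height in meters (default 500).
#' @return list with `sites` (the grouped site table; extra columns
#'   `n_members` and `members`) and `records` (re-keyed).
#' @export
aggregate_sites <- function(sites, records, cutoff_m = 500) {
  if (!nrow(sites)) stop("need at least one site", call. = FALSE)
  if (cutoff_m <= 0) stop("cutoff_m must be > 0", call. = FALSE)
  if (nrow(sites) == 1L) {
    grp <- 1L
  } else {
    d <- dist(cbind(sites$x, sites$y))
    grp <- cutree(hclust(d, method = "complete"), h = cutoff_m)
  }
  ord <- order(vapply(split(seq_len(nrow(sites)), grp), min, 1L))
  grp <- match(grp, as.integer(names(split(seq_len(nrow(sites)), grp))[ord]))
  gid <- sprintf("grp_%03d", grp)

  majority <- function(x) {
    tab <- table(factor(x, levels = unique(x)))  # unique() keeps input order
    names(tab)[which.max(tab)]
  }
  pieces <- lapply(split(seq_len(nrow(sites)), gid), function(idx) {
    s <- sites[idx, , drop = FALSE]
    data.frame(
      x = mean(s$x), y = mean(s$y),
      pop_density = mean(s$pop_density),
      impervious_pct = mean(s$impervious_pct),
      region = majority(s$region),
      active_days = sum(s$active_days),
      passive_hours = sum(s$passive_hours),
      kick_net = max(s$kick_net),
      n_members = nrow(s),
      members = paste(s$site_id, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  grouped <- cbind(site_id = names(pieces), do.call(rbind, pieces))
  rownames(grouped) <- NULL

  out_records <- records
  if (nrow(records)) {
    out_records$site_id <- gid[match(records$site_id, sites$site_id)]
    if (anyNA(out_records$site_id)) {
      stop("records reference site ids absent from the site table", call. = FALSE)
    }
  }
  list(sites = grouped, records = out_records)
}
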