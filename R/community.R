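#' Filter taxa excluded from the analyses
#'
#' Removes the managed honeybee (*Apis mellifera*) and/or parasitic
#' (cleptoparasitic) species from the specimen records. The honeybee is a
#' domesticated species whose occurrence tracks beekeeping rather than
#' habitat quality; parasitic bees depend on their host's presence rather
#' than directly on the environment, so trait-filtering analyses exclude
#' them.
#'
#' Species without a row in the trait table are treated as non-parasitic,
#' with a warning.
#'
#' @param records validated specimen records.
#' @param traits validated trait table (used for the parasitic flag).
#' @param drop_honeybee remove all *Apis mellifera* records?
#' @param drop_parasitic remove records of parasitic-flagged species?
#' @return the filtered records, with attribute `"removed"` giving the
#'   number of records removed by each filter.
#' @export
filter_taxa <- function(records, traits, drop_honeybee = TRUE,
                        drop_parasitic = TRUE) {
  removed <- c(honeybee = 0L, parasitic = 0L)
  if (nrow(records)) {
    if (drop_honeybee) {
      is_apis <- records$species == "Apis mellifera"
      removed["honeybee"] <- sum(is_apis)
      records <- records[!is_apis, , drop = FALSE]
    }
    if (drop_parasitic && nrow(records)) {
      unknown <- setdiff(unique(records$species), traits$species)
      if (length(unknown)) {
        warning(length(unknown),
                " species without trait rows treated as non-parasitic",
                call. = FALSE)
      }
      para_sp <- traits$species[isTRUE_vec(traits$parasitic)]
      is_para <- records$species %in% para_sp
      removed["parasitic"] <- sum(is_para)
      records <- records[!is_para, , drop = FALSE]
    }
  }
  rownames(records) <- NULL
  attr(records, "removed") <- removed
  records
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Build the sites-by-species community table
#'
#' Cross-tabulates filtered specimen records into abundance and incidence
#' (presence/absence) matrices with deterministic lexicographic row and
#' column order. Abundance cells sum the counts of all records for a
#' (site, species) pair; incidence is `abundance >= 1`.
#'
#' Sites in `sites` with no record do not appear as rows: the surveys have
#' no null community sample, and downstream dissimilarity is undefined for
#' empty communities.
#'
#' @param records filtered specimen records.
#' @param sites validated site (or aggregated site-group) table.
#' @return an object of class `community_table`: a list with `site_ids`,
#'   `species`, `abundance` and `incidence` matrices.
#' @export
build_community_table <- function(records, sites) {
  if (!nrow(records)) stop("no records: cannot build a community table",
                           call. = FALSE)
  site_ids <- sort(intersect(sites$site_id, unique(records$site_id)))
  species <- sort(unique(records$species))
  abundance <- matrix(0L, length(site_ids), length(species),
                      dimnames = list(site_ids, species))
  i <- match(records$site_id, site_ids)
  j <- match(records$species, species)
  for (k in seq_len(nrow(records))) {
    abundance[i[k], j[k]] <- abundance[i[k], j[k]] + records$count[k]
  }
  structure(list(
    site_ids = site_ids,
    species = species,
    abundance = abundance,
    incidence = (abundance >= 1L) * 1L), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", length(x$site_ids), "sites x",
      length(x$species), "species;",
      sum(x$abundance), "specimens,", sum(x$incidence), "occurrences\n")
  invisible(x)
}
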