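#' Load a survey dataset from delimited files
#'
#' Reads the three standard tables of a wild-bee survey dataset and
#' validates them against the package schema:
#'
#' \describe{
#'   \item{records}{`site_id, species, count[, year]` — one row per
#'     (site, species) specimen batch, `count >= 1`.}
#'   \item{sites}{`site_id, x, y, pop_density, impervious_pct, region,
#'     active_days, passive_hours, kick_net` — one row per sampling site.
#'     `x`/`y` are projected planar coordinates in meters (a national grid
#'     such as Lambert-93 is assumed; all distance rules are metric).
#'     `pop_density` is inhabitants per km2 within a 500 m radius;
#'     `impervious_pct` the percent impervious surface within 500 m.}
#'   \item{traits}{`species, nesting, sociality, diet, size, itd_mm,
#'     parasitic` — per-species functional trait modalities. Missing
#'     modalities are coded `"no_information"`.}
#' }
#'
#' Rows violating a type invariant (e.g. `impervious_pct` outside
#' \[0, 100\], `count < 1`, a record referencing an unknown site) are
#' reported with row-addressed messages and cause an error. Species
#' present in the records but absent from the trait table are permitted;
#' their traits default to `"no_information"` and `parasitic = FALSE`.
#'
#' @param records_path,sites_path,traits_path paths to the delimited files.
#' @param sep field separator; `","` (default) or `"\t"`. Files ending in
#'   `.tsv`/`.txt` default to tab.
#' @return a list with validated data frames `records`, `sites`, `traits`.
#' @export
#' @examples
#' dir <- tempfile(); make_fixture("tiny", dir, seed = 1)
#' d <- load_dataset(file.path(dir, "records.csv"),
#'                   file.path(dir, "sites.csv"),
#'                   file.path(dir, "traits.csv"))
#' nrow(d$sites)
load_dataset <- function(records_path, sites_path, traits_path, sep = NULL) {
  records <- read_table_checked(records_path, c("site_id", "species", "count"), sep)
  sites   <- read_table_checked(sites_path,
    c("site_id", "x", "y", "pop_density", "impervious_pct", "region",
      "active_days", "passive_hours", "kick_net"), sep)
  traits  <- read_table_checked(traits_path,
    c("species", "nesting", "sociality", "diet", "size", "parasitic"), sep)

  sites   <- validate_sites(sites)
  records <- validate_records(records, sites)
  traits  <- validate_traits(traits)
  list(records = records, sites = sites, traits = traits)
}

read_table_checked <- function(path, required, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error in '", basename(path), "': missing mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

regions <- c("Continental", "Atlantic", "Mediterranean", "Alpine")

#' @rdname load_dataset
#' @param sites a sites data frame (already read).
#' @export
validate_sites <- function(sites) {
  problems <- character(0)
  num_cols <- c("x", "y", "pop_density", "impervious_pct",
                "active_days", "passive_hours", "kick_net")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(sites[[col]]))
    bad <- which(is.na(v) & !is.na(sites[[col]]))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "sites row %d: non-numeric %s ('%s')", bad, col, sites[[col]][bad]))
    }
    sites[[col]] <- v
  }
  chk <- function(idx, msg) {
    if (length(idx)) problems <<- c(problems, sprintf("sites row %d: %s", idx, msg))
  }
  chk(which(sites$impervious_pct < 0 | sites$impervious_pct > 100),
      "impervious_pct outside [0, 100]")
  chk(which(sites$pop_density < 0), "pop_density must be >= 0")
  chk(which(sites$active_days < 0), "active_days must be >= 0")
  chk(which(sites$passive_hours < 0), "passive_hours must be >= 0")
  chk(which(!sites$kick_net %in% c(0, 1)), "kick_net must be 0 or 1")
  chk(which(!sites$region %in% regions),
      paste0("region must be one of ", paste(regions, collapse = ", ")))
  chk(which(duplicated(sites$site_id)), "duplicated site_id")
  if (length(problems)) {
    stop("invalid sites table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  sites$site_id <- as.character(sites$site_id)
  sites
}

#' @rdname load_dataset
#' @param records a records data frame (already read).
#' @export
validate_records <- function(records, sites) {
  problems <- character(0)
  cnt <- suppressWarnings(as.numeric(records$count))
  bad <- which((is.na(cnt) & !is.na(records$count)) | cnt < 1 | cnt != round(cnt))
  if (length(bad)) {
    problems <- c(problems, sprintf("records row %d: count must be an integer >= 1", bad))
  }
  records$count <- as.integer(cnt)
  records$site_id <- as.character(records$site_id)
  records$species <- normalize_species(records$species)
  orphans <- setdiff(unique(records$site_id), sites$site_id)
  if (length(orphans)) {
    problems <- c(problems, paste0(
      "referential error: record site_id(s) absent from sites table: ",
      paste(orphans, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid records table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  records
}

#' @rdname load_dataset
#' @param traits a traits data frame (already read).
#' @export
validate_traits <- function(traits) {
  problems <- character(0)
  allowed <- list(
    nesting   = c("above", "below", "no_information"),
    sociality = c("social", "solitary", "no_information"),
    diet      = c("generalist", "specialist", "no_information"),
    size      = c("small", "large", "no_information"))
  for (col in names(allowed)) {
    v <- as.character(traits[[col]])
    v[is.na(v) | v == ""] <- "no_information"
    bad <- which(!v %in% allowed[[col]])
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "traits row %d: %s = '%s' not in {%s}", bad, col, v[bad],
        paste(allowed[[col]], collapse = ", ")))
    }
    traits[[col]] <- v
  }
  traits$parasitic <- as.logical(traits$parasitic)
  if (anyNA(traits$parasitic)) {
    problems <- c(problems, sprintf(
      "traits row %d: parasitic must be TRUE/FALSE",
      which(is.na(traits$parasitic))))
  }
  if ("itd_mm" %in% names(traits)) {
    itd <- suppressWarnings(as.numeric(traits$itd_mm))
    inconsistent <- which(!is.na(itd) &
      ((traits$size == "small" & itd >= 2) | (traits$size == "large" & itd <= 2)))
    if (length(inconsistent)) {
      problems <- c(problems, sprintf(
        "traits row %d: size class inconsistent with itd_mm (cut at 2 mm)",
        inconsistent))
    }
    traits$itd_mm <- itd
  }
  traits$species <- normalize_species(traits$species)
  if (length(problems)) {
    stop("invalid traits table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  traits
}

# Case-insensitive matching after whitespace normalization; species-complex
# labels ("Bombus gr. terrestris") stay single taxa.
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
}

#' Write an analysis result with a JSON metadata sidecar
#'
#' Serializes any result object of the package (a [fit_richness_model()] /
#' [fit_trait_glmm()] fit, a list of beta-diversity level summaries, a data
#' frame) to a delimited table for human consumption plus a JSON sidecar
#' (`<path>.json`) holding the complete object together with metadata
#' (package version, optional seed, config hash). [read_results()] restores
#' the object from the sidecar so that `read_results(write_results(x)) == x`.
#'
#' @param x the result object.
#' @param path output path for the delimited table.
#' @param format `"csv"` or `"tsv"`.
#' @param force overwrite an existing file? Default `FALSE` (refuse).
#' @param seed,config optional metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "tsv"), force = FALSE,
                          seed = NULL, config = NULL) {
  format <- match.arg(format)
  sidecar <- paste0(path, ".json")
  if (!force && (file.exists(path) || file.exists(sidecar))) {
    stop("refusing to overwrite '", path, "' (use force = TRUE)", call. = FALSE)
  }
  tab <- as_result_table(x)
  write.csv(tab, path, row.names = FALSE,
            quote = TRUE)
  meta <- list(
    package = "urbanbees",
    version = as.character(utils::packageVersion("urbanbees")),
    class = class(x),
    seed = seed,
    config_hash = if (!is.null(config)) {
      sum(utf8ToInt(paste(deparse(config), collapse = "")))
    },
    object = strip_environments(x))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

# model frames / fitted lme4 objects are not JSON-serializable; results keep
# only plain components in the sidecar
strip_environments <- function(x) {
  if (is.function(x) || inherits(x, c("merMod", "formula"))) return(NULL)
  if (is.environment(x)) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, strip_environments)
    attributes(out) <- attributes(x)[setdiff(names(attributes(x)), "names")]
    names(out) <- names(x)
    return(out)
  }
  x
}

as_result_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "fit_result")) return(x$coefficients)
  if (inherits(x, "beta_level_list") ||
      (is.list(x) && length(x) && inherits(x[[1]], "beta_level_summary"))) {
    return(do.call(rbind, lapply(x, as.data.frame)))
  }
  if (is.list(x)) {
    flat <- x[vapply(x, function(el) is.atomic(el) && length(el) == 1, TRUE)]
    return(as.data.frame(flat))
  }
  as.data.frame(x)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("no sidecar found at ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  obj <- restore_result(meta$object, meta$class)
  attr(obj, "metadata") <- meta[c("package", "version", "seed", "config_hash")]
  obj
}

restore_result <- function(obj, cls) {
  if (is.null(obj)) return(NULL)
  if ("fit_result" %in% cls || "trait_fit_result" %in% cls) {
    obj$coefficients <- as.data.frame(obj$coefficients)
    if (!is.null(obj$lrt)) obj$lrt <- as.data.frame(obj$lrt)
    class(obj) <- intersect(cls, c("trait_fit_result", "fit_result"))
    return(obj)
  }
  if ("beta_level_list" %in% cls) {
    if (is.data.frame(obj)) {  # jsonlite simplifies the list of records
      obj <- lapply(seq_len(nrow(obj)), function(i) as.list(obj[i, ]))
    }
    out <- lapply(obj, function(lv) {
      lv <- as.list(lv)
      class(lv) <- "beta_level_summary"
      lv
    })
    class(out) <- "beta_level_list"
    return(out)
  }
  if ("data.frame" %in% cls) return(as.data.frame(obj))
  obj
}
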