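#' Construct a community matrix
#'
#' A `community_matrix` holds a sites-by-species occurrence table. In
#' presence/absence mode every entry is 0 or 1; abundance tables are carried
#' through unchanged (binary mode is auto-detected unless given).
#'
#' @param occurrences numeric matrix (sites in rows, species in columns) with
#'   unique row and column names.
#' @param binary logical; `NULL` (default) auto-detects whether all entries
#'   are in `{0, 1}`.
#' @return an object of class `community_matrix` with elements `occurrences`,
#'   `site_ids`, `species_ids`, `binary`.
#' @export
community_matrix <- function(occurrences, binary = NULL) {
  occurrences <- as.matrix(occurrences)
  if (is.null(rownames(occurrences)) || is.null(colnames(occurrences)))
    stop("occurrence matrix must carry site (row) and species (column) names")
  if (anyDuplicated(rownames(occurrences)))
    stop("duplicate site label(s): ",
         paste(unique(rownames(occurrences)[duplicated(rownames(occurrences))]),
               collapse = ", "))
  if (anyDuplicated(colnames(occurrences)))
    stop("duplicate species label(s): ",
         paste(unique(colnames(occurrences)[duplicated(colnames(occurrences))]),
               collapse = ", "))
  if (!is.numeric(occurrences) || anyNA(occurrences))
    stop("occurrences must be numeric with no missing values")
  storage.mode(occurrences) <- "double"
  if (any(occurrences < 0)) stop("occurrences must be nonnegative")
  if (is.null(binary)) binary <- all(occurrences %in% c(0, 1))
  if (binary && !all(occurrences %in% c(0, 1)))
    stop("binary mode requested but entries outside {0, 1} present")
  empty <- rowSums(occurrences) == 0
  if (any(empty))
    warning("all-zero site row(s): ",
            paste(rownames(occurrences)[empty], collapse = ", "))
  structure(
    list(occurrences = occurrences,
         site_ids = rownames(occurrences),
         species_ids = colnames(occurrences),
         binary = binary),
    class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species (%s)\n",
              nrow(x$occurrences), ncol(x$occurrences),
              if (x$binary) "presence/absence" else "abundance"))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$occurrences)

#' Read a site-by-species table from delimited text
#'
#' Expects a header row of species labels and a first column of site labels;
#' remaining cells must parse as nonnegative numbers. Binary
#' (presence/absence) mode is auto-detected and recorded.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return a [community_matrix()].
#' @export
read_presence_absence <- function(path, sep = ",") {
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    row.names = NULL, colClasses = "character",
                    fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("table must have a site-label column plus >= 1 species")
  sites <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals),
                dimnames = list(sites, colnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at site '%s', species '%s'",
                 sites[bad[1]], colnames(vals)[bad[2]]))
  }
  community_matrix(num)
}

#' Write a community matrix as delimited text
#'
#' Inverse of [read_presence_absence()]: header row of species labels, first
#' column of site labels.
#'
#' @param x a [community_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_presence_absence <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "community_matrix"))
  df <- data.frame(site_id = x$site_ids, x$occurrences,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Combine two community matrices over disjoint site sets
#'
#' Appends the sites of `addition` to `base`; the species set becomes the
#' union (base species first, then the addition's new species in their own
#' order), with absences filled in as zeros. Used to join newly surveyed
#' sites onto an existing regional dataset.
#'
#' @param base,addition [community_matrix()] objects with disjoint site labels.
#' @return a [community_matrix()] with all sites and the species union.
#' @export
combine_datasets <- function(base, addition) {
  stopifnot(inherits(base, "community_matrix"),
            inherits(addition, "community_matrix"))
  shared_sites <- intersect(base$site_ids, addition$site_ids)
  if (length(shared_sites))
    stop("overlapping site label(s): ", paste(shared_sites, collapse = ", "))
  species <- c(base$species_ids,
               setdiff(addition$species_ids, base$species_ids))
  out <- matrix(0, nrow = length(base$site_ids) + length(addition$site_ids),
                ncol = length(species),
                dimnames = list(c(base$site_ids, addition$site_ids), species))
  out[base$site_ids, base$species_ids] <- base$occurrences
  out[addition$site_ids, addition$species_ids] <- addition$occurrences
  community_matrix(out, binary = base$binary && addition$binary)
}

#' Read a site coordinate table
#'
#' Delimited text with columns `site_id`, `latitude_deg`, `longitude_deg`
#' (optionally `region_label`). Latitudes must lie in \[-90, 90\] and
#' longitudes in \[-180, 180).
#'
#' @param path file path.
#' @param sep field separator.
#' @return a data frame of site records.
#' @export
read_site_coords <- function(path, sep = ",") {
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  validate_site_records(df)
}

validate_site_records <- function(df) {
  need <- c("site_id", "latitude_deg", "longitude_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing coordinate column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id in coordinate table")
  if (any(df$latitude_deg < -90 | df$latitude_deg > 90))
    stop("latitude out of [-90, 90]")
  if (any(df$longitude_deg < -180 | df$longitude_deg >= 180))
    stop("longitude out of [-180, 180)")
  df
}
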