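#' Construct and validate an incidence matrix
#'
#' An incidence matrix is a binary units-by-species occurrence table: rows are
#' analysis units (sampling sites or whole streams), columns are species, and
#' cells are 1 (present) or 0 (absent). It is the universal input of all
#' pairwise beta-diversity computations in this package.
#'
#' @param x matrix or data.frame of 0/1 values, units in rows, species in
#'   columns. Row and column names are the unit and species labels.
#' @param coerce if `TRUE`, any nonzero cell is binarized to 1 (for abundance
#'   exports). If `FALSE` (default) non-binary cells are an error: the
#'   analyses are strictly presence/absence and binarization must be opt-in.
#' @return an object of class `incidence_matrix`: an integer matrix with unit
#'   and species dimnames.
#' @examples
#' m <- incidence_matrix(rbind(s1 = c(A = 1, B = 0), s2 = c(A = 1, B = 1)))
#' unit_ids(m)
#' @export
incidence_matrix <- function(x, coerce = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data.frame")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty incidence matrix")
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("incidence matrix contains missing values")
  if (coerce) {
    x[] <- as.numeric(x != 0)
  } else if (!all(x == 0 | x == 1)) {
    bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-binary cell at unit '%s', species '%s'; set coerce = TRUE to binarize",
      rownames(x)[bad[1]] %||% bad[1], colnames(x)[bad[2]] %||% bad[2]
    ))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("unit", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate unit labels")
  if (anyDuplicated(colnames(x))) stop("duplicate species labels")
  storage.mode(x) <- "integer"
  class(x) <- c("incidence_matrix", "matrix", "array")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf(
    "incidence matrix: %d units x %d species (%d presences)\n",
    nrow(x), ncol(x), sum(x)
  ))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(8L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L || ncol(x) > 8L) cat("...\n")
  invisible(x)
}

#' @rdname incidence_matrix
#' @param m an `incidence_matrix`
#' @export
unit_ids <- function(m) rownames(m)

#' @rdname incidence_matrix
#' @export
species_ids <- function(m) colnames(m)

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an incidence matrix from delimited text
#'
#' Expects units in rows and species in columns (first column = unit labels,
#' header = species labels); `transpose = TRUE` handles the other orientation.
#' The delimiter is auto-detected from the extension (`.tsv`/`.txt` = tab,
#' anything else = comma) unless given explicitly.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects by extension.
#' @param transpose set `TRUE` when the file stores species in rows.
#' @param coerce passed to [incidence_matrix()]: opt-in binarization of
#'   abundance values.
#' @return an `incidence_matrix`.
#' @export
read_incidence <- function(path, delim = NULL, transpose = FALSE, coerce = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                         row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (transpose) m <- t(m)
  incidence_matrix(m, coerce = coerce)
}

#' Write an incidence matrix to delimited text
#'
#' Inverse of [read_incidence()]: a round trip preserves labels and values
#' exactly.
#'
#' @inheritParams read_incidence
#' @param m an `incidence_matrix`.
#' @export
write_incidence <- function(m, path, delim = NULL) {
  d <- data.frame(unit = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(d, path, sep = delim_for(path, delim), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a species taxonomy table
#'
#' A two- or three-column delimited file mapping each species to its family
#' (and optionally order). Every species must appear exactly once.
#'
#' @param path file path to a CSV/TSV with columns `species,family[,order]`.
#' @param delim delimiter, auto-detected by extension when `NULL`.
#' @return a data.frame with columns `species`, `family` and (if present)
#'   `order`.
#' @export
read_taxonomy <- function(path, delim = NULL) {
  d <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  names(d) <- tolower(names(d))
  if (!all(c("species", "family") %in% names(d)))
    stop("taxonomy table needs columns 'species' and 'family'")
  validate_taxonomy(d)
}

validate_taxonomy <- function(d) {
  if (anyDuplicated(d$species))
    stop("duplicate species in taxonomy: ",
         paste(unique(d$species[duplicated(d$species)]), collapse = ", "))
  d
}

#' IUCN-style threat categories recognised by the package
#' @export
THREAT_CATEGORIES <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Read a species threat-status table
#'
#' Two-column delimited file `species,category` with categories from the
#' IUCN-style vocabulary CR, EN, VU, NT, LC, DD, NE.
#'
#' @inheritParams read_taxonomy
#' @return data.frame with columns `species`, `category`.
#' @export
read_threat <- function(path, delim = NULL) {
  d <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  names(d) <- tolower(names(d))
  if (!all(c("species", "category") %in% names(d)))
    stop("threat table needs columns 'species' and 'category'")
  bad <- setdiff(unique(d$category), THREAT_CATEGORIES)
  if (length(bad))
    stop("unknown threat categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(d$species)) stop("duplicate species in threat table")
  d
}

#' The seven environmental variables of a stream table
#' @export
ENV_VARIABLES <- c("length", "area", "gradient", "precipitation",
                   "temperature", "runoff", "altitude")

#' Read a per-stream environmental table
#'
#' One row per stream with the seven hydrological/environmental variables
#' used by the driver analysis: `length` (km), `area` (km^2), `gradient`
#' (average channel gradient, %), `precipitation` (average annual, mm),
#' `temperature` (average, degrees C), `runoff` (annual average, 1e8 m^3),
#' `altitude` (average, m). All values must be finite and positive.
#'
#' @inheritParams read_taxonomy
#' @return data.frame with a `stream` column plus the seven numeric columns.
#' @export
read_env <- function(path, delim = NULL) {
  d <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- tolower(names(d))
  if (!"stream" %in% names(d)) stop("environmental table needs a 'stream' column")
  d$stream <- as.character(d$stream)
  miss <- setdiff(ENV_VARIABLES, names(d))
  if (length(miss))
    stop("environmental table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$stream)) stop("duplicate stream rows")
  vals <- as.matrix(d[ENV_VARIABLES])
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("environmental values must be finite and positive")
  d
}

#' Read a site-to-stream grouping map
#'
#' Two-column delimited file `site,stream`, optionally with a third `region`
#' column assigning streams to regions (e.g. ES / WS).
#'
#' @inheritParams read_taxonomy
#' @return data.frame with columns `site`, `stream` and optionally `region`.
#' @export
read_grouping <- function(path, delim = NULL) {
  d <- utils::read.table(path, sep = delim_for(path, delim), header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  names(d) <- tolower(names(d))
  if (!all(c("site", "stream") %in% names(d)))
    stop("grouping map needs columns 'site' and 'stream'")
  if (anyDuplicated(d$site)) stop("duplicate site rows in grouping map")
  d
}

#' Aggregate a site-level incidence matrix to stream level
#'
#' Stream presence is the union (logical OR) of the member sites' presences.
#' Stream order is first-appearance order in the grouping map, never
#' alphabetical, so downstream pairwise matrices are reproducible.
#'
#' @param m site-level `incidence_matrix`.
#' @param grouping data.frame with columns `site`, `stream`
#'   (see [read_grouping()]).
#' @return stream-level `incidence_matrix`.
#' @examples
#' m <- incidence_matrix(rbind(s1 = c(1, 0), s2 = c(0, 1)))
#' g <- data.frame(site = c("s1", "s2"), stream = "A")
#' aggregate_to_streams(m, g)  # stream A row is 1,1
#' @export
aggregate_to_streams <- function(m, grouping) {
  missing_sites <- setdiff(rownames(m), grouping$site)
  if (length(missing_sites))
    stop("sites missing from grouping map: ",
         paste(missing_sites, collapse = ", "))
  g <- grouping[match(rownames(m), grouping$site), , drop = FALSE]
  streams <- unique(grouping$stream[grouping$site %in% rownames(m)])
  out <- matrix(0L, length(streams), ncol(m),
                dimnames = list(streams, colnames(m)))
  for (s in streams) {
    rows <- m[g$stream == s, , drop = FALSE]
    out[s, ] <- as.integer(apply(rows, 2, max))
  }
  incidence_matrix(out)
}

#' Restrict an incidence matrix to one family's species
#'
#' Keeps only the columns whose species belong to `family` in the taxonomy.
#' Units whose row becomes all-zero are kept by default (the convention used
#' for family-level summary tables, where a unit lacking the family still
#' takes part in pairwise comparisons under the degenerate-pair rules) or
#' dropped with `empty_units = "drop"`.
#'
#' @param m an `incidence_matrix`.
#' @param taxonomy data.frame with `species`, `family` columns.
#' @param family family label to keep.
#' @param empty_units `"keep"` (default) or `"drop"` all-zero unit rows.
#' @return an `incidence_matrix` over the family's species.
#' @export
subset_by_family <- function(m, taxonomy, family,
                             empty_units = c("keep", "drop")) {
  empty_units <- match.arg(empty_units)
  if (!family %in% taxonomy$family) stop("unknown family: ", family)
  sp <- taxonomy$species[taxonomy$family == family]
  keep <- intersect(colnames(m), sp)
  if (!length(keep)) stop("family '", family, "' has no species in the matrix")
  out <- unclass(m)[, keep, drop = FALSE]
  if (empty_units == "drop") out <- out[rowSums(out) > 0, , drop = FALSE]
  if (nrow(out) == 0L) stop("no units left after dropping empty rows")
  incidence_matrix(out)
}
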