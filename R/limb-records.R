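#' Construct a table of limb records
#'
#' A limb record holds one species' element lengths (mm), its taxonomic
#' group, stratigraphic range (first and last appearance data, Ma before
#' present, decreasing toward the present) and lifestyle flags.  Records are
#' stored as a data frame with one row per species; element columns that
#' were never measured may be absent or `NA`.
#'
#' @param species character vector of unique species identifiers.
#' @param group character vector; each entry one of [TAXON_GROUPS].
#' @param fad,lad numeric, first/last appearance ages in Ma; `fad >= lad`.
#' @param flying,aquatic logical flags; flying and fully aquatic taxa are
#'   excluded from locomotor analyses.
#' @param ... element length columns named after [LIMB_ELEMENTS], numeric,
#'   strictly positive where present.
#' @return a `data.frame` of class `limb_records`.
#' @export
limb_records <- function(species, group, fad, lad,
                         flying = FALSE, aquatic = FALSE, ...) {
  df <- data.frame(species = as.character(species),
                   group = as.character(group),
                   fad = as.numeric(fad), lad = as.numeric(lad),
                   flying = as.logical(flying), aquatic = as.logical(aquatic),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  bad <- setdiff(names(extra), LIMB_ELEMENTS)
  if (length(bad) > 0)
    stop("unknown element column(s): ", paste(bad, collapse = ", "))
  for (el in names(extra)) df[[el]] <- as.numeric(extra[[el]])
  validate_limb_records(df)
}

#' Validate a limb-record table
#'
#' Checks the invariants of the record table: unique species identifiers,
#' recognised groups, `fad >= lad`, and strictly positive element lengths.
#' Violations are reported with the offending row numbers and species.
#'
#' @param df data frame with at least columns `species`, `group`, `fad`,
#'   `lad`.
#' @return the validated data frame with class `limb_records` prepended.
#' @export
validate_limb_records <- function(df) {
  req <- c("species", "group", "fad", "lad")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicated species identifiers: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  badg <- !(df$group %in% TAXON_GROUPS)
  if (any(badg))
    stop("unrecognised group in row(s) ",
         paste(which(badg), collapse = ", "), ": ",
         paste(unique(df$group[badg]), collapse = ", "))
  rev <- !is.na(df$fad) & !is.na(df$lad) & df$fad < df$lad
  if (any(rev))
    stop("fad < lad (ranges reversed) for species: ",
         paste(df$species[rev], collapse = ", "),
         " (row ", paste(which(rev), collapse = ", "), ")")
  for (el in intersect(LIMB_ELEMENTS, names(df))) {
    neg <- !is.na(df[[el]]) & df[[el]] <= 0
    if (any(neg))
      stop("non-positive ", el, " length for species: ",
           paste(df$species[neg], collapse = ", "),
           " (row ", paste(which(neg), collapse = ", "), ")")
  }
  if (!("flying" %in% names(df))) df$flying <- FALSE
  if (!("aquatic" %in% names(df))) df$aquatic <- FALSE
  class(df) <- unique(c("limb_records", class(df)))
  df
}

#' Read a limb-measurement table from CSV
#'
#' Expects a header row with at least `species`, `group`, `fad`, `lad`;
#' element columns (see [LIMB_ELEMENTS]) and `flying`/`aquatic` flags are
#' optional.  Rows violating the record invariants abort the read with an
#' error naming the rows and species involved.
#'
#' @param path path to a CSV file.
#' @return a `limb_records` data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "group", "fad", "lad")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("measurement file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  validate_limb_records(df)
}

#' Write a limb-measurement table to CSV
#'
#' @param records a `limb_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
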