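#' Default column mapping for survey manifests
#'
#' A survey manifest is a tab-separated table with one row per sampling event
#' (site and date), carrying location, a short unique code, decimal-degree
#' coordinates, a verbatim date string, the sample type (`ES` for an
#' environmental sequence, `CI` for a cultured isolate), the host taxon, and a
#' semicolon-separated list of sequence accession identifiers. The dialect maps
#' these logical fields to column names in the file.
#'
#' @param location,code,lon,lat,date,sample_type,host,accessions Column names
#'   in the file for each logical field.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_manifest()].
#' @export
manifest_dialect <- function(location = "Location", code = "Code",
                             lon = "Lon", lat = "Lat", date = "Date",
                             sample_type = "SampleType", host = "Host",
                             accessions = "Accessions") {
  c(location = location, code = code, lon = lon, lat = lat, date = date,
    sample_type = sample_type, host = host, accessions = accessions)
}

#' Hosts recognised by default in survey manifests
#'
#' The four North American amphibian hosts whose egg capsules harbour
#' chlamydomonad symbionts, plus the free-living category used for culture
#' collection strains. Hosts outside the vocabulary raise a warning (not an
#' error) so the reader can be reused for other surveys.
#'
#' @return Character vector of host labels.
#' @export
default_host_vocabulary <- function() {
  c("A. maculatum", "A. gracile", "L. sylvatica", "L. aurora", "Free-living")
}

# en dash / minus sign / figure dash to ASCII hyphen
normalize_dashes <- function(x) {
  gsub("–|−|‒|—", "-", x)
}

split_accessions <- function(x) {
  x[is.na(x)] <- ""
  parts <- strsplit(x, "[;,[:space:]]+")
  lapply(parts, function(p) p[nzchar(p)])
}

#' Read a clone-library survey manifest
#'
#' Reads a tab-separated manifest (one row per sampling event) and validates
#' it: codes must be unique, coordinates in range, sample types `ES`/`CI`,
#' and every accession non-empty and unique across the whole file. En dashes
#' in any field are normalised to ASCII hyphens on ingest; dates are kept as
#' verbatim strings because field records mix day-first and month-first forms.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param dialect Column mapping, see [manifest_dialect()].
#' @param host_vocabulary Character vector of expected host labels; hosts
#'   outside it produce a warning, not an error. `NULL` disables the check.
#' @return A tibble of class `sample_manifest` with columns `location`,
#'   `code`, `lon`, `lat`, `date`, `sample_type`, `host` and a list-column
#'   `accessions`, rows in file order.
#' @seealso [count_accessions()], [write_manifest()]
#' @examples
#' m <- read_manifest(system.file("extdata", "egg_capsule_survey.tsv",
#'                                package = "clonesurvey"))
#' count_accessions(m)
#' @export
read_manifest <- function(path, dialect = manifest_dialect(),
                          host_vocabulary = default_host_vocabulary()) {
  if (!file.exists(path)) abort(paste0("manifest file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(new_manifest(tibble(
      location = character(), code = character(), lon = double(),
      lat = double(), date = character(), sample_type = character(),
      host = character(), accessions = list()
    )))
  }
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  get_col <- function(field) normalize_dashes(raw[[dialect[[field]]]])

  lon_chr <- get_col("lon")
  lat_chr <- get_col("lat")
  lon <- suppressWarnings(as.numeric(lon_chr))
  lat <- suppressWarnings(as.numeric(lat_chr))
  bad_coord <- which(is.na(lon) | is.na(lat) |
                       lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (length(bad_coord)) {
    abort(paste0("malformed or out-of-range coordinate in manifest row ",
                 bad_coord[1], " ('", lon_chr[bad_coord[1]], "', '",
                 lat_chr[bad_coord[1]], "')"))
  }

  m <- tibble(
    location = get_col("location"),
    code = get_col("code"),
    lon = lon,
    lat = lat,
    date = get_col("date"),
    sample_type = get_col("sample_type"),
    host = get_col("host"),
    accessions = split_accessions(get_col("accessions"))
  )
  validate_manifest(m, host_vocabulary = host_vocabulary)
  new_manifest(m)
}

new_manifest <- function(m) {
  class(m) <- c("sample_manifest", class(m))
  m
}

validate_manifest <- function(m, host_vocabulary = NULL) {
  dup <- m$code[duplicated(m$code)]
  if (length(dup)) {
    abort(paste0("duplicate sample code(s) in manifest: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad_type <- which(!m$sample_type %in% c("ES", "CI"))
  if (length(bad_type)) {
    abort(paste0("sample_type must be 'ES' or 'CI'; row ", bad_type[1],
                 " has '", m$sample_type[bad_type[1]], "'"))
  }
  n_acc <- lengths(m$accessions)
  if (any(n_acc == 0)) {
    abort(paste0("empty accession list in manifest row ",
                 which(n_acc == 0)[1]))
  }
  all_acc <- unlist(m$accessions)
  if (any(!nzchar(all_acc))) abort("empty accession identifier in manifest")
  dup_acc <- all_acc[duplicated(all_acc)]
  if (length(dup_acc)) {
    abort(paste0("duplicate accession(s) across manifest: ",
                 paste(unique(dup_acc), collapse = ", ")))
  }
  if (!is.null(host_vocabulary)) {
    unknown <- setdiff(unique(m$host), host_vocabulary)
    if (length(unknown)) {
      warn(paste0("host label(s) outside the configured vocabulary: ",
                  paste(unknown, collapse = ", ")))
    }
  }
  invisible(m)
}

#' Write a survey manifest
#'
#' Inverse of [read_manifest()]; writing then reading reproduces the manifest
#' exactly (accession lists are serialised semicolon-separated).
#'
#' @param manifest A `sample_manifest` tibble.
#' @param path Output TSV path.
#' @param dialect Column mapping, see [manifest_dialect()].
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, dialect = manifest_dialect()) {
  out <- tibble(
    !!dialect[["location"]] := manifest$location,
    !!dialect[["code"]] := manifest$code,
    !!dialect[["lon"]] := manifest$lon,
    !!dialect[["lat"]] := manifest$lat,
    !!dialect[["date"]] := manifest$date,
    !!dialect[["sample_type"]] := manifest$sample_type,
    !!dialect[["host"]] := manifest$host,
    !!dialect[["accessions"]] := vapply(manifest$accessions, paste,
                                        character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Count accessions in a manifest, optionally filtered
#'
#' Counts accession identifiers across manifest rows matching the given
#' dplyr-style filter conditions (all rows when no condition is given). The
#' count is additive over disjoint filters: summing counts over a partition of
#' the rows reproduces the unfiltered total.
#'
#' @param manifest A `sample_manifest` tibble.
#' @param ... Filter conditions evaluated in the manifest's columns, as in
#'   [dplyr::filter()], e.g. `host == "A. gracile"`.
#' @return Non-negative integer; 0 for an empty selection.
#' @examples
#' m <- read_manifest(system.file("extdata", "egg_capsule_survey.tsv",
#'                                package = "clonesurvey"))
#' count_accessions(m, host == "A. gracile")
#' @export
count_accessions <- function(manifest, ...) {
  rows <- dplyr::filter(as_tibble(manifest), ...)
  sum(lengths(rows$accessions))
}

#' Path to the bundled egg-capsule survey manifest
#'
#' The package ships a manifest transcribing the collection records of a
#' published multi-host egg-capsule survey: 29 amphibian-derived sampling
#' events plus three culture-collection strains, 129 accessions in all (126
#' amphibian-derived).
#'
#' @return File path to the TSV manifest.
#' @export
example_manifest_path <- function() {
  system.file("extdata", "egg_capsule_survey.tsv", package = "clonesurvey",
              mustWork = TRUE)
}
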