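#' Construct a spectra dataset
#'
#' A spectra dataset is a tibble with one row per compound and columns
#' `compound_id`, `name`, `smiles`, `ri`, `column_polarity`, a `peaks`
#' list-column of `(mz, intensity)` tibbles, the four taxonomy label columns
#' (`kingdom`, `superclass`, `class`, `subclass`), the seven property columns
#' (see [property_names()]), and a `metadata` list-column preserving unknown
#' MSP header lines. Two attributes travel with it: `provenance` (free text)
#' and `mz_range`, the global nominal m/z frame covering every record's peaks.
#'
#' @param records A data frame with at least `compound_id`, `name` and
#'   `peaks`; missing optional columns are added as `NA`/empty.
#' @param provenance Free-text origin of the data.
#' @param mz_range Optional integer length-2 global m/z frame. Defaults to
#'   the span of the nominal peak masses, widened to at least 35--600 u so
#'   matrices from different datasets share a frame.
#'
#' @return A tibble of class `spectra_dataset`.
#' @export
spectra_dataset <- function(records, provenance = "unspecified",
                            mz_range = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("compound_id", "name", "peaks") %in% names(records))) {
    abort("records must contain compound_id, name and peaks columns")
  }
  if (anyDuplicated(records$compound_id)) {
    abort("compound_id values must be unique")
  }
  if (!"smiles" %in% names(records)) records$smiles <- NA_character_
  if (!"ri" %in% names(records)) records$ri <- NA_real_
  if (!"column_polarity" %in% names(records)) {
    records$column_polarity <- "unknown"
  }
  for (lv in TAXONOMY_LEVELS) {
    if (!lv %in% names(records)) records[[lv]] <- NA_character_
  }
  for (pn in PROPERTY_NAMES) {
    if (!pn %in% names(records)) records[[pn]] <- NA_real_
  }
  if (!"metadata" %in% names(records)) {
    records$metadata <- replicate(nrow(records), list(), simplify = FALSE)
  }
  validate_peaks(records)
  if (is.null(mz_range)) {
    if (nrow(records) > 0) {
      masses <- unlist(lapply(records$peaks, function(p) nominal_mass(p$mz)))
      mz_range <- c(min(35L, min(masses)), max(600L, max(masses)))
    } else {
      mz_range <- c(35L, 600L)
    }
  }
  mz_range <- as.integer(mz_range)
  if (nrow(records) > 0) {
    masses <- unlist(lapply(records$peaks, function(p) nominal_mass(p$mz)))
    if (min(masses) < mz_range[1] || max(masses) > mz_range[2]) {
      abort("mz_range does not cover every record's peaks")
    }
  }
  ord <- c("compound_id", "name", "smiles", "ri", "column_polarity", "peaks",
           TAXONOMY_LEVELS, PROPERTY_NAMES, "metadata")
  records <- records[, c(ord, setdiff(names(records), ord))]
  structure(records,
            class = c("spectra_dataset", class(tibble::tibble())),
            provenance = provenance,
            mz_range = mz_range)
}

validate_peaks <- function(records) {
  for (i in seq_len(nrow(records))) {
    p <- records$peaks[[i]]
    if (is.null(p) || nrow(p) == 0) {
      abort(paste0("record ", records$compound_id[i], " has no peaks"))
    }
    if (any(p$mz <= 0) || any(p$intensity < 0) || !any(p$intensity > 0)) {
      abort(paste0("record ", records$compound_id[i],
                   " has invalid peak masses or intensities"))
    }
    if (is.unsorted(p$mz, strictly = TRUE)) {
      abort(paste0("record ", records$compound_id[i],
                   " peaks must be strictly increasing in m/z"))
    }
  }
  invisible(records)
}

#' Global m/z frame of a dataset
#' @param data A `spectra_dataset`.
#' @return Integer vector `c(mz_min, mz_max)`.
#' @export
mz_range <- function(data) attr(data, "mz_range", exact = TRUE)

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("# spectra_dataset:", nrow(x), "compounds, m/z frame",
      paste(mz_range(x), collapse = "-"),
      "u, provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

# Nominal (unit) mass: round-half-up of measured m/z, so 77.5 -> 78.
nominal_mass <- function(mz) as.integer(floor(mz + 0.5))
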