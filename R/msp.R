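#' Read a NIST-style MSP spectral library
#'
#' Parses MSP entries separated by blank lines. Each entry needs a `Name:`
#' field and a `Num Peaks:` count followed by the peak list; both
#' semicolon-separated (`"77 500; 152 999;"`) and whitespace-separated peak
#' lines are accepted. The retention index is taken from a
#' `Retention_index:` header line first, else from an `RI=` token inside
#' `Comments:`; when both are present and disagree the header (semi-polar)
#' value is kept and the conflict reported. Duplicate m/z within an entry
#' have their intensities summed. Unknown header lines are preserved
#' verbatim in the `metadata` list-column.
#'
#' @param path Path to an MSP file (UTF-8).
#' @param provenance Provenance string stored on the returned dataset.
#' @return A [spectra_dataset()] tibble, one row per entry.
#' @export
read_msp <- function(path, provenance = path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split into entries on runs of blank lines
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(blank & !c(FALSE, utils::head(blank, -1)))
  entries <- split(lines[!blank], grp[!blank])
  entries <- Filter(length, entries)
  records <- lapply(entries, parse_msp_entry, lines = lines)
  if (length(records) == 0) {
    return(spectra_dataset(tibble::tibble(compound_id = character(),
                                          name = character(),
                                          peaks = list()),
                           provenance = provenance))
  }
  spectra_dataset(dplyr::bind_rows(records), provenance = provenance)
}

parse_msp_entry <- function(entry, lines) {
  header_re <- "^([A-Za-z_#][A-Za-z0-9_# ]*):\\s*(.*)$"
  is_header <- grepl(header_re, entry)
  headers <- entry[is_header]
  keys <- tolower(gsub(" ", "_", sub(header_re, "\\1", headers)))
  vals <- sub(header_re, "\\2", headers)
  named <- stats::setNames(as.list(vals), keys)

  if (is.null(named$name)) abort("MSP entry without a Name field")
  nm <- named$name
  if (is.null(named$num_peaks)) {
    abort(paste0("MSP entry '", nm, "' has no Num Peaks field"))
  }
  n_declared <- suppressWarnings(as.integer(named$num_peaks))
  if (is.na(n_declared)) {
    abort(paste0("MSP entry '", nm, "': non-numeric Num Peaks"))
  }

  # peak lines: everything after the Num Peaks header
  np_idx <- which(keys == "num_peaks")
  peak_lines <- entry[!is_header]
  # also, anything following the Num Peaks line that looks numeric even if a
  # colon slipped in is not expected; peaks are the non-header lines.
  toks <- unlist(strsplit(paste(peak_lines, collapse = " "),
                          "[;,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  bad <- suppressWarnings(is.na(as.numeric(toks)))
  if (any(bad)) {
    ln <- which(lines %in% peak_lines[grepl(toks[bad][1], peak_lines,
                                            fixed = TRUE)])[1]
    abort(paste0("MSP entry '", nm, "': non-numeric peak token '",
                 toks[bad][1], "'", if (!is.na(ln)) paste0(" at line ", ln)))
  }
  num <- as.numeric(toks)
  if (length(num) %% 2 != 0 || length(num) / 2 != n_declared) {
    abort(paste0("MSP entry '", nm, "': declared ", n_declared,
                 " peaks but parsed ", floor(length(num) / 2)))
  }
  mz <- num[seq(1, length(num), by = 2)]
  intensity <- num[seq(2, length(num), by = 2)]
  # consolidate duplicate m/z, sort ascending
  agg <- rowsum(intensity, group = mz)
  peaks <- tibble::tibble(mz = as.numeric(rownames(agg)),
                          intensity = as.numeric(agg[, 1]))
  peaks <- peaks[order(peaks$mz), ]

  ri <- NA_real_
  polarity <- named$column_polarity %||% "unknown"
  ri_header <- suppressWarnings(as.numeric(named$retention_index))
  ri_comment <- NA_real_
  if (!is.null(named$comments)) {
    m <- regmatches(named$comments,
                    regexpr("RI=([0-9.]+)", named$comments))
    if (length(m) == 1) ri_comment <- as.numeric(sub("RI=", "", m))
  }
  if (length(ri_header) == 1 && !is.na(ri_header)) {
    ri <- ri_header
    if (!is.na(ri_comment) && ri_comment != ri_header) {
      inform(paste0("entry '", nm, "': semi-polar Retention_index ",
                    ri_header, " kept over Comments RI=", ri_comment))
    }
  } else if (!is.na(ri_comment)) {
    ri <- ri_comment
  }

  known <- c("name", "num_peaks", "retention_index", "comments", "smiles",
             "id", "column_polarity")
  extra <- named[setdiff(names(named), known)]

  tibble::tibble(
    compound_id = named$id %||% nm,
    name = nm,
    smiles = named$smiles %||% NA_character_,
    ri = ri,
    column_polarity = polarity,
    peaks = list(peaks),
    metadata = list(extra)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectra dataset to MSP
#'
#' Emits `Name`, `ID`, `SMILES`, `Retention_index`, `Column_polarity`, any
#' preserved metadata headers, `Num Peaks` and the whitespace-separated peak
#' list in ascending m/z. Files written here are re-read losslessly by
#' [read_msp()].
#'
#' @param data A `spectra_dataset` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(data, path) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) abort(paste0("cannot write ", path)))
  on.exit(close(con))
  for (i in seq_len(nrow(data))) {
    out <- c(paste0("Name: ", data$name[i]),
             paste0("ID: ", data$compound_id[i]))
    if (!is.na(data$smiles[i])) out <- c(out, paste0("SMILES: ", data$smiles[i]))
    if (!is.na(data$ri[i])) {
      out <- c(out, paste0("Retention_index: ", format(data$ri[i], digits = 12)))
    }
    pol <- if ("column_polarity" %in% names(data)) data$column_polarity[i] else "unknown"
    out <- c(out, paste0("Column_polarity: ", pol))
    meta <- if ("metadata" %in% names(data)) data$metadata[[i]] else list()
    for (k in names(meta)) {
      pretty <- gsub("_", " ", k)
      # restore canonical capitalization of the first letter only
      pretty <- paste0(toupper(substr(pretty, 1, 1)), substr(pretty, 2, nchar(pretty)))
      out <- c(out, paste0(gsub(" ", "_", pretty), ": ", meta[[k]]))
    }
    p <- data$peaks[[i]][order(data$peaks[[i]]$mz), ]
    out <- c(out, paste0("Num Peaks: ", nrow(p)),
             paste(format(p$mz, trim = TRUE, digits = 12),
                   format(p$intensity, trim = TRUE, digits = 12)),
             "")
    writeLines(out, con)
  }
  invisible(path)
}

#' Attach property and class-label tables to a dataset
#'
#' Left-joins per-compound property values and taxonomy labels onto the
#' dataset. Records without a table entry keep `NA`s; table rows whose
#' `compound_id` does not occur in the dataset are reported and ignored.
#' Peaks and retention indices are never altered.
#'
#' @param data A `spectra_dataset`.
#' @param properties Data frame or CSV path with `compound_id` plus any of
#'   the columns in [property_names()].
#' @param classes Data frame or CSV path with `compound_id` plus any of
#'   `kingdom`, `superclass`, `class`, `subclass`.
#' @return The dataset with merged columns.
#' @export
attach_annotations <- function(data, properties = NULL, classes = NULL) {
  stopifnot(inherits(data, "spectra_dataset"))
  prov <- attr(data, "provenance")
  rng <- mz_range(data)
  merge_one <- function(data, tbl, cols, what) {
    if (is.character(tbl)) tbl <- readr::read_csv(tbl, show_col_types = FALSE)
    tbl <- tibble::as_tibble(tbl)
    if (!"compound_id" %in% names(tbl)) {
      abort(paste0(what, " table must have a compound_id column"))
    }
    if (anyDuplicated(tbl$compound_id)) {
      abort(paste0("duplicate compound_id in ", what, " table: ",
                   tbl$compound_id[duplicated(tbl$compound_id)][1]))
    }
    unmatched <- setdiff(tbl$compound_id, data$compound_id)
    if (length(unmatched) > 0) {
      inform(paste0(length(unmatched), " ", what,
                    " rows have no matching compound and were ignored"))
    }
    use <- intersect(setdiff(names(tbl), "compound_id"), cols)
    matched <- 0L
    for (cl in use) {
      idx <- match(data$compound_id, tbl$compound_id)
      new <- tbl[[cl]][idx]
      hit <- !is.na(new)
      data[[cl]][hit] <- new[hit]
      matched <- matched + sum(hit)
    }
    inform(paste0("attached ", matched, " ", what, " values over ",
                  length(use), " columns"))
    data
  }
  if (!is.null(properties)) {
    data <- merge_one(data, properties, PROPERTY_NAMES, "property")
  }
  if (!is.null(classes)) {
    data <- merge_one(data, classes, TAXONOMY_LEVELS, "class")
  }
  spectra_dataset(data, provenance = prov, mz_range = rng)
}
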