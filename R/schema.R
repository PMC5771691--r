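#' Controlled vocabularies for animal-level measurement records
#'
#' The tabular data model is one row per quantitative observation on one
#' animal: which animal, its genotype and sex, its age in months (postnatal
#' day 0 is encoded as age 0), which brain region was measured, what kind of
#' measure it is, the value, and the units. Genotypes are restricted to
#' wild-type (`WT`) and mutant (`MUT`) because the study design is a
#' two-genotype cross-sectional comparison.
#'
#' @format Character vectors of admissible labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
genotype_levels <- c("WT", "MUT")

#' @rdname vocabularies
#' @export
sex_levels <- c("M", "F")

#' @rdname vocabularies
#' @export
region_levels <- c(
  "whole_brain", "cortex", "cerebellum", "cerebellum_midbrain",
  "striatum", "hippocampus", "hippocampus_CA", "hippocampus_DG",
  "spinal_cord"
)

#' @rdname vocabularies
#' @export
measure_kind_levels <- c(
  "gross_area", "tissue_area", "thickness", "width",
  "pc_density", "signal_fraction", "cell_count", "puncta_area"
)

# Canonical units per measure kind, with accepted ASCII/unicode spellings.
.unit_table <- list(
  gross_area      = c("cm^2", "cm2", "cm²"),
  tissue_area     = c("mm^2", "mm2", "mm²"),
  thickness       = c("mm"),
  width           = c("mm"),
  pc_density      = c("cells/100 um", "cells/100um", "cells/100 µm"),
  signal_fraction = c("%", "percent"),
  cell_count      = c("count", "cells"),
  puncta_area     = c("um^2", "um2", "µm²")
)

#' Canonical units for a measure kind
#'
#' @param measure_kind One of [measure_kind_levels].
#' @return The canonical units string (first accepted spelling).
#' @export
#' @examples
#' canonical_units("gross_area")
canonical_units <- function(measure_kind) {
  measure_kind <- match.arg(measure_kind, measure_kind_levels)
  .unit_table[[measure_kind]][1]
}

.measurement_columns <- c(
  "subject_id", "genotype", "sex", "age_months",
  "region", "measure_kind", "value", "units"
)

.is_region <- function(x) {
  x %in% region_levels | grepl("^other:.+", x)
}

#' Validate a table of animal-level measurement records
#'
#' Checks every row of a candidate measurement table against the data model:
#' declared columns present, genotype/sex/region/measure-kind labels drawn
#' from the controlled vocabularies, ages non-negative, values finite, and
#' the units consistent with the measure kind (gross areas in cm^2, histology
#' areas in mm^2, thickness and width in mm, and so on).
#'
#' @param data A data frame.
#' @param line_offset Added to row indices in error messages, so errors from
#'   a file can point at physical line numbers (the header is line 1).
#' @return `data` as a tibble, with `units` normalised to canonical
#'   spellings, invisibly usable in a pipe. Throws a single error listing
#'   every offending row if any row fails validation.
#' @export
validate_measurements <- function(data, line_offset = 0L) {
  missing_cols <- setdiff(.measurement_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Measurement table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- as_tibble(data)
  n <- nrow(data)
  problems <- character(0)
  note <- function(rows, msg, token = NULL) {
    if (length(rows) == 0) return()
    lines <- rows + line_offset
    tok <- if (is.null(token)) "" else paste0(" (offending token: ",
      paste(unique(token), collapse = ", "), ")")
    problems <<- c(problems, paste0(
      "line ", paste(lines, collapse = ", "), ": ", msg, tok
    ))
  }

  bad <- which(!data$genotype %in% genotype_levels)
  note(bad, "unknown genotype label", data$genotype[bad])
  bad <- which(!data$sex %in% sex_levels)
  note(bad, "unknown sex label", data$sex[bad])
  bad <- which(!.is_region(data$region))
  note(bad, "unknown region label", data$region[bad])
  bad <- which(!data$measure_kind %in% measure_kind_levels)
  note(bad, "unknown measure_kind label", data$measure_kind[bad])

  if (!is.numeric(data$age_months)) {
    note(which(is.na(suppressWarnings(as.numeric(data$age_months)))),
      "unparseable age_months", data$age_months)
    data$age_months <- suppressWarnings(as.numeric(data$age_months))
  }
  bad <- which(is.na(data$age_months) | data$age_months < 0)
  note(bad, "age_months must be a non-negative number")

  if (!is.numeric(data$value)) {
    note(which(is.na(suppressWarnings(as.numeric(data$value)))),
      "unparseable value", data$value)
    data$value <- suppressWarnings(as.numeric(data$value))
  }
  bad <- which(!is.finite(data$value))
  note(bad, "value must be finite")

  known_kind <- data$measure_kind %in% measure_kind_levels
  expected <- lapply(data$measure_kind[known_kind], function(k) .unit_table[[k]])
  ok_units <- mapply(function(u, exp) u %in% exp,
    data$units[known_kind], expected)
  if (length(ok_units) > 0) {
    bad <- which(known_kind)[!ok_units]
    note(bad, "units inconsistent with measure_kind", data$units[bad])
  }

  if (length(problems) > 0) {
    abort(paste0(
      "Invalid measurement record(s):\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }

  # normalise unit spellings to canonical form
  data$units <- vapply(seq_len(n), function(i) {
    canonical_units(data$measure_kind[i])
  }, character(1))
  data
}

#' Read animal-level measurement records from a delimited file
#'
#' Reads a TSV or CSV file whose header names the measurement-record columns
#' (`subject_id genotype sex age_months region measure_kind value units`),
#' then validates every row. The delimiter is auto-detected from the file
#' extension (`.csv` means comma, anything else tab) and can be overridden.
#'
#' @param path Path to an existing file.
#' @param delim Field delimiter; `NULL` (default) auto-detects from the
#'   extension.
#' @return A validated tibble of measurement records.
#' @seealso [validate_measurements()], [write_table()]
#' @export
read_measurements <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File does not exist: ", path))
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  # header occupies line 1; data row i sits on physical line i + 1
  validate_measurements(data, line_offset = 1L)
}

#' Write a result table to TSV, CSV, or JSON
#'
#' Writes any data frame (measurement records, summary cells, coefficient
#' tables, test results) as a UTF-8 text file with a header row. Numeric
#' columns are rendered with a configurable number of significant digits.
#' JSON output mirrors the column names, one object per row.
#'
#' @param data A data frame.
#' @param path Output path.
#' @param format `"tsv"`, `"csv"`, or `"json"`; `NULL` auto-detects from the
#'   extension.
#' @param digits Significant digits used to render numeric fields
#'   (default 6).
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, format = NULL, digits = 6) {
  data <- as_tibble(data)
  format <- format %||% {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tsv", "csv", "json")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "json"))
  if (format == "json") {
    jsonlite::write_json(data, path, dataframe = "rows", digits = digits,
      pretty = TRUE, na = "null")
    return(invisible(path))
  }
  out <- data
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
  })
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
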