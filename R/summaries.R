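#' Reduce measurement records to group-summary cells
#'
#' Collapses animal-level records into one row per group: arithmetic mean,
#' standard error of the mean (sample SD with the n - 1 denominator, divided
#' by sqrt(n)), and the record count. This is the reduction behind published
#' "Mean / SEM / n" tables, so the rest of the package can run either from
#' raw records or from printed summaries.
#'
#' Cells with a single record get `sem = 0` and are flagged
#' (`sem_undefined = TRUE`) with a warning, since a sample SD is undefined
#' at n = 1.
#'
#' @param records A data frame of measurement records (see
#'   [validate_measurements()]); only the grouping columns and `value` are
#'   required.
#' @param keys Character vector of grouping columns. Defaults to the
#'   genotype x age x region x measure-kind cell.
#' @return A tibble with the key columns plus `mean`, `sem`, `n`,
#'   `sem_undefined`, ordered by key. The reduction is invariant to the
#'   input row order.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   genotype = "WT", age_months = 23, region = "cerebellum",
#'   measure_kind = "gross_area", value = c(1, 2, 3)
#' )
#' summarize_groups(recs)
summarize_groups <- function(records,
                             keys = c("genotype", "age_months",
                                      "region", "measure_kind")) {
  records <- as_tibble(records)
  missing_cols <- setdiff(c(keys, "value"), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack column(s): ",
      paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    abort("records is empty; each emitted cell needs at least one record")
  }
  cells <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_undefined = .data$n == 1L) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  if (any(cells$sem_undefined)) {
    warn(paste0(sum(cells$sem_undefined),
      " cell(s) have n = 1; their SEM is reported as 0 and flagged"))
  }
  cells
}

#' Construct a single group-summary cell
#'
#' Convenience constructor for a one-row (mean, SEM, n) cell, the unit of
#' input for the summary-statistic tests and the atrophy calculations.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean; must be non-negative, and 0 is
#'   only admissible when `n = 1` or the underlying values were identical.
#' @param n Number of animals in the group (integer >= 1).
#' @param ... Optional key columns (e.g. `genotype = "WT"`).
#' @return A one-row tibble.
#' @export
#' @examples
#' summary_cell(0.2483, 0.0078, 4, genotype = "WT", region = "cerebellum")
summary_cell <- function(mean, sem, n, ...) {
  stopifnot(is.numeric(mean), is.numeric(sem), sem >= 0, n >= 1)
  tibble(..., mean = mean, sem = sem, n = as.integer(n))
}

# Reduce either a raw numeric vector or a one-row summary cell to the
# sufficient statistics (mean, sd, n). Group SD is reconstructed from a
# summary as SEM * sqrt(n).
.suff_stats <- function(x, arg = "x") {
  if (is.numeric(x) && is.null(dim(x))) {
    n <- length(x)
    list(mean = mean(x), sd = if (n > 1) sd(x) else 0, n = n)
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1 || !all(c("mean", "sem", "n") %in% names(x))) {
      abort(paste0(arg,
        " must be a numeric vector or a one-row tibble with mean, sem, n"))
    }
    if (x$sem < 0) abort(paste0(arg, ": sem must be non-negative"))
    list(mean = x$mean, sd = x$sem * sqrt(x$n), n = as.integer(x$n))
  } else {
    abort(paste0(arg,
      " must be a numeric vector or a one-row tibble with mean, sem, n"))
  }
}

#' Realize raw values that reproduce a (mean, SD, n) summary exactly
#'
#' Produces `n` values whose sample mean and sample SD (n - 1 denominator)
#' equal the requested summary to machine precision. Used to run raw-data
#' routines from published summary cells: every classical statistic computed
#' here depends on the data only through these sufficient statistics, so any
#' exact realization gives the same answer.
#'
#' @param mean Target sample mean.
#' @param sd Target sample standard deviation (ignored when `n = 1`).
#' @param n Number of values.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- realize_values(5, 1.2, 4)
#' c(mean(x), sd(x))
realize_values <- function(mean, sd, n) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (n == 1) return(mean)
  z <- seq_len(n) - (n + 1) / 2
  z <- z / sd(z)
  mean + sd * z
}
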