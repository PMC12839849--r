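
SUBTYPE_LEVELS <- c("CMS1", "CMS2", "CMS3", "CMS4", "NOLBL")

#' Validate a clinical/survival table
#'
#' @param df Data frame with columns `sample_id`, `time`, `event`, and
#'   optionally `subtype` (one of CMS1..CMS4 or NOLBL) and `cohort`.
#' @param time_unit Declared unit of the `time` column (`"days"`, `"months"`
#'   or `"years"`); survival inputs never carry an implicit unit.
#' @return A `clinical_tbl` tibble with the unit stored as attribute
#'   `time_unit`.
#' @export
as_clinical_table <- function(df, time_unit = c("months", "days", "years")) {
  time_unit <- match.arg(time_unit)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(glue("Clinical table is missing column(s): {paste(miss, collapse = ', ')}."))
  }
  df <- as_tibble(df)
  stop_if_duplicated(df$sample_id, "sample")
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time <= 0)) {
    bad <- df$sample_id[which(!is.finite(df$time) | df$time <= 0)[1L]]
    abort(glue("Survival time must be a positive number (sample '{bad}')."))
  }
  if (anyNA(df$event) || !all(df$event %in% c(0, 1))) {
    bad <- df$sample_id[which(!(df$event %in% c(0, 1)))[1L]]
    abort(glue("Event indicator must be 0 or 1 (sample '{bad}')."))
  }
  df$event <- as.integer(df$event)
  if ("subtype" %in% names(df)) {
    ok <- is.na(df$subtype) | df$subtype %in% SUBTYPE_LEVELS
    if (!all(ok)) {
      abort(glue(
        "Unknown subtype label '{df$subtype[which(!ok)[1L]]}' ",
        "(expected CMS1..CMS4 or NOLBL)."
      ))
    }
  }
  structure(df, time_unit = time_unit,
            class = c("clinical_tbl", class(df)))
}

#' Read a clinical/survival CSV
#'
#' Rows with missing time or event are excluded (not errors) and counted in
#' attribute `n_excluded`, mirroring the usual exclusion of samples with
#' incomplete survival information. A non-positive time or an event value
#' outside {0, 1} on a retained row is a hard error.
#'
#' @param path CSV path.
#' @param sample_col,time_col,event_col,subtype_col,cohort_col Column
#'   mapping; `subtype_col`/`cohort_col` may be absent from the file.
#' @inheritParams as_clinical_table
#' @return A `clinical_tbl` tibble.
#' @export
read_clinical <- function(path,
                          time_unit = c("months", "days", "years"),
                          sample_col = "sample_id", time_col = "time",
                          event_col = "event", subtype_col = "subtype",
                          cohort_col = "cohort") {
  time_unit <- match.arg(time_unit)
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  for (col in c(sample_col, time_col, event_col)) {
    if (!col %in% names(raw)) abort(glue("Clinical CSV lacks column '{col}'."))
  }
  df <- tibble(
    sample_id = as.character(raw[[sample_col]]),
    time = suppressWarnings(as.numeric(raw[[time_col]])),
    event = suppressWarnings(as.numeric(raw[[event_col]]))
  )
  if (subtype_col %in% names(raw)) df$subtype <- as.character(raw[[subtype_col]])
  if (cohort_col %in% names(raw)) df$cohort <- as.character(raw[[cohort_col]])
  keep <- !is.na(df$time) & !is.na(df$event)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    inform(glue("Excluded {n_excluded} sample(s) with incomplete survival information."))
  }
  out <- as_clinical_table(df[keep, , drop = FALSE], time_unit = time_unit)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a clinical table to CSV
#'
#' @param clinical A `clinical_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  stopifnot(inherits(clinical, "clinical_tbl"))
  readr::write_csv(as_tibble(clinical), path, progress = FALSE)
  invisible(path)
}
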