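# Ingestion and validation of multi-reader annotation records.
#
# One record = one reader's assessment of one ROI: a four-category ROI
# label, a percent tumor-associated stroma, and an sTILs density. The two
# percentages are continuous in [0, 100] and may be absent (empty CSV
# field). A density only makes sense under an evaluable label; historical
# pilot data predate enforcement of that rule, which is why validation has
# a lenient mode that flags rather than rejects such rows.

annotation_columns <- c(
  "roi_id", "reader_id", "cohort", "roi_label", "percent_stroma", "stils_density"
)

#' Validate a table of annotation records
#'
#' Checks a data frame of reader annotations against the record contract:
#' required columns present; `cohort` one of `"crowd"`/`"expert"`;
#' `roi_label` in the four-label vocabulary (any dialect accepted by
#' [as_roi_label()]); percentages within \[0, 100\]; `(roi_id, reader_id)`
#' unique; and — the evaluability rule — no density recorded under a
#' non-evaluable label.
#'
#' Violations are classified by severity. `"error"` rows (bad label or
#' cohort, out-of-range percentage, duplicate key) are excluded from the
#' accepted records; `"flag"` rows (density under a non-evaluable label)
#' are retained but reported. Every input row lands either in the accepted
#' records or in the error part of the report — never both, never neither.
#' In strict mode any violation, including flags, aborts with an error.
#'
#' @param x Data frame with columns `roi_id`, `reader_id`, `cohort`,
#'   `roi_label`, `percent_stroma`, `stils_density`.
#' @param strict If `TRUE`, any violation is an error. Default `FALSE`
#'   (lenient), suited to historical pilot data.
#' @return A tibble of accepted records (canonical label factor, character
#'   ids, numeric percentages) with the validation report attached as
#'   attribute `"report"`; retrieve it with [validation_report()].
#' @seealso [read_annotations()], [validation_report()]
#' @export
validate_annotations <- function(x, strict = FALSE) {
  missing_cols <- setdiff(annotation_columns, names(x))
  if (length(missing_cols) > 0) {
    stop(
      "annotation table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- tibble::as_tibble(x)[annotation_columns]
  x$roi_id <- as.character(x$roi_id)
  x$reader_id <- as.character(x$reader_id)
  x$cohort <- tolower(trimws(as.character(x$cohort)))
  x$percent_stroma <- as.numeric(x$percent_stroma)
  x$stils_density <- as.numeric(x$stils_density)
  label <- as_roi_label(x$roi_label, strict = FALSE)

  flag_row <- function(rows, rule, severity) {
    tibble::tibble(
      row = rows,
      roi_id = x$roi_id[rows],
      reader_id = x$reader_id[rows],
      rule = rule,
      severity = severity
    )
  }
  report <- list()

  bad_label <- which(!is.na(x$roi_label) & is.na(label) | is.na(x$roi_label))
  if (length(bad_label) > 0) {
    report <- c(report, list(flag_row(bad_label, "unrecognized_roi_label", "error")))
  }
  bad_cohort <- which(!x$cohort %in% c("crowd", "expert"))
  if (length(bad_cohort) > 0) {
    report <- c(report, list(flag_row(bad_cohort, "unrecognized_cohort", "error")))
  }
  out_of_range <- function(v) which(!is.na(v) & (v < 0 | v > 100))
  bad_stroma <- out_of_range(x$percent_stroma)
  if (length(bad_stroma) > 0) {
    report <- c(report, list(flag_row(bad_stroma, "percent_stroma_out_of_range", "error")))
  }
  bad_density <- out_of_range(x$stils_density)
  if (length(bad_density) > 0) {
    report <- c(report, list(flag_row(bad_density, "stils_density_out_of_range", "error")))
  }
  dup <- which(duplicated(x[c("roi_id", "reader_id")]))
  if (length(dup) > 0) {
    report <- c(report, list(flag_row(dup, "duplicate_roi_reader_pair", "error")))
  }
  noneval_density <- which(
    !is.na(label) & !(label %in% roi_labels()[1:2]) & !is.na(x$stils_density)
  )
  if (length(noneval_density) > 0) {
    report <- c(report, list(
      flag_row(noneval_density, "density_under_non_evaluable_label", if (strict) "error" else "flag")
    ))
  }

  report <- if (length(report) > 0) {
    dplyr::arrange(dplyr::bind_rows(report), .data$row)
  } else {
    tibble::tibble(
      row = integer(), roi_id = character(), reader_id = character(),
      rule = character(), severity = character()
    )
  }

  if (strict && nrow(report) > 0) {
    stop(
      "annotation validation failed (strict mode): ",
      nrow(report), " violation(s); first: row ", report$row[1],
      " [", report$rule[1], "]",
      call. = FALSE
    )
  }

  drop <- unique(report$row[report$severity == "error"])
  accepted <- x
  accepted$roi_label <- label
  if (length(drop) > 0) accepted <- accepted[-drop, ]
  attr(accepted, "report") <- report
  accepted
}

#' Retrieve the validation report attached to accepted annotations
#'
#' @param x A tibble returned by [validate_annotations()] or
#'   [read_annotations()].
#' @return Tibble with columns `row` (input row number), `roi_id`,
#'   `reader_id`, `rule`, `severity` (`"error"` rows were dropped,
#'   `"flag"` rows retained). Zero rows when the input was clean.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "report", exact = TRUE)
  if (is.null(rep)) {
    stop("no validation report attached; run validate_annotations() first", call. = FALSE)
  }
  rep
}

#' Read annotation records from CSV
#'
#' Expects a UTF-8 CSV with header columns `roi_id`, `reader_id`,
#' `cohort`, `roi_label`, `percent_stroma`, `stils_density`; an empty
#' field encodes an absent percentage. Rows are validated on ingest (see
#' [validate_annotations()] for the rules and the strict/lenient split).
#'
#' @param path Path to the CSV file.
#' @param strict Passed to [validate_annotations()]. Use `TRUE` for newly
#'   generated data, `FALSE` (default) for historical pilot data collected
#'   before the evaluability rule was enforced.
#' @return Tibble of accepted records with a `"report"` attribute.
#' @export
read_annotations <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"),
    progress = FALSE
  )
  validate_annotations(raw, strict = strict)
}

#' Write annotation records to CSV
#'
#' Inverse of [read_annotations()] on valid collections: absent
#' percentages become empty fields, labels are written canonically.
#'
#' @param x Data frame of annotation records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  out <- tibble::as_tibble(x)[annotation_columns]
  out$roi_label <- as.character(as_roi_label(out$roi_label))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a validation report as JSON lines
#'
#' One JSON object per reported row, suitable for machine consumption by
#' audit tooling.
#'
#' @param report Tibble from [validation_report()].
#' @param path Output path, or `""` to print to stdout.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path = "") {
  lines <- vapply(
    seq_len(nrow(report)),
    function(i) as.character(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE)),
    character(1)
  )
  if (identical(path, "")) writeLines(lines) else writeLines(lines, path)
  invisible(path)
}
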