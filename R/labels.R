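# Four-category ROI label vocabulary and its evaluability semantics.

#' Canonical ROI label vocabulary
#'
#' Each annotated region of interest (ROI) carries one of four tissue
#' labels. The first two describe tissue in which tumor-associated stroma
#' (and hence stromal TILs) can exist; the last two describe tissue with no
#' tumor-associated stroma, where an sTILs density is undefined. The order
#' returned here is the canonical order used everywhere in the package:
#' for factor levels, for listing tied majority labels, and for the columns
#' of label-count tables.
#'
#' @return Character vector of the four admissible labels, in canonical
#'   order.
#' @examples
#' roi_labels()
#' @export
roi_labels <- function() {
  c(
    "Intra-Tumoral Stroma",
    "Invasive Margin",
    "Tumor with No Intervening Stroma",
    "Other Regions"
  )
}

#' Parse free-text ROI labels into the canonical factor
#'
#' Matching is case-insensitive after whitespace normalization (leading and
#' trailing whitespace stripped, internal runs collapsed to single spaces),
#' so dialects such as `"intra-tumoral  stroma"` are accepted and stored
#' canonically.
#'
#' @param x Character (or factor) vector of label text.
#' @param strict If `TRUE` (default), any unrecognized value is an error;
#'   if `FALSE`, unrecognized values become `NA`.
#' @return Factor with levels `roi_labels()`.
#' @examples
#' as_roi_label(c("other regions", "INVASIVE MARGIN"))
#' @export
as_roi_label <- function(x, strict = TRUE) {
  x <- as.character(x)
  norm <- tolower(gsub("\\s+", " ", trimws(x)))
  idx <- match(norm, tolower(roi_labels()))
  if (strict && anyNA(idx[!is.na(x)])) {
    bad <- unique(x[is.na(idx) & !is.na(x)])
    stop(
      "unrecognized ROI label(s): ",
      paste(sQuote(bad), collapse = ", "),
      "; admissible labels are: ",
      paste(sQuote(roi_labels()), collapse = ", "),
      call. = FALSE
    )
  }
  factor(roi_labels()[idx], levels = roi_labels())
}

#' Is an ROI label evaluable for sTILs?
#'
#' "Intra-Tumoral Stroma" and "Invasive Margin" mark tissue containing
#' tumor-associated stroma, where an sTILs density is defined; "Tumor with
#' No Intervening Stroma" and "Other Regions" contain none, so no density
#' can be scored there. This binary reading of the four-category label is
#' also the planned replacement vocabulary ("Evaluable for sTILs" /
#' "Not evaluable for sTILs") for future data collection.
#'
#' @param label Character or factor vector of ROI labels (canonical or any
#'   dialect accepted by [as_roi_label()]).
#' @return Logical vector: `TRUE` where the label is evaluable for sTILs.
#' @examples
#' label_is_evaluable(c("Invasive Margin", "Other Regions"))
#' @export
label_is_evaluable <- function(label) {
  lab <- as_roi_label(label, strict = TRUE)
  lab %in% roi_labels()[1:2]
}

#' Binarize an ROI label to its evaluability class
#'
#' @inheritParams label_is_evaluable
#' @return Factor with levels `"Evaluable for sTILs"`,
#'   `"Not evaluable for sTILs"`.
#' @examples
#' binarize_label("Tumor with No Intervening Stroma")
#' @export
binarize_label <- function(label) {
  factor(
    ifelse(label_is_evaluable(label), "Evaluable for sTILs", "Not evaluable for sTILs"),
    levels = c("Evaluable for sTILs", "Not evaluable for sTILs")
  )
}
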