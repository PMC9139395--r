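# Area-ratio definitions behind the two percentage data elements.

check_areas <- function(roi_area, stroma_area, tils_area) {
  n <- max(length(roi_area), length(stroma_area), length(tils_area))
  roi_area <- rep_len(roi_area, n)
  stroma_area <- rep_len(stroma_area, n)
  tils_area <- rep_len(tils_area, n)
  if (any(roi_area < 0 | stroma_area < 0 | tils_area < 0, na.rm = TRUE)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  if (any(stroma_area > roi_area, na.rm = TRUE)) {
    stop("stroma_area cannot exceed roi_area", call. = FALSE)
  }
  if (any(tils_area > stroma_area, na.rm = TRUE)) {
    stop("tils_area cannot exceed stroma_area", call. = FALSE)
  }
  list(roi = roi_area, stroma = stroma_area, tils = tils_area)
}

#' Percent tumor-associated stroma of an ROI
#'
#' The fraction of the entire ROI area (including empty space, vessel
#' lumens, adipose tissue) covered by tumor-associated stroma, expressed
#' as a percentage:
#' \deqn{100 \cdot \mathrm{stroma\ area} / \mathrm{ROI\ area}.}
#' Areas may be in any consistent unit (e.g. square micrometres).
#'
#' @param roi_area Total ROI area; must be positive.
#' @param stroma_area Tumor-associated stroma area within the ROI.
#' @param tils_area TILs area (accepted for interface symmetry with
#'   [compute_stils_density()]; must not exceed `stroma_area`).
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' compute_percent_stroma(roi_area = 1, stroma_area = 0.25)
#' @export
compute_percent_stroma <- function(roi_area, stroma_area, tils_area = 0) {
  a <- check_areas(roi_area, stroma_area, tils_area)
  if (any(a$roi == 0, na.rm = TRUE)) {
    stop("roi_area is zero: percent stroma is undefined", call. = FALSE)
  }
  a$stroma / a$roi * 100
}

#' sTILs density of an ROI
#'
#' The fraction of the tumor-associated stroma area occupied by
#' tumor-infiltrating lymphocytes (lymphocytes and plasma cells only),
#' expressed as a percentage:
#' \deqn{100 \cdot \mathrm{TILs\ area} / \mathrm{stroma\ area}.}
#' When an ROI contains no tumor-associated stroma the density is
#' undefined — there is nowhere for stromal TILs to live — and this
#' function errors rather than returning 0.
#'
#' @param stroma_area Tumor-associated stroma area; must be positive.
#' @param tils_area TILs area within the stroma.
#' @param roi_area Optional total ROI area, used only to validate that
#'   `stroma_area` does not exceed it.
#' @return Numeric vector of percentages in \[0, 100\].
#' @examples
#' compute_stils_density(stroma_area = 0.5, tils_area = 0.25)
#' @export
compute_stils_density <- function(stroma_area, tils_area, roi_area = Inf) {
  a <- check_areas(roi_area, stroma_area, tils_area)
  if (any(a$stroma == 0, na.rm = TRUE)) {
    stop(
      "stroma_area is zero: no tumor-associated stroma, sTILs density undefined",
      call. = FALSE
    )
  }
  a$tils / a$stroma * 100
}
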