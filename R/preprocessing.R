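stop_empty_segmentation <- function(msg) {
  stop(errorCondition(msg, class = c("thermotan_empty_segmentation",
                                     "error", "condition")))
}

#' Threshold segmentation of a temperature grid
#'
#' Removes (masks out) every valid cell with a temperature strictly below
#' `threshold`, the standard way of separating the body from the cooler
#' ambient background in a thermogram. Cells at exactly the threshold are
#' kept; no surviving value is modified, so the operation is idempotent.
#'
#' @param grid a [thermogram].
#' @param threshold segmentation threshold in degC (default 29).
#' @return The segmented [thermogram].
#' @export
threshold_segment <- function(grid, threshold = 29) {
  stopifnot(inherits(grid, "thermogram"), is.numeric(threshold))
  mask <- grid$mask & grid$values >= threshold
  mask[is.na(mask)] <- FALSE
  if (!any(mask))
    stop_empty_segmentation(sprintf(
      "segmentation at %.2f degC leaves no valid cells", threshold))
  thermogram(grid$values, mask = mask, meta = grid$meta)
}

#' Breast region of interest
#'
#' A temperature grid restricted to one breast, tagged with its laterality
#' (image side) and its diagnostic role in the affected/healthy pair.
#'
#' @param grid a [thermogram] with at least one valid cell.
#' @param laterality `"left"` or `"right"` (image coordinates).
#' @param role `"affected"`, `"healthy"`, or `NA` before role assignment.
#' @return An object of class `"breast_roi"`.
#' @export
breast_roi <- function(grid, laterality = c("left", "right"), role = NA) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(grid, "thermogram"))
  if (!any(grid$mask))
    stop_empty_segmentation("breast ROI has no valid cells")
  if (!is.na(role)) role <- match.arg(role, c("affected", "healthy"))
  structure(list(grid = grid, laterality = laterality, role = role),
            class = "breast_roi")
}

#' @export
print.breast_roi <- function(x, ...) {
  cat(sprintf("<breast ROI: %s, role=%s>\n", x$laterality,
              if (is.na(x$role)) "unassigned" else x$role))
  print(x$grid)
  invisible(x)
}

#' Split a thermogram into left and right breast ROIs
#'
#' Splits at the vertical midline: the left ROI takes columns `1..floor(W/2)`
#' and the right ROI the remainder. Laterality refers to image left/right.
#' Per-breast grids produced by the synthetic cohort generator bypass this
#' operation.
#'
#' @param grid a [thermogram] of width >= 2.
#' @return A list with `breast_roi` elements `left` and `right`.
#' @export
split_bilateral <- function(grid) {
  stopifnot(inherits(grid, "thermogram"))
  w <- ncol(grid$values)
  half <- w %/% 2L
  take <- function(cols, lat) {
    g <- thermogram(grid$values[, cols, drop = FALSE],
                    mask = grid$mask[, cols, drop = FALSE],
                    meta = c(grid$meta, list(laterality = lat)))
    if (!any(g$mask))
      stop_empty_segmentation(sprintf("%s half has no valid cells", lat))
    breast_roi(g, lat)
  }
  list(left = take(seq_len(half), "left"),
       right = take((half + 1L):w, "right"))
}

#' Assign affected/healthy roles to a breast pair
#'
#' For a sick patient the breast named by `record$affected_side` takes the
#' affected role. For a tumour-free patient the convention is fixed: the
#' left breast is treated as affected and the right as healthy, so that the
#' bilateral difference factors are defined for every patient.
#'
#' @param left,right `breast_roi` objects for the two sides.
#' @param record patient record (list or one-row data.frame with `diagnosis`
#'   and `affected_side`).
#' @return A list with elements `affected` and `healthy`, each a
#'   `breast_roi` with its role filled in.
#' @export
assign_roles <- function(left, right, record) {
  stopifnot(inherits(left, "breast_roi"), inherits(right, "breast_roi"))
  diagnosis <- as.integer(record$diagnosis)
  side <- as.character(record$affected_side)
  if (diagnosis == 1L) {
    if (!side %in% c("left", "right"))
      stop("inconsistent record: diagnosis 1 with affected_side '", side, "'",
           call. = FALSE)
    aff_side <- side
  } else {
    aff_side <- "left"
  }
  set_role <- function(roi, role) { roi$role <- role; roi }
  if (aff_side == "left")
    list(affected = set_role(left, "affected"),
         healthy = set_role(right, "healthy"))
  else
    list(affected = set_role(right, "affected"),
         healthy = set_role(left, "healthy"))
}
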