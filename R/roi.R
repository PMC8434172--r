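# Region-of-interest extraction around the segmented epidermis.
#
# Five modes crop the image axially relative to the epidermis band and zero
# out anatomically irrelevant ("avoided") pixels:
#   mode 0 - no crop, no zeroing (original image);
#   mode 1 - remove rows more than 30 px above the top epidermis pixel;
#   mode 2 - remove rows more than 1 mm above the top epidermis pixel;
#   mode 3 - as mode 1, plus remove rows more than 2 mm below the bottom
#            epidermis pixel;
#   mode 4 - as mode 2, plus the same 2 mm lower crop.
# In modes 1-4, retained pixels whose skin-layer-map value is -1 are set
# to 0.

#' Specify an ROI extraction mode
#'
#' @param mode integer 0-4, see Details in [extract_roi()].
#' @param upper_margin_px pixel margin above the epidermis (modes 1 and 3).
#' @param upper_margin_mm mm margin above the epidermis (modes 2 and 4).
#' @param lower_margin_mm mm margin below the epidermis (modes 3 and 4).
#' @param zero_avoided set avoided (SLM = -1) pixels to 0 (modes 1-4).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(mode, upper_margin_px = 30L, upper_margin_mm = 1.0,
                     lower_margin_mm = 2.0, zero_avoided = mode != 0L) {
  mode <- as.integer(mode)
  stopifnot(mode %in% 0:4, upper_margin_px > 0, upper_margin_mm > 0,
            lower_margin_mm > 0)
  if (mode == 0L && zero_avoided)
    stop("mode 0 is a pure passthrough; zero_avoided must be FALSE")
  structure(list(mode = mode, upper_margin_px = as.integer(upper_margin_px),
                 upper_margin_mm = upper_margin_mm,
                 lower_margin_mm = lower_margin_mm,
                 zero_avoided = zero_avoided),
            class = "roi_spec")
}

#' Extract the ROI around the epidermis
#'
#' Crops the image rows according to the ROI mode (see [roi_spec()]) and, in
#' modes 1-4, zeroes every retained pixel whose SLM value is -1. "Top" and
#' "bottom" epidermis pixels are the global minimum and maximum epidermis
#' rows over all columns, so crops are rectangular. Millimetre margins are
#' converted to pixels through the axial resolution, rounded to the nearest
#' integer. Crop bounds outside the image are clamped to the image.
#'
#' @param image numeric matrix.
#' @param mask epidermis mask (logical/0-1 matrix, same size, non-empty).
#' @param slm skin layer map from [build_slm()], same size.
#' @param spec a [roi_spec()].
#' @param axial_res axial resolution in mm/px (needed for modes 2-4).
#' @return a list of class `roi_result`: `image_roi` (cropped matrix),
#'   `row_offset` (number of removed rows above the ROI, i.e. the 0-based
#'   index of the first retained original row), and `rows_kept`.
#' @export
extract_roi <- function(image, mask, slm, spec, axial_res = NULL) {
  stopifnot(inherits(spec, "roi_spec"), is.matrix(image))
  assert_same_dim(image, mask, "image and mask")
  assert_same_dim(image, slm, "image and SLM")
  h <- nrow(image)
  if (spec$mode == 0L)
    return(structure(list(image_roi = image, row_offset = 0L,
                          rows_kept = h), class = "roi_result"))
  mask <- mask > 0
  if (!any(mask)) stop("empty epidermis mask: ROI undefined")
  if (spec$mode %in% c(2L, 3L, 4L) && is.null(axial_res))
    stop("axial_res is required for mm-based margins (modes 2-4)")
  rows_with <- which(rowSums(mask) > 0)
  top <- min(rows_with); bottom <- max(rows_with)
  margin_px <- if (spec$mode %in% c(1L, 3L)) spec$upper_margin_px
               else as.integer(round(spec$upper_margin_mm / axial_res))
  first <- max(1L, top - margin_px)
  last <- if (spec$mode %in% c(3L, 4L)) {
    min(h, bottom + as.integer(round(spec$lower_margin_mm / axial_res)))
  } else h
  roi <- image[first:last, , drop = FALSE]
  if (spec$zero_avoided) {
    slm_roi <- slm[first:last, , drop = FALSE]
    roi[slm_roi == -1] <- 0
  }
  structure(list(image_roi = roi, row_offset = first - 1L,
                 rows_kept = last - first + 1L),
            class = "roi_result")
}
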