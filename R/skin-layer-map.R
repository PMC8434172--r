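# Skin layer map (SLM): per-pixel anatomical relevance derived from the
# epidermis mask and the axial resolution.

SLM_VALUES <- c(-1, 0, 0.5, 1, 2, 3)

#' Build a skin layer map from an epidermis mask
#'
#' The SLM grades each pixel by its diagnostic relevance. Epidermis pixels
#' take the maximum value 3. Below the epidermis the value decreases twice
#' by 1 every 0.5 mm (half of the dermis layer thickness), then twice by 0.5
#' every 0.5 mm, so depth `d` mm below a column's lowest epidermis pixel
#' maps to 2 for `d` in (0, 0.5], 1 in (0.5, 1], 0.5 in (1, 1.5], 0 in
#' (1.5, 2], and -1 beyond 2 mm. The `gel_band_px` pixels directly above a
#' column's highest epidermis pixel are set to 0 (coupling gel); everything
#' above that band, and every column without epidermis, is -1 (avoided:
#' probe membrane, remaining gel, muscle).
#'
#' Depths are measured per column on pixel-centre coordinates: row `r` lies
#' `(r - boundary_row) * axial_res` mm below the boundary.
#'
#' @param mask logical (or 0/1) matrix; epidermis pixels are `TRUE`.
#'   Must contain at least one positive pixel.
#' @param axial_res axial pixel size in mm/px.
#' @param gel_band_px height of the gel band above the epidermis, in pixels.
#' @return numeric matrix with values in `{-1, 0, 0.5, 1, 2, 3}`, same size
#'   as `mask`.
#' @export
build_slm <- function(mask, axial_res, gel_band_px = 30L) {
  mask <- mask > 0
  if (!any(mask)) stop("empty epidermis mask: SLM undefined")
  stopifnot(axial_res > 0, gel_band_px >= 0)
  h <- nrow(mask); w <- ncol(mask)
  top <- rep(NA_integer_, w); bot <- rep(NA_integer_, w)
  has <- colSums(mask) > 0
  if (any(has)) {
    rr <- matrix(seq_len(h), h, w)
    rr_in <- rr; rr_in[!mask] <- NA_integer_
    top[has] <- apply(rr_in[, has, drop = FALSE], 2, min, na.rm = TRUE)
    bot[has] <- apply(rr_in[, has, drop = FALSE], 2, max, na.rm = TRUE)
  }
  H <- matrix(-1, h, w)
  R <- matrix(seq_len(h), h, w)
  TOP <- matrix(top, h, w, byrow = TRUE)
  BOT <- matrix(bot, h, w, byrow = TRUE)
  valid <- matrix(has, h, w, byrow = TRUE)
  d <- (R - BOT) * axial_res                 # depth below the epidermis, mm
  below <- valid & R > BOT
  H[below & d <= 2.0] <- 0
  H[below & d <= 1.5] <- 0.5
  H[below & d <= 1.0] <- 1
  H[below & d <= 0.5] <- 2
  gel <- valid & R < TOP & R >= TOP - gel_band_px
  H[gel] <- 0
  # non-mask pixels enclosed by the band (holes) take the first sub-band value
  inside <- valid & R >= TOP & R <= BOT & !mask
  H[inside] <- 2
  H[mask] <- 3
  H
}
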