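# Classification confidence level (CCL): agreement between the normalized
# Grad-CAM map L and the skin layer map H.
#
# The confidence map collects the element-wise products L(i,j) * H(i,j) that
# are strictly positive (set G, cardinality M); the CCL is their mean
#   t = (1/M) * sum over G.
# Pixels with H <= 0 (gel, avoided regions) and pixels with no saliency
# (L = 0) never contribute. With L in [0, 1] and max(H) = 3, t lies in
# [0, 3]; M = 0 (no saliency inside relevant anatomy) is defined as t = 0.

#' Confidence map from a Grad-CAM map and a skin layer map
#'
#' @param L_norm normalized, aligned Grad-CAM map in `[0, 1]`.
#' @param H skin layer map from [build_slm()], same grid.
#' @return a list of class `confidence_map`: `products` (L * H),
#'   `included` (logical, products strictly > 0), `M` (count of included
#'   pixels).
#' @export
confidence_map <- function(L_norm, H) {
  stopifnot(is.matrix(L_norm), is.matrix(H))
  assert_same_dim(L_norm, H, "Grad-CAM map and SLM")
  if (any(L_norm < 0 | L_norm > 1))
    stop("L_norm must be normalized to [0, 1]")
  products <- L_norm * H
  included <- products > 0
  structure(list(products = products, included = included,
                 M = sum(included)),
            class = "confidence_map")
}

#' Classification confidence level
#'
#' Mean of the strictly positive products of the confidence map; 0 when no
#' pixel is included.
#'
#' @param cmap a [confidence_map()].
#' @return a list of class `ccl_result` with `t` (the CCL) and `M`.
#' @export
ccl <- function(cmap) {
  stopifnot(inherits(cmap, "confidence_map"))
  t_val <- if (cmap$M == 0L) 0 else mean(cmap$products[cmap$included])
  structure(list(t = t_val, M = cmap$M), class = "ccl_result")
}
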