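# Grad-CAM: gradient-weighted class activation maps for the built-in
# convolutional networks.
#
# For a target class c with pre-softmax score y_c and final-convolutional
# feature maps A^k (Z spatial positions each), the channel weights are
#   alpha_k = (1/Z) * sum_ij  d y_c / d A^k_ij
# and the raw map is ReLU(sum_k alpha_k A^k). The raw map lives at
# feature-map resolution; it is min-max normalized to [0, 1] per image and
# bilinearly rescaled/placed back onto the original image grid.

# default Grad-CAM layer: output of the last layer with spatial extent
# before global pooling (by convention the ReLU following the last conv).
default_gradcam_layer <- function(net) {
  spatial <- vapply(net$layers, function(l)
    l$out_shape[1] > 1 || l$out_shape[2] > 1, logical(1))
  if (!any(spatial)) stop("network has no layer with spatial activations")
  max(which(spatial))
}

#' Raw Grad-CAM map
#'
#' Computes the unnormalized Grad-CAM map of `net` for `target_class` at the
#' output of layer `layer_id` (default: the last spatial layer before global
#' pooling). The map is non-negative (ReLU) and at feature-map resolution.
#'
#' @param net a trained `usconf_net` whose final layer outputs class logits.
#' @param x input image: matrix or `h x w x c` array matching the network
#'   input shape.
#' @param target_class class index (1-based into the logit vector). Defaults
#'   to the network's predicted class for `x`.
#' @param layer_id index of the layer whose output activations are used.
#' @return a list of class `gradcam_map` with `raw` (matrix), `alpha`
#'   (channel weights), `target_class`, `layer_id`, `logits`.
#' @export
gradcam_raw <- function(net, x, target_class = NULL, layer_id = NULL) {
  stopifnot(inherits(net, "usconf_net"))
  if (is.null(layer_id)) layer_id <- default_gradcam_layer(net)
  shp <- net$layers[[layer_id]]$out_shape
  if (shp[1] == 1 && shp[2] == 1)
    stop("layer ", layer_id, " has no spatial activations; Grad-CAM needs a ",
         "convolutional feature map")
  fw <- net_forward(net, x)
  logits <- as.vector(fw$acts[[length(fw$acts)]])
  if (is.null(target_class)) target_class <- which.max(logits)
  stopifnot(target_class >= 1, target_class <= length(logits))
  dout <- array(0, dim = dim(fw$acts[[length(fw$acts)]]))
  dout[target_class] <- 1
  bk <- net_backward(net, fw, dout, upto = layer_id)
  dA <- bk$d_act                             # d y_c / d A at layer output
  A <- fw$acts[[layer_id + 1L]]
  Z <- dim(A)[1] * dim(A)[2]
  alpha <- colSums(matrix(dA, Z, dim(A)[3])) / Z
  raw <- matrix(matrix(A, Z, dim(A)[3]) %*% alpha, dim(A)[1], dim(A)[2])
  raw <- pmax(raw, 0)
  structure(list(raw = raw, alpha = alpha, target_class = target_class,
                 layer_id = layer_id, logits = logits),
            class = "gradcam_map")
}

#' Min-max normalize a saliency map to [0, 1]
#'
#' `(raw - min) / (max - min)`; an all-constant map (no localized evidence)
#' normalizes to all zeros.
#'
#' @param raw non-negative numeric matrix.
#' @return matrix in `[0, 1]`.
#' @export
normalize_map <- function(raw) {
  stopifnot(is.matrix(raw), all(raw >= 0))
  rng <- range(raw)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(raw), ncol(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Align a normalized Grad-CAM map to original image coordinates
#'
#' Bilinearly upsamples the map to the ROI grid, then places it at the ROI's
#' row offset inside a zero canvas of the original image size, so the result
#' is aligned pixel-for-pixel with the skin layer map. Pixels outside the
#' ROI are 0 and therefore never contribute to the confidence level.
#'
#' @param normalized matrix in `[0, 1]` (typically at classifier-input
#'   resolution).
#' @param original_size `c(height, width)` of the original image.
#' @param roi the `roi_result` the classifier input was taken from.
#' @return numeric matrix of size `original_size`.
#' @export
align_map <- function(normalized, original_size, roi) {
  stopifnot(is.matrix(normalized), length(original_size) == 2,
            inherits(roi, "roi_result"))
  h <- original_size[1]; w <- original_size[2]
  if (roi$row_offset < 0 || roi$row_offset + roi$rows_kept > h)
    stop("ROI offsets inconsistent with the original image size")
  up <- resize_bilinear(normalized, roi$rows_kept, w)
  canvas <- matrix(0, h, w)
  canvas[(roi$row_offset + 1L):(roi$row_offset + roi$rows_kept), ] <- up
  canvas
}
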