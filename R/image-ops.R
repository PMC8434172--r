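# Grid-level image operations shared across modules.

#' Bilinear resize of a matrix
#'
#' Resizes a numeric matrix to `out_h` x `out_w` by bilinear interpolation
#' with corner alignment: the four corner values of the input are preserved
#' in the output. Values in `[0, 1]` stay in `[0, 1]` (interpolation is a
#' convex combination).
#'
#' @param x numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @return numeric `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(is.matrix(x), out_h >= 1, out_w >= 1)
  h <- nrow(x); w <- ncol(x)
  src <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(1, n_out)
    else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ri <- src(out_h, h); cj <- src(out_w, w)
  r0 <- pmin(floor(ri), h - if (h > 1) 1 else 0); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(floor(cj), w - if (w > 1) 1 else 0); c1 <- pmin(c0 + 1, w)
  fr <- ri - r0; fc <- cj - c0
  A <- x[r0, c0, drop = FALSE]; B <- x[r1, c0, drop = FALSE]
  C <- x[r0, c1, drop = FALSE]; D <- x[r1, c1, drop = FALSE]
  FR <- matrix(fr, out_h, out_w)
  FC <- matrix(fc, out_h, out_w, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * FR * (1 - FC) + C * (1 - FR) * FC + D * FR * FC
}

# Integer translation with zero padding: positive dr moves content down,
# positive dc moves it right.
translate_image <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  sr <- max(1, 1 - dr):min(h, h - dr)
  sc <- max(1, 1 - dc):min(w, w - dc)
  if (dr <= -h || dr >= h || dc <= -w || dc >= w) return(out)
  out[sr + dr, sc + dc] <- x[sr, sc]
  out
}

# Rotation about the image centre by `angle` degrees (counter-clockwise in
# row/col coordinates), bilinear resampling, zero fill outside the source.
rotate_image <- function(x, angle) {
  h <- nrow(x); w <- ncol(x)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- matrix(rep(seq_len(h), w), h, w) - cy
  C <- matrix(rep(seq_len(w), each = h), h, w) - cx
  # inverse mapping: sample source at the back-rotated coordinate
  sr <- cos(th) * R + sin(th) * C + cy
  sc <- -sin(th) * R + cos(th) * C + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- x[cbind(ri[ok], ci[ok])]
    v
  }
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  frv <- as.vector(fr); fcv <- as.vector(fc)
  out <- val(r0v, c0v) * (1 - frv) * (1 - fcv) +
    val(r0v + 1, c0v) * frv * (1 - fcv) +
    val(r0v, c0v + 1) * (1 - frv) * fcv +
    val(r0v + 1, c0v + 1) * frv * fcv
  matrix(out, h, w)
}

flip_horizontal <- function(x) x[, ncol(x):1, drop = FALSE]

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Largest connected component (4-connectivity) of a binary matrix.
# EBImage::bwlabel works on the transposed (x, y) convention but labelling
# is orientation-invariant, so the matrix is passed as-is.
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

assert_same_dim <- function(a, b, what = "grids") {
  if (!all(dim(a) == dim(b)))
    stop(what, " differ in size: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}
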