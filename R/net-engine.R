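# Minimal convolutional-network engine.
#
# Provides just what the package needs: stride-1 "same" 2D convolutions,
# ReLU, 2x2 max pooling, nearest-neighbour 2x upsampling, global average
# pooling and dense layers, with analytic backpropagation and SGD with
# momentum. Convolutions are evaluated as im2col patch-matrix products so
# the heavy lifting happens in BLAS. Backprop exposes the gradient of any
# class score with respect to an intermediate activation, which is what
# Grad-CAM requires.
#
# Tensors are base arrays with dim c(height, width, channels); weights for a
# k x k convolution with ci input and co output channels are a
# (k*k*ci) x co matrix whose rows are ordered (di, dj, channel), di fastest.

# im2col index cache: the gather index for a given (h, w, c, k) is reused
# across calls because every training step hits the same shapes.
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(h, w, c, k) {
  key <- paste(h, w, c, k, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  wp <- w + 2L * p
  # output position (i, j), column-major
  a <- rep(seq_len(h), times = w) + (rep(seq_len(w), each = h) - 1L) * hp
  # patch offset (di, dj, ch), di fastest
  di <- rep(0:(k - 1L), times = k * c)
  dj <- rep(rep(0:(k - 1L), each = k), times = c)
  ch <- rep(0:(c - 1L), each = k * k)
  b <- di + dj * hp + ch * hp * wp
  idx <- outer(a, b, "+")
  .im2col_cache[[key]] <- idx
  idx
}

pad_input <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

im2col <- function(x, k) {
  d <- dim(x)
  p <- (k - 1L) %/% 2L
  xp <- pad_input(x, p)
  idx <- im2col_idx(d[1], d[2], d[3], k)
  # index with a plain vector: a matrix subscript whose width equals the
  # array rank would be taken as per-dimension coordinates
  matrix(xp[as.vector(idx)], nrow = nrow(idx))
}

conv_forward <- function(x, W, b, k) {
  d <- dim(x)
  P <- im2col(x, k)
  out <- P %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, dim = c(d[1], d[2], length(b))), P = P)
}

# Gradient w.r.t. the convolution input: a same-padded convolution of the
# output gradient with the spatially flipped, channel-transposed kernel.
conv_backward_input <- function(dout, W, k, ci) {
  co <- ncol(W)
  Wa <- array(W, dim = c(k, k, ci, co))
  Wf <- Wa[k:1, k:1, , , drop = FALSE]
  Wb <- aperm(Wf, c(1, 2, 4, 3))          # (k, k, co, ci)
  Wb <- matrix(Wb, nrow = k * k * co, ncol = ci)
  d <- dim(dout)
  P <- im2col(dout, k)
  array(P %*% Wb, dim = c(d[1], d[2], ci))
}

maxpool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  a1 <- x[io, jo, , drop = FALSE]
  a2 <- x[io + 1L, jo, , drop = FALSE]
  a3 <- x[io, jo + 1L, , drop = FALSE]
  a4 <- x[io + 1L, jo + 1L, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  # first-maximum tie-break, fixed order
  which4 <- ifelse(a1 == m, 1L, ifelse(a2 == m, 2L, ifelse(a3 == m, 3L, 4L)))
  list(out = m, which = which4, in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, dim = d)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  w <- cache$which
  dx[io, jo, ]           <- dout * (w == 1L)
  dx[io + 1L, jo, ]      <- dx[io + 1L, jo, , drop = FALSE] + dout * (w == 2L)
  dx[io, jo + 1L, ]      <- dx[io, jo + 1L, , drop = FALSE] + dout * (w == 3L)
  dx[io + 1L, jo + 1L, ] <- dx[io + 1L, jo + 1L, , drop = FALSE] + dout * (w == 4L)
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample_backward <- function(dout) {
  d <- dim(dout)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  dout[io, jo, , drop = FALSE] + dout[io + 1L, jo, , drop = FALSE] +
    dout[io, jo + 1L, , drop = FALSE] + dout[io + 1L, jo + 1L, , drop = FALSE]
}

#' Define a small convolutional network
#'
#' Builds an untrained network from a layer specification. Supported layer
#' types: `conv(k, filters)`, `relu`, `maxpool` (2x2), `upsample` (2x
#' nearest-neighbour), `gap` (global average pooling) and `dense(units)`.
#' Weights are He-initialized from R's RNG, so results are reproducible
#' under `set.seed()`.
#'
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param layers list of layer specs, e.g.
#'   `list(list(type = "conv", k = 3, filters = 8), list(type = "relu"))`.
#' @return an object of class `usconf_net`.
#' @export
net_define <- function(input_shape, layers) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  shape <- as.integer(input_shape)
  built <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    type <- lay$type
    if (type == "conv") {
      k <- as.integer(lay$k %||% 3L)
      ci <- shape[3]; co <- as.integer(lay$filters)
      fan_in <- k * k * ci
      W <- matrix(stats::rnorm(fan_in * co, sd = sqrt(2 / fan_in)), fan_in, co)
      lay$W <- W; lay$b <- numeric(co); lay$k <- k; lay$ci <- ci
      shape[3] <- co
    } else if (type == "maxpool") {
      if (shape[1] %% 2L || shape[2] %% 2L)
        stop("maxpool requires even spatial dimensions, got ",
             shape[1], "x", shape[2])
      shape[1:2] <- shape[1:2] %/% 2L
    } else if (type == "upsample") {
      shape[1:2] <- shape[1:2] * 2L
    } else if (type == "gap") {
      shape <- c(1L, 1L, shape[3])
    } else if (type == "dense") {
      ni <- prod(shape); no <- as.integer(lay$units)
      lay$W <- matrix(stats::rnorm(ni * no, sd = sqrt(2 / ni)), ni, no)
      lay$b <- numeric(no)
      shape <- c(1L, 1L, no)
    } else if (type == "skip_add") {
      from <- as.integer(lay$from)
      if (from < 1L || from >= li)
        stop("skip_add 'from' must reference an earlier layer")
      src_shape <- built[[from]]$out_shape
      if (!all(src_shape == shape))
        stop("skip_add shapes differ: ", paste(src_shape, collapse = "x"),
             " vs ", paste(shape, collapse = "x"))
      lay$from <- from
    } else if (type != "relu") {
      stop("unknown layer type: ", type)
    }
    lay$out_shape <- shape
    built[[li]] <- lay
  }
  structure(list(input_shape = as.integer(input_shape), layers = built),
            class = "usconf_net")
}

#' @export
print.usconf_net <- function(x, ...) {
  cat("<usconf_net> input", paste(x$input_shape, collapse = "x"), "\n")
  for (lay in x$layers)
    cat(sprintf("  %-8s -> %s\n", lay$type, paste(lay$out_shape, collapse = "x")))
  invisible(x)
}

# Forward pass. Returns the list of activations: acts[[1]] is the input,
# acts[[i + 1]] the output of layer i; caches needed by backprop ride along.
net_forward <- function(net, x, keep = TRUE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(all(dim(x) == net$input_shape))
  acts <- vector("list", length(net$layers) + 1L)
  caches <- vector("list", length(net$layers))
  acts[[1L]] <- x
  cur <- x
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    if (lay$type == "conv") {
      cf <- conv_forward(cur, lay$W, lay$b, lay$k)
      cur <- cf$out
      if (keep) caches[[li]] <- cf$P
    } else if (lay$type == "relu") {
      cur <- pmax(cur, 0)
    } else if (lay$type == "maxpool") {
      mp <- maxpool_forward(cur)
      cur <- mp$out
      if (keep) caches[[li]] <- mp[c("which", "in_dim")]
    } else if (lay$type == "upsample") {
      cur <- upsample_forward(cur)
    } else if (lay$type == "gap") {
      d <- dim(cur)
      cur <- array(colMeans(matrix(cur, d[1] * d[2], d[3])), dim = c(1L, 1L, d[3]))
      if (keep) caches[[li]] <- d
    } else if (lay$type == "dense") {
      v <- as.vector(cur)
      cur <- array(drop(v %*% lay$W) + lay$b, dim = lay$out_shape)
    } else if (lay$type == "skip_add") {
      cur <- cur + acts[[lay$from + 1L]]
    }
    acts[[li + 1L]] <- cur
  }
  list(acts = acts, caches = caches)
}

# Backward pass from a gradient on the final output. Gradients at each
# layer's output are accumulated (a skip connection contributes a second
# path), so `douts[[li + 1]]` is complete by the time the reverse sweep
# reaches layer li. Returns per-layer weight gradients, and stops early at
# `upto` (a layer index) if given, in which case the gradient w.r.t. that
# layer's OUTPUT is returned as d_act.
net_backward <- function(net, fw, dout, upto = 0L) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  douts <- vector("list", nl + 1L)
  douts[[nl + 1L]] <- dout
  add_to <- function(slot, d) {
    if (is.null(douts[[slot]])) douts[[slot]] <<- d
    else douts[[slot]] <<- douts[[slot]] + d
  }
  for (li in rev(seq_len(nl))) {
    d <- douts[[li + 1L]]
    if (li == upto) return(list(grads = grads, d_act = d))
    lay <- net$layers[[li]]
    a_in <- fw$acts[[li]]
    if (lay$type == "conv") {
      dm <- matrix(d, ncol = dim(d)[3])
      grads[[li]] <- list(W = crossprod(fw$caches[[li]], dm), b = colSums(dm))
      d <- conv_backward_input(d, lay$W, lay$k, lay$ci)
    } else if (lay$type == "relu") {
      d <- d * (a_in > 0)
    } else if (lay$type == "maxpool") {
      d <- maxpool_backward(d, fw$caches[[li]])
    } else if (lay$type == "upsample") {
      d <- upsample_backward(d)
    } else if (lay$type == "gap") {
      din <- fw$caches[[li]]
      z <- din[1] * din[2]
      d <- array(rep(as.vector(d) / z, each = z), dim = din)
    } else if (lay$type == "dense") {
      v <- as.vector(a_in); dv <- as.vector(d)
      grads[[li]] <- list(W = outer(v, dv), b = dv)
      d <- array(drop(lay$W %*% dv), dim = dim(a_in))
    } else if (lay$type == "skip_add") {
      add_to(lay$from + 1L, d)
    }
    add_to(li, d)
  }
  list(grads = grads, d_act = douts[[1L]])
}

# Forward pass that injects a replacement activation at the output of layer
# `at` and evaluates only the remainder of the network. Used by the
# finite-difference checks of the Grad-CAM gradients. `context_acts`
# (a previous full forward's activation list) supplies skip-connection
# sources that precede `at`.
net_forward_from <- function(net, at, act, context_acts = NULL) {
  nl <- length(net$layers)
  acts <- vector("list", nl + 1L)
  if (!is.null(context_acts)) acts[seq_len(at)] <- context_acts[seq_len(at)]
  acts[[at + 1L]] <- act
  cur <- act
  if (at < nl) for (li in (at + 1L):nl) {
    lay <- net$layers[[li]]
    if (lay$type == "conv") {
      cur <- conv_forward(cur, lay$W, lay$b, lay$k)$out
    } else if (lay$type == "relu") {
      cur <- pmax(cur, 0)
    } else if (lay$type == "maxpool") {
      cur <- maxpool_forward(cur)$out
    } else if (lay$type == "upsample") {
      cur <- upsample_forward(cur)
    } else if (lay$type == "gap") {
      d <- dim(cur)
      cur <- array(colMeans(matrix(cur, d[1] * d[2], d[3])), dim = c(1L, 1L, d[3]))
    } else if (lay$type == "dense") {
      cur <- array(drop(as.vector(cur) %*% lay$W) + lay$b, dim = lay$out_shape)
    } else if (lay$type == "skip_add") {
      src <- acts[[lay$from + 1L]]
      if (is.null(src))
        stop("net_forward_from needs context_acts covering skip sources")
      cur <- cur + src
    }
    acts[[li + 1L]] <- cur
  }
  cur
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# One SGD-with-momentum step over accumulated gradients (in place on the
# returned net). `vel` carries the momentum state between calls.
sgdm_step <- function(net, grads, vel, lr, momentum) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    if (is.null(vel[[li]])) vel[[li]] <- list(W = 0 * g$W, b = 0 * g$b)
    vel[[li]]$W <- momentum * vel[[li]]$W - lr * g$W
    vel[[li]]$b <- momentum * vel[[li]]$b - lr * g$b
    net$layers[[li]]$W <- net$layers[[li]]$W + vel[[li]]$W
    net$layers[[li]]$b <- net$layers[[li]]$b + vel[[li]]$b
  }
  list(net = net, vel = vel)
}

accumulate_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (li in seq_along(g)) {
    if (is.null(g[[li]])) next
    if (is.null(acc[[li]])) { acc[[li]] <- g[[li]]; next }
    acc[[li]]$W <- acc[[li]]$W + g[[li]]$W
    acc[[li]]$b <- acc[[li]]$b + g[[li]]$b
  }
  acc
}

scale_grads <- function(g, s) {
  for (li in seq_along(g)) {
    if (is.null(g[[li]])) next
    g[[li]]$W <- g[[li]]$W * s
    g[[li]]$b <- g[[li]]$b * s
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
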