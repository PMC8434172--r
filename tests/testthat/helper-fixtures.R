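# Shared fixtures built in code.

# flat-strip epidermis mask: rows given in 0-based coordinates to match the
# row_offset convention used in documentation examples
strip_mask <- function(h, w, top0, bottom0) {
  m <- matrix(FALSE, h, w)
  m[(top0 + 1L):(bottom0 + 1L), ] <- TRUE
  m
}

# random undulating band mask (always non-empty, one band per column)
random_band_mask <- function(h, w, seed) {
  set.seed(seed)
  top <- round(h * 0.3 + (h * 0.1) *
                 sin(2 * pi * runif(1) + seq_len(w) / w * 2 * pi * runif(1, 0.5, 2)))
  thick <- sample(2:max(3, round(h * 0.08)), 1)
  m <- matrix(FALSE, h, w)
  for (j in seq_len(w)) {
    r0 <- min(max(1L, top[j]), h - thick)
    m[r0:(r0 + thick - 1L), j] <- TRUE
  }
  m
}

# small random CNN in the shape Grad-CAM expects (conv stages then a head)
tiny_cnn <- function(seed, input_px = 8L, k1 = 3L, k2 = 4L, n_classes = 4L) {
  set.seed(seed)
  net_define(c(input_px, input_px, 1L), list(
    list(type = "conv", k = 3, filters = k1), list(type = "relu"),
    list(type = "conv", k = 3, filters = k2), list(type = "relu"),
    list(type = "gap"),
    list(type = "dense", units = n_classes)))
}

# central finite-difference oracle for the Grad-CAM channel weights alpha_k:
# perturb each entry of the layer activation A, re-run the remaining
# layers, and average the score differences over the feature map
alpha_fd_oracle <- function(net, x, target_class, layer_id, h = 1e-4) {
  fw <- usconf:::net_forward(net, x)
  A <- fw$acts[[layer_id + 1L]]
  dA <- dim(A)
  vapply(seq_len(dA[3]), function(k) {
    s <- 0
    for (i in seq_len(dA[1])) for (j in seq_len(dA[2])) {
      Ap <- A; Ap[i, j, k] <- Ap[i, j, k] + h
      Am <- A; Am[i, j, k] <- Am[i, j, k] - h
      yp <- usconf:::net_forward_from(net, layer_id, Ap, fw$acts)
      ym <- usconf:::net_forward_from(net, layer_id, Am, fw$acts)
      s <- s + (as.vector(yp)[target_class] - as.vector(ym)[target_class]) /
        (2 * h)
    }
    s / (dA[1] * dA[2])
  }, numeric(1))
}

# brute-force percentile sweep oracle, written independently of ccl_sweep():
# it recomputes every quantity by direct subsetting per percentile
sweep_oracle <- function(ccl_values, correct, percentiles = 1:99) {
  N <- length(ccl_values)
  out <- data.frame(p = integer(), t_p = numeric(), n_p = integer(),
                    a_p = numeric(), m_p = numeric())
  for (p in percentiles) {
    t_p <- as.numeric(stats::quantile(ccl_values, p / 100, type = 7))
    sel <- which(ccl_values > t_p)
    n_p <- length(sel)
    a_p <- if (n_p == 0) 0 else sum(correct[sel]) / n_p
    out <- rbind(out, data.frame(p = p, t_p = t_p, n_p = n_p, a_p = a_p,
                                 m_p = a_p * (n_p / N) * t_p))
  }
  out
}
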