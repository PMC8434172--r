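# Grad-CAM maps: gradient correctness, normalization, alignment.

test_that("alpha matches the finite-difference oracle on tiny random CNNs", {
  for (seed in c(101, 202, 303)) {
    net <- tiny_cnn(seed)
    set.seed(seed + 1)
    x <- matrix(runif(64), 8, 8)
    for (cls in c(1L, 3L)) {
      g <- gradcam_raw(net, x, target_class = cls, layer_id = 4L)
      a_fd <- alpha_fd_oracle(net, x, cls, 4L)
      expect_equal(g$alpha, a_fd, tolerance = 1e-3)
      # and the map itself is ReLU(sum_k alpha_k A_k), elementwise
      fw <- usconf:::net_forward(net, x)
      A <- fw$acts[[5]]
      raw_fd <- matrix(0, 8, 8)
      for (k in seq_along(a_fd)) raw_fd <- raw_fd + a_fd[k] * A[, , k]
      expect_equal(g$raw, pmax(raw_fd, 0), tolerance = 1e-3)
    }
  }
})

test_that("raw maps are non-negative and default class is the prediction", {
  net <- tiny_cnn(7)
  set.seed(8)
  x <- matrix(runif(64), 8, 8)
  g <- gradcam_raw(net, x)
  expect_true(all(g$raw >= 0))
  expect_equal(g$target_class, which.max(g$logits))
})

test_that("a mean-score single-channel model gives raw proportional to ReLU(A)", {
  # head = mean of the one feature map => dy/dA_ij = 1/Z, alpha = 1/Z
  set.seed(40)
  net <- net_define(c(6, 6, 1), list(
    list(type = "conv", k = 3, filters = 1), list(type = "relu"),
    list(type = "gap"),
    list(type = "dense", units = 1)))
  net$layers[[4]]$W <- matrix(1, 1, 1); net$layers[[4]]$b <- 0
  x <- matrix(runif(36), 6, 6)
  g <- gradcam_raw(net, x, target_class = 1, layer_id = 2L)
  fw <- usconf:::net_forward(net, x)
  A <- fw$acts[[3]][, , 1]
  expect_equal(g$alpha, 1 / 36, tolerance = 1e-12)
  expect_equal(g$raw, pmax(A, 0) / 36)
})

test_that("raw maps are positively homogeneous in the feature maps", {
  # under a fixed linear head, dy/dA is constant, so alpha is unchanged and
  # scaling every feature map by s scales the raw map by exactly s
  set.seed(50)
  net <- net_define(c(6, 6, 1), list(
    list(type = "conv", k = 3, filters = 2),
    list(type = "gap"),
    list(type = "dense", units = 2)))
  x <- matrix(runif(36), 6, 6)
  g1 <- gradcam_raw(net, x, target_class = 2, layer_id = 1L)
  net2 <- net
  net2$layers[[1]]$W <- 3 * net$layers[[1]]$W   # A scales by 3
  net2$layers[[1]]$b <- 3 * net$layers[[1]]$b
  g2 <- gradcam_raw(net2, x, target_class = 2, layer_id = 1L)
  expect_equal(g2$alpha, g1$alpha, tolerance = 1e-10)
  expect_equal(g2$raw, 3 * g1$raw, tolerance = 1e-10)
})

test_that("normalize_map is exact min-max with degenerate cases", {
  raw <- matrix(c(0, 4, 2, 8), 2, 2)     # [[0,2],[4,8]]
  expect_equal(normalize_map(raw), matrix(c(0, 0.5, 0.25, 1), 2, 2))
  expect_equal(normalize_map(matrix(5, 3, 3)), matrix(0, 3, 3))
  already <- matrix(c(0, 1, 0.3, 0.7), 2, 2)
  expect_equal(normalize_map(already), already)
})

test_that("align_map places the upsampled map at the ROI offset", {
  # identity: ROI = whole image, map already image-sized
  set.seed(3)
  m <- matrix(runif(16), 4, 4)
  roi_full <- structure(list(image_roi = m, row_offset = 0L, rows_kept = 4L),
                        class = "roi_result")
  expect_equal(align_map(m, c(4, 4), roi_full), m)
  # closed-form bilinear 2x2 -> 4x4: corners preserved, centres interpolated
  m2 <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- resize_bilinear(m2, 4, 4)
  expect_equal(up[1, 1], 0); expect_equal(up[4, 4], 0)
  expect_equal(up[1, 4], 1); expect_equal(up[4, 1], 1)
  expect_equal(up[2, 2], (0 * 4 + 1 * 2 + 1 * 2 + 0 * 1) / 9)
  grid <- (seq_len(4) - 1) / 3
  bilinear <- outer(grid, grid, function(r, c)
    (1 - r) * (1 - c) * 0 + r * (1 - c) * 1 + (1 - r) * c * 1 + r * c * 0)
  expect_equal(up, bilinear)
  # placement inside the original canvas
  roi <- structure(list(image_roi = NULL, row_offset = 3L, rows_kept = 4L),
                   class = "roi_result")
  out <- align_map(m2, c(10, 4), roi)
  expect_equal(dim(out), c(10, 4))
  expect_true(all(out[c(1:3, 8:10), ] == 0))
  expect_equal(out[4:7, ], bilinear)
  # all-zero map stays all-zero
  expect_true(all(align_map(matrix(0, 2, 2), c(10, 4), roi) == 0))
  # inconsistent offsets error
  bad <- structure(list(row_offset = 8L, rows_kept = 4L), class = "roi_result")
  expect_error(align_map(m2, c(10, 4), bad), "inconsistent")
})

test_that("alignment preserves the argmax location of a peaked map", {
  set.seed(31)
  for (case in 1:5) {
    m <- matrix(0, 8, 8)
    pk <- c(sample(2:7, 1), sample(2:7, 1))
    m[pk[1], pk[2]] <- 1
    roi <- structure(list(row_offset = 0L, rows_kept = 32L),
                     class = "roi_result")
    out <- align_map(m, c(32, 32), roi)
    got <- which(out == max(out), arr.ind = TRUE)[1, ]
    scale_r <- 31 / 7; scale_c <- 31 / 7
    expect_lte(abs(got[1] - (1 + (pk[1] - 1) * scale_r)), scale_r / 2 + 1)
    expect_lte(abs(got[2] - (1 + (pk[2] - 1) * scale_c)), scale_c / 2 + 1)
  }
})

test_that("layers without spatial extent are rejected", {
  net <- tiny_cnn(9)
  set.seed(10)
  x <- matrix(runif(64), 8, 8)
  expect_error(gradcam_raw(net, x, layer_id = 5L), "spatial")
})
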