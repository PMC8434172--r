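# Convolutional-network engine: correctness of the building blocks.

test_that("same-padded convolution matches a direct loop computation", {
  set.seed(1)
  x <- array(runif(5 * 6 * 2), dim = c(5, 6, 2))
  W <- matrix(rnorm(3 * 3 * 2 * 3), 18, 3)
  b <- rnorm(3)
  out <- usconf:::conv_forward(x, W, b, 3L)$out
  Wa <- array(W, dim = c(3, 3, 2, 3))
  xp <- array(0, dim = c(7, 8, 2)); xp[2:6, 2:7, ] <- x
  ref <- array(0, dim = c(5, 6, 3))
  for (co in 1:3) for (i in 1:5) for (j in 1:6) {
    acc <- b[co]
    for (di in 0:2) for (dj in 0:2) for (ci in 1:2)
      acc <- acc + xp[i + di, j + dj, ci] * Wa[di + 1, dj + 1, ci, co]
    ref[i, j, co] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("weight gradients match finite differences through a deep net", {
  set.seed(2)
  net <- usconf:::seg_net_define(8, 8, c(3L, 4L, 5L))
  x <- matrix(runif(64), 8, 8)
  msk <- matrix(FALSE, 8, 8); msk[3:5, ] <- TRUE
  target <- array(c(as.numeric(!msk), as.numeric(msk)), dim = c(8, 8, 2))
  lossfun <- function(nn) {
    fw <- usconf:::net_forward(nn, x, keep = FALSE)
    usconf:::seg_loss_grad(fw$acts[[length(fw$acts)]], target,
                           "generalized_dice_weighted")$loss
  }
  fw <- usconf:::net_forward(net, x)
  lg <- usconf:::seg_loss_grad(fw$acts[[length(fw$acts)]], target,
                               "generalized_dice_weighted")
  bk <- usconf:::net_backward(net, fw, lg$dlogits)
  h <- 1e-5
  for (li in c(1, 7, 13, 19)) {       # encoder, bottleneck, decoder, head
    for (rep in 1:3) {
      i <- sample(length(net$layers[[li]]$W), 1)
      np <- net; np$layers[[li]]$W[i] <- np$layers[[li]]$W[i] + h
      nm <- net; nm$layers[[li]]$W[i] <- nm$layers[[li]]$W[i] - h
      fd <- (lossfun(np) - lossfun(nm)) / (2 * h)
      expect_equal(bk$grads[[li]]$W[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("maxpool keeps the maximum and routes gradient to it", {
  x <- array(0, dim = c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 2, 3, 4,
                       5, 6, 7, 8,
                       9, 10, 11, 12,
                       13, 14, 15, 16), 4, 4, byrow = TRUE)
  mp <- usconf:::maxpool_forward(x)
  expect_equal(mp$out[, , 1], matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  d <- array(1, dim = c(2, 2, 1))
  dx <- usconf:::maxpool_backward(d, mp)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1], 1)       # position of the 6
})

test_that("upsample and its backward are consistent adjoints", {
  set.seed(4)
  x <- array(runif(3 * 3 * 2), dim = c(3, 3, 2))
  up <- usconf:::upsample_forward(x)
  expect_equal(dim(up), c(6, 6, 2))
  expect_equal(up[3, 5, 1], x[2, 3, 1])
  d <- array(runif(6 * 6 * 2), dim = c(6, 6, 2))
  dx <- usconf:::upsample_backward(d)
  # adjoint identity: <up(x), d> = <x, up^T(d)>
  expect_equal(sum(up * d), sum(x * dx), tolerance = 1e-12)
})

test_that("skip connections add activations and validate shapes", {
  expect_error(net_define(c(8, 8, 1), list(
    list(type = "conv", k = 3, filters = 2),
    list(type = "maxpool"),
    list(type = "skip_add", from = 1L))), "shapes differ")
  set.seed(5)
  net <- net_define(c(4, 4, 1), list(
    list(type = "conv", k = 3, filters = 2), list(type = "relu"),
    list(type = "conv", k = 3, filters = 2),
    list(type = "skip_add", from = 2L)))
  x <- matrix(runif(16), 4, 4)
  fw <- usconf:::net_forward(net, x)
  expect_equal(fw$acts[[5]], fw$acts[[4]] + fw$acts[[3]])
})

test_that("training steps are deterministic under a fixed seed", {
  imgs <- lapply(1:8, function(i) {
    set.seed(i); matrix(runif(16 * 16), 16, 16)
  })
  labs <- rep(c("AD", "control"), 4)
  m1 <- train_classifier(imgs, labs, augmentation = "none", input_px = 16,
                         max_epochs = 1, seed = 42)
  m2 <- train_classifier(imgs, labs, augmentation = "none", input_px = 16,
                         max_epochs = 1, seed = 42)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$net$layers[[1]]$W, m2$net$layers[[1]]$W)
})
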