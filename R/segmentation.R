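# Epidermis segmentation: Dice metrics, a generalized Dice loss, and a
# small trainable encoder-decoder network. The encoder-decoder is a
# desk-scale stand-in for large pretrained semantic-segmentation backbones;
# any model exposing the same handle (a `segment_epidermis()` method
# returning a binary grid of the input size) can be plugged in instead.

#' Dice index between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, the standard overlap measure for
#' segmentation masks. Defined as 1 when both masks are empty.
#'
#' @param a,b logical (or 0/1) matrices of identical size.
#' @return a scalar in `[0, 1]`.
#' @export
dice_index <- function(a, b) {
  assert_same_dim(a, b, "masks")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

#' Generalized Dice loss
#'
#' `1 - 2 * sum_c w_c sum(p_c t_c) / sum_c w_c sum(p_c + t_c)` over classes
#' c, where `p` are per-class predicted probabilities and `t` the one-hot
#' target. Weighting (by default the inverse squared class volume) lets the
#' loss handle strong class imbalance such as thin-epidermis vs background.
#' The loss is 0 exactly when the prediction equals the target.
#'
#' @param pred `h x w x C` array of per-class probabilities (each pixel a
#'   probability simplex).
#' @param target `h x w x C` one-hot array.
#' @param class_weights positive weights per class, or `NULL` for inverse
#'   squared class volume `1 / (sum t_c)^2` (empty classes get weight 0).
#' @return non-negative scalar.
#' @export
generalized_dice_loss <- function(pred, target, class_weights = NULL) {
  stopifnot(length(dim(pred)) == 3, all(dim(pred) == dim(target)))
  C <- dim(pred)[3]
  pm <- matrix(pred, ncol = C); tm <- matrix(target, ncol = C)
  if (max(abs(rowSums(pm) - 1)) > 1e-6)
    stop("pred pixels must sum to 1 over classes")
  if (is.null(class_weights)) {
    vol <- colSums(tm)
    class_weights <- ifelse(vol > 0, 1 / vol^2, 0)
  }
  if (any(!is.finite(class_weights)) || any(class_weights < 0))
    stop("class weights must be finite and non-negative")
  num <- sum(class_weights * colSums(pm * tm))
  den <- sum(class_weights * colSums(pm + tm))
  1 - 2 * num / den
}

# gradient of the generalized Dice loss w.r.t. pred (same shape as pred)
gdl_gradient <- function(pred, target, class_weights) {
  C <- dim(pred)[3]
  pm <- matrix(pred, ncol = C); tm <- matrix(target, ncol = C)
  num <- sum(class_weights * colSums(pm * tm))
  den <- sum(class_weights * colSums(pm + tm))
  # d/dp_c(i) [1 - 2 num/den] = -2 (w_c t_c(i) den - num w_c) / den^2
  g <- -2 * (sweep(tm, 2, class_weights, "*") * den - num *
               matrix(class_weights, nrow(tm), C, byrow = TRUE)) / den^2
  array(g, dim = dim(pred))
}

#' Training configuration for the epidermis segmenter
#'
#' @param loss `"generalized_dice_weighted"` (default), `"dice"` (equal
#'   class weights) or `"cross_entropy"`.
#' @param batch_size minibatch size (default 8).
#' @param max_epochs training epochs (default 30; phantoms converge fast).
#' @param lr,momentum SGD-with-momentum parameters. The learning rate decays
#'   as `lr / (1 + lr_decay * (epoch - 1))`.
#' @param lr_decay inverse-time decay coefficient (0 disables decay).
#' @param augment apply horizontal reflection and +-10 px translations to
#'   each training draw.
#' @param channels encoder filter counts (3 levels).
#' @param val_fraction fraction of samples held out for checkpoint selection
#'   (the returned weights are those with the best validation Dice).
#' @param val_every validate every this many epochs.
#' @param seed RNG seed for weight init, batching and augmentation.
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(loss = c("generalized_dice_weighted", "dice",
                                "cross_entropy"),
                       batch_size = 8L, max_epochs = 30L, lr = 0.02,
                       momentum = 0.9, lr_decay = 0, augment = TRUE,
                       channels = c(8L, 16L, 16L), val_fraction = 0.15,
                       val_every = 5L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, max_epochs >= 1, lr > 0, momentum >= 0,
            momentum < 1, lr_decay >= 0, val_fraction >= 0, val_fraction < 0.5,
            val_every >= 1, length(channels) == 3)
  structure(list(loss = loss, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 momentum = momentum, lr_decay = lr_decay, augment = augment,
                 channels = as.integer(channels), val_fraction = val_fraction,
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "seg_config")
}

# U-Net-style encoder-decoder: 3 resolution levels with additive skip
# connections from each encoder stage into the matching decoder stage, so
# the decoder recovers boundary detail lost to pooling.
seg_net_define <- function(h, w, channels) {
  ch <- channels
  net_define(c(h, w, 1L), list(
    list(type = "conv", k = 3, filters = ch[1]), list(type = "relu"),  # 2
    list(type = "maxpool"),
    list(type = "conv", k = 3, filters = ch[2]), list(type = "relu"),  # 5
    list(type = "maxpool"),
    list(type = "conv", k = 3, filters = ch[3]), list(type = "relu"),
    list(type = "upsample"),
    list(type = "conv", k = 3, filters = ch[2]), list(type = "relu"),
    list(type = "skip_add", from = 5L),
    list(type = "conv", k = 3, filters = ch[1]), list(type = "relu"),
    list(type = "upsample"),
    list(type = "skip_add", from = 2L),
    list(type = "conv", k = 3, filters = ch[1]), list(type = "relu"),
    list(type = "conv", k = 1, filters = 2L)))
}

# per-pixel softmax over the channel dimension of an h x w x C array
pixel_softmax <- function(z) {
  C <- dim(z)[3]
  zm <- matrix(z, ncol = C)
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  array(e / rowSums(e), dim = dim(z))
}

seg_loss_grad <- function(logits, target, loss) {
  p <- pixel_softmax(logits)
  C <- dim(p)[3]
  npix <- dim(p)[1] * dim(p)[2]
  if (loss == "cross_entropy") {
    l <- -sum(target * log(pmax(p, 1e-12))) / npix
    dlogits <- (p - target) / npix
    return(list(loss = l, dlogits = dlogits))
  }
  tm <- matrix(target, ncol = C)
  w <- if (loss == "generalized_dice_weighted") {
    vol <- colSums(tm)
    ifelse(vol > 0, 1 / vol^2, 0)
  } else rep(1, C)
  l <- generalized_dice_loss(p, target, w)
  dp <- gdl_gradient(p, target, w)
  # chain rule through the per-pixel softmax
  pm <- matrix(p, ncol = C); dpm <- matrix(dp, ncol = C)
  dz <- pm * (dpm - rowSums(dpm * pm))
  list(loss = l, dlogits = array(dz, dim = dim(p)))
}

# per-image z-score standardization of segmenter inputs
seg_standardize <- function(x) {
  s <- stats::sd(x)
  if (s > 0) (x - mean(x)) / s else x * 0
}

# pad a matrix with zeros on the bottom/right so both dims are multiples of m
pad_to_multiple <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  hp <- as.integer(ceiling(h / m) * m); wp <- as.integer(ceiling(w / m) * m)
  if (hp == h && wp == w) return(list(x = x, h = h, w = w))
  out <- matrix(0, hp, wp)
  out[seq_len(h), seq_len(w)] <- x
  list(x = out, h = h, w = w)
}

#' Train the epidermis segmenter
#'
#' Trains a small 3-level encoder-decoder network to label each pixel as
#' epidermis or background, using SGD with momentum and (by default) the
#' weighted generalized Dice loss with inverse-squared-volume class weights.
#' Augmentation draws a horizontal reflection and +-10 px translations per
#' sample per epoch (applied identically to image and mask).
#'
#' @param samples list of `phantom_sample` objects (or any list whose
#'   elements have `image` and non-empty `mask` matrices of a common size).
#' @param config a [seg_config()].
#' @param restarts maximum number of re-initializations if training collapses
#'   to the all-background solution (resubstitution Dice below 0.5); an
#'   occasional bad weight draw makes the Dice-type losses fall into that
#'   local optimum.
#' @return an object of class `usconf_segmenter` with the trained network
#'   and a per-epoch training log (tibble `epoch`, `loss`).
#' @export
train_segmenter <- function(samples, config = seg_config(), restarts = 2L) {
  stopifnot(inherits(config, "seg_config"), length(samples) >= 2)
  imgs <- lapply(samples, function(s) s$image)
  masks <- lapply(samples, function(s) s$mask > 0)
  d <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    assert_same_dim(imgs[[i]], masks[[i]], "image and mask")
    if (!all(dim(imgs[[i]]) == d)) stop("all training images must share a size")
    if (!any(masks[[i]])) stop("training mask ", i, " is empty")
  }
  if (all(vapply(masks, all, logical(1))))
    warning("degenerate dataset: masks cover every pixel")
  if (d[1] %% 4L || d[2] %% 4L)
    stop("segmenter needs image dimensions divisible by 4, got ",
         d[1], "x", d[2])
  n <- length(samples)
  raw_dice <- function(net, i) {
    fw <- net_forward(net, seg_standardize(imgs[[i]]), keep = FALSE)
    logits <- fw$acts[[length(fw$acts)]]
    dice_index(logits[, , 2] > logits[, , 1], masks[[i]])
  }
  attempt <- function(attempt_seed) {
    set.seed(attempt_seed)
    n_val <- min(n - 2L, round(config$val_fraction * n))
    val_ids <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_ids <- setdiff(seq_len(n), val_ids)
    net <- seg_net_define(d[1], d[2], config$channels)
    vel <- vector("list", length(net$layers))
    log_rows <- vector("list", config$max_epochs)
    best <- list(dice = -1, net = net, epoch = 0L)
    validate <- function(epoch) {
      if (!length(val_ids)) { best <<- list(dice = 0, net = net,
                                            epoch = epoch); return() }
      v <- mean(vapply(val_ids, function(i) raw_dice(net, i), numeric(1)))
      if (v > best$dice) best <<- list(dice = v, net = net, epoch = epoch)
    }
    for (epoch in seq_len(config$max_epochs)) {
      lr_epoch <- config$lr / (1 + config$lr_decay * (epoch - 1))
      ord <- sample(tr_ids)
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL
        for (i in ids) {
          img <- imgs[[i]]; msk <- masks[[i]]
          if (config$augment) {
            if (stats::runif(1) < 0.5) {
              img <- flip_horizontal(img); msk <- flip_horizontal(msk)
            }
            dr <- sample(-10:10, 1); dc <- sample(-10:10, 1)
            img <- translate_image(img, dr, dc)
            msk <- translate_image(msk, dr, dc) > 0
          }
          target <- array(c(as.numeric(!msk), as.numeric(msk)), dim = c(d, 2L))
          fw <- net_forward(net, seg_standardize(img))
          lg <- seg_loss_grad(fw$acts[[length(fw$acts)]], target, config$loss)
          ep_loss <- ep_loss + lg$loss
          bk <- net_backward(net, fw, lg$dlogits)
          acc <- accumulate_grads(acc, bk$grads)
        }
        st <- sgdm_step(net, scale_grads(acc, 1 / length(ids)), vel,
                        lr_epoch, config$momentum)
        net <- st$net; vel <- st$vel
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                          loss = ep_loss / length(ord))
      if (epoch %% config$val_every == 0L || epoch == config$max_epochs)
        validate(epoch)
      # Dice-type losses have an all-background local optimum near loss 0.85;
      # a run still stuck above 0.8 after a few epochs will not recover
      if (config$loss != "cross_entropy" && epoch >= 3L &&
          log_rows[[epoch]]$loss > 0.8)
        return(list(net = net, log = dplyr::bind_rows(log_rows),
                    aborted = TRUE))
    }
    list(net = best$net, log = dplyr::bind_rows(log_rows), aborted = FALSE,
         val_dice = best$dice, best_epoch = best$epoch)
  }
  model_of <- function(fit, used) {
    structure(list(net = fit$net, config = config, input_dim = d,
                   log = fit$log, restarts_used = used),
              class = "usconf_segmenter")
  }
  resub_dice <- function(model) {
    probe <- seq_len(min(5L, n))
    mean(vapply(probe, function(i) {
      pred <- tryCatch(segment_epidermis(model, imgs[[i]]),
                       error = function(e) NULL)
      if (is.null(pred)) 0 else dice_index(pred, masks[[i]])
    }, numeric(1)))
  }
  used <- 0L
  fit <- attempt(config$seed)
  while ((fit$aborted || resub_dice(model_of(fit, used)) < 0.5) &&
         used < restarts) {
    used <- used + 1L
    fit <- attempt(config$seed + 7919L * used)
  }
  model_of(fit, used)
}

#' Segment the epidermis in an image
#'
#' Runs the trained segmenter and returns a binary mask of the input size.
#' Only the largest connected component of the predicted epidermis is kept
#' (downstream skin-layer-map and ROI geometry assume a single band). Inputs
#' whose dimensions are not multiples of 4 are zero-padded for the forward
#' pass and the prediction is cropped back.
#'
#' @param model a `usconf_segmenter` from [train_segmenter()], or a
#'   `phantom_sample` when `ground_truth = TRUE`.
#' @param image numeric matrix.
#' @param ground_truth if `TRUE`, `model` is ignored and `image` must be a
#'   `phantom_sample`, whose stored mask is returned unchanged (ground-truth
#'   passthrough mode).
#' @return logical matrix, same size as `image`.
#' @export
segment_epidermis <- function(model, image, ground_truth = FALSE) {
  if (ground_truth) {
    stopifnot(inherits(image, "phantom_sample"))
    return(image$mask > 0)
  }
  stopifnot(inherits(model, "usconf_segmenter"), is.matrix(image))
  pd <- pad_to_multiple(seg_standardize(image), 4L)
  net <- model$net
  if (!all(dim(pd$x) == net$input_shape[1:2]))
    net <- seg_net_retarget(model, dim(pd$x))
  fw <- net_forward(net, pd$x, keep = FALSE)
  logits <- fw$acts[[length(fw$acts)]]
  pred <- logits[, , 2] > logits[, , 1]
  pred <- pred[seq_len(pd$h), seq_len(pd$w), drop = FALSE]
  if (!any(pred))
    stop("segmenter predicted an empty epidermis mask; fall back to the ",
         "ground-truth mask or skip this sample")
  largest_component(pred)
}

# rebuild the (fully convolutional) network for a new input size, reusing
# the trained weights
seg_net_retarget <- function(model, new_dim) {
  if (new_dim[1] %% 4L || new_dim[2] %% 4L)
    stop("segmenter input dimensions must be multiples of 4")
  net2 <- seg_net_define(new_dim[1], new_dim[2], model$config$channels)
  for (li in seq_along(net2$layers)) {
    if (!is.null(model$net$layers[[li]]$W)) {
      net2$layers[[li]]$W <- model$net$layers[[li]]$W
      net2$layers[[li]]$b <- model$net$layers[[li]]$b
    }
  }
  net2
}
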