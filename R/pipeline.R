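# Experiment pipeline: augmentation, patient-wise cross-validation, the
# small CNN classifier, and the end-to-end phantom experiment that strings
# together segmentation masks, skin layer maps, ROI extraction, Grad-CAM,
# CCL and the multicriteria evaluation.

CLASS_LEVELS <- c("AD", "psoriasis", "tumor", "control")

#' Randomly augment an image
#'
#' Draws one random geometric transform from the augmentation mode's set and
#' applies it. `Aug0` uses horizontal reflection and +-10 px translations in
#' both directions; `Aug1` additionally applies a random rotation in
#' [-20, 20] degrees (bilinear resampling, zero fill). Transforms are drawn
#' from R's RNG, so augmentation is reproducible under `set.seed()`.
#'
#' @param image numeric matrix.
#' @param mode `"Aug0"` or `"Aug1"`.
#' @param translate_px maximum absolute translation in pixels.
#' @param rotate_deg maximum absolute rotation (Aug1 only).
#' @return the transformed matrix, same size.
#' @export
augment_image <- function(image, mode = c("Aug0", "Aug1"),
                          translate_px = 10L, rotate_deg = 20) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image))
  out <- image
  if (mode == "Aug1") {
    ang <- stats::runif(1, -rotate_deg, rotate_deg)
    out <- rotate_image(out, ang)
  }
  if (stats::runif(1) < 0.5) out <- flip_horizontal(out)
  dr <- sample(seq(-translate_px, translate_px), 1)
  dc <- sample(seq(-translate_px, translate_px), 1)
  translate_image(out, dr, dc)
}

#' Patient-wise k-fold assignment
#'
#' Assigns whole patients to test folds so that no patient's images are ever
#' split across training and testing. Patients are stratified by class and
#' dealt round-robin into folds, keeping folds approximately class-balanced.
#' Within each fold's non-test patients, a validation subset is reserved at
#' an 8:1 train:validation ratio (by patient, at least one).
#'
#' @param manifest tibble/data frame with columns `patient_id` and `label`.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return a list of class `fold_assignment`: `patients` (tibble
#'   `patient_id`, `label`, `fold`), `k`, and `roles(fold)` accessor data;
#'   use [fold_roles()] to get train/validation/test patient sets.
#' @export
patientwise_kfold <- function(manifest, k = 10L, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(manifest)), k >= 2)
  pats <- dplyr::distinct(tibble::as_tibble(manifest),
                          .data$patient_id, .data$label)
  if (any(duplicated(pats$patient_id)))
    stop("a patient_id appears under more than one class label")
  if (nrow(pats) < k)
    stop("fewer patients (", nrow(pats), ") than folds (", k, ")")
  set.seed(seed)
  pats <- pats[sample.int(nrow(pats)), ]
  pats <- dplyr::arrange(pats, .data$label)
  # deal class-ordered patients round-robin with one continuing counter:
  # folds stay within one patient of each other in total size and within
  # one patient per class (approximate class balance)
  pats$fold <- ((seq_len(nrow(pats)) - 1L) %% k) + 1L
  # validation patients: per test fold, 1/9 of the remaining patients
  val_sets <- lapply(seq_len(k), function(f) {
    rest <- pats$patient_id[pats$fold != f]
    n_val <- max(1L, round(length(rest) / 9))
    sample(rest, n_val)
  })
  structure(list(patients = pats, k = as.integer(k), val_sets = val_sets),
            class = "fold_assignment")
}

#' Train / validation / test patients of one fold
#'
#' @param assignment a [patientwise_kfold()] result.
#' @param fold fold index in `1..k`.
#' @return list with character vectors `train`, `validation`, `test`.
#' @export
fold_roles <- function(assignment, fold) {
  stopifnot(inherits(assignment, "fold_assignment"),
            fold >= 1, fold <= assignment$k)
  test <- assignment$patients$patient_id[assignment$patients$fold == fold]
  rest <- setdiff(assignment$patients$patient_id, test)
  val <- assignment$val_sets[[fold]]
  list(train = setdiff(rest, val), validation = val, test = test)
}

#' Confusion matrix and accuracy
#'
#' Tallies predictions against truths in the fixed class order AD,
#' psoriasis, tumor, control (rows = true class, columns = predicted).
#'
#' @param preds,truths character/factor vectors of class labels.
#' @return list with `confusion` (4 x 4 count matrix) and `accuracy`
#'   (trace / total).
#' @export
confusion_and_accuracy <- function(preds, truths) {
  if (length(preds) != length(truths))
    stop("preds and truths differ in length")
  bad <- setdiff(unique(c(preds, truths)), CLASS_LEVELS)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(truths, levels = CLASS_LEVELS),
              factor(preds, levels = CLASS_LEVELS))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(true = CLASS_LEVELS, pred = CLASS_LEVELS))
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

classifier_net_define <- function(input_px, n_classes = 4L) {
  net_define(c(input_px, input_px, 1L), list(
    list(type = "conv", k = 3, filters = 8L), list(type = "relu"),
    list(type = "maxpool"),
    list(type = "conv", k = 3, filters = 16L), list(type = "relu"),
    list(type = "maxpool"),
    list(type = "conv", k = 3, filters = 16L), list(type = "relu"),
    list(type = "dense", units = n_classes)))
}

# classifier input standardization: resize, then per-image z-score
standardize_input <- function(x, input_px) {
  x <- resize_bilinear(x, input_px, input_px)
  s <- stats::sd(x)
  if (s > 0) (x - mean(x)) / s else x * 0
}

#' Train the small CNN classifier
#'
#' Trains a 4-class softmax CNN (3 conv blocks, dense head) on standardized
#' ROI images with SGD-with-momentum and
#' cross-entropy loss. Each training draw is augmented per `augmentation`
#' before resizing to the network input.
#'
#' @param images list of numeric matrices (ROI images, original scale).
#' @param labels character vector of class labels (must contain at least
#'   two distinct classes; all four for the standard experiment).
#' @param augmentation `"Aug0"`, `"Aug1"`, or `"none"`.
#' @param input_px classifier input size (images are bilinearly resized,
#'   aspect-distorting, to `input_px x input_px`).
#' @param batch_size,max_epochs,lr,momentum SGDM training parameters.
#' @param seed RNG seed (weights, batching, augmentation).
#' @param classes class levels for the softmax head.
#' @param restarts maximum number of re-initializations if training fails to
#'   converge (resubstitution accuracy below 0.7 — an occasional bad weight
#'   draw kills all ReLU paths and the network collapses to one class).
#' @return an object of class `usconf_classifier` with the trained net, the
#'   class levels and a per-epoch loss log.
#' @export
train_classifier <- function(images, labels, augmentation = "Aug0",
                             input_px = 32L, batch_size = 8L,
                             max_epochs = 12L, lr = 0.01, momentum = 0.9,
                             seed = 1L, classes = CLASS_LEVELS,
                             restarts = 2L) {
  stopifnot(length(images) == length(labels), length(images) >= 2)
  labels <- as.character(labels)
  missing_cls <- setdiff(unique(labels), classes)
  if (length(missing_cls))
    stop("unknown class label(s): ", paste(missing_cls, collapse = ", "))
  if (length(unique(labels)) < 2)
    stop("training data must contain at least two classes")
  n <- length(images)
  y <- match(labels, classes)
  xs_plain <- lapply(images, standardize_input, input_px = input_px)
  attempt <- function(attempt_seed) {
    set.seed(attempt_seed)
    net <- classifier_net_define(as.integer(input_px), length(classes))
    vel <- vector("list", length(net$layers))
    log_rows <- vector("list", max_epochs)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1L, n)]
        acc <- NULL
        for (i in ids) {
          x <- if (augmentation %in% c("Aug0", "Aug1"))
            standardize_input(augment_image(images[[i]], augmentation),
                              input_px)
          else xs_plain[[i]]
          fw <- net_forward(net, x)
          logits <- as.vector(fw$acts[[length(fw$acts)]])
          p <- softmax(logits)
          ep_loss <- ep_loss - log(max(p[y[i]], 1e-12))
          dlog <- p; dlog[y[i]] <- dlog[y[i]] - 1
          bk <- net_backward(net, fw, array(dlog, dim = c(1, 1, length(p))))
          acc <- accumulate_grads(acc, bk$grads)
        }
        st <- sgdm_step(net, scale_grads(acc, 1 / length(ids)), vel,
                        lr, momentum)
        net <- st$net; vel <- st$vel
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss / n)
    }
    list(net = net, log = dplyr::bind_rows(log_rows))
  }
  resub_acc <- function(net) {
    ok <- vapply(seq_len(n), function(i) {
      fw <- net_forward(net, xs_plain[[i]], keep = FALSE)
      which.max(as.vector(fw$acts[[length(fw$acts)]])) == y[i]
    }, logical(1))
    mean(ok)
  }
  used_restarts <- 0L
  fit <- attempt(seed)
  while (resub_acc(fit$net) < 0.7 && used_restarts < restarts) {
    used_restarts <- used_restarts + 1L
    fit <- attempt(seed + 7919L * used_restarts)
  }
  structure(list(net = fit$net, classes = classes,
                 input_px = as.integer(input_px), log = fit$log,
                 restarts_used = used_restarts),
            class = "usconf_classifier")
}

#' Predict classes with the trained classifier
#'
#' @param model a `usconf_classifier`.
#' @param images list of ROI image matrices.
#' @return tibble with columns `pred` (class label) and `logits`
#'   (list-column of numeric logit vectors).
#' @export
predict_classes <- function(model, images) {
  stopifnot(inherits(model, "usconf_classifier"))
  rows <- lapply(images, function(img) {
    x <- standardize_input(img, model$input_px)
    fw <- net_forward(model$net, x, keep = FALSE)
    logits <- as.vector(fw$acts[[length(fw$acts)]])
    tibble::tibble(pred = model$classes[which.max(logits)],
                   logits = list(logits))
  })
  dplyr::bind_rows(rows)
}

#' Configure a phantom experiment
#'
#' @param n_per_class,n_patients_per_class dataset size (see
#'   [generate_dataset()]).
#' @param roi_mode ROI extraction mode 0-4.
#' @param augmentation `"Aug0"` or `"Aug1"`.
#' @param folds number of patient-wise CV folds.
#' @param input_px classifier input size.
#' @param batch_size,max_epochs,lr,momentum classifier training parameters.
#' @param use_gt_masks use ground-truth phantom masks (`TRUE`, default) or a
#'   trained segmenter passed to [run_experiment()].
#' @param gel_band_px gel band height for [build_slm()].
#' @param percentile_method see [ccl_percentile()].
#' @param seed master seed: dataset, folds and training all derive from it.
#' @param ... passed to [phantom_spec()] via [generate_dataset()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_per_class = 100L, n_patients_per_class = 10L,
                              roi_mode = 4L, augmentation = c("Aug0", "Aug1"),
                              folds = 10L, input_px = 32L, batch_size = 8L,
                              max_epochs = 12L, lr = 0.01, momentum = 0.9,
                              use_gt_masks = TRUE, gel_band_px = 30L,
                              percentile_method = "linear", seed = 1L, ...) {
  augmentation <- match.arg(augmentation)
  stopifnot(folds >= 2, n_patients_per_class >= 1)
  if (n_patients_per_class * 4L < folds)
    stop("need at least `folds` patients in total")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_patients_per_class = as.integer(n_patients_per_class),
                 roi_mode = as.integer(roi_mode), augmentation = augmentation,
                 folds = as.integer(folds), input_px = as.integer(input_px),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 momentum = momentum, use_gt_masks = use_gt_masks,
                 gel_band_px = as.integer(gel_band_px),
                 percentile_method = percentile_method,
                 seed = as.integer(seed), phantom_args = list(...)),
            class = "experiment_config")
}

#' Run the end-to-end phantom experiment
#'
#' Generates a phantom dataset, builds per-sample skin layer maps, extracts
#' ROIs, and runs patient-wise k-fold cross-validation: per fold the CNN is
#' trained on the train+validation patients' ROIs and applied to the test
#' patients; Grad-CAM (for the predicted class) is aligned back to original
#' coordinates and combined with the SLM into a per-sample CCL. Per-sample
#' results pooled over all test folds feed the multicriteria evaluation.
#'
#' @param config an [experiment_config()].
#' @param segmenter optional `usconf_segmenter` used instead of ground-truth
#'   masks when `config$use_gt_masks` is `FALSE`.
#' @return an object of class `usconf_experiment`: `results` (per-sample
#'   tibble: `id`, `patient_id`, `fold`, `label`, `pred`, `correct`, `ccl`,
#'   `M`), `eval` (a `usconf_eval`), `fold_accuracy` (tibble), `confusion`
#'   and `confusion_popt` (4 x 4 matrices), `mean_ccl`, `accuracy`,
#'   `skipped` (tibble of skipped samples), `config`.
#' @export
run_experiment <- function(config, segmenter = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!config$use_gt_masks && is.null(segmenter))
    stop("use_gt_masks = FALSE requires a trained segmenter")
  ds <- do.call(generate_dataset,
                c(list(n_per_class = config$n_per_class,
                       n_patients_per_class = config$n_patients_per_class,
                       seed = config$seed), config$phantom_args))
  samples <- ds$samples
  rspec <- roi_spec(config$roi_mode)
  skipped <- list()
  prep <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    mask <- if (config$use_gt_masks) s$mask else
      tryCatch(segment_epidermis(segmenter, s$image), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(id = s$id, reason = "empty segmentation mask")
      next
    }
    slm <- build_slm(mask, s$axial_res, config$gel_band_px)
    roi <- extract_roi(s$image, mask, slm, rspec, s$axial_res)
    prep[[i]] <- list(sample = s, slm = slm, roi = roi)
  }
  keep <- !vapply(prep, is.null, logical(1))
  if (mean(!keep) > 0.10)
    stop("more than 10% of samples were skipped (",
         sum(!keep), "/", length(samples), ")")
  prep <- prep[keep]
  man <- ds$manifest[keep, ]
  assign_folds <- patientwise_kfold(man, config$folds,
                                    seed = config$seed + 1L)
  res_rows <- vector("list", length(prep))
  fold_rows <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    roles <- fold_roles(assign_folds, f)
    tr_pat <- c(roles$train, roles$validation)
    tr_idx <- which(man$patient_id %in% tr_pat)
    te_idx <- which(man$patient_id %in% roles$test)
    if (!length(te_idx)) next
    model <- train_classifier(
      images = lapply(prep[tr_idx], function(p) p$roi$image_roi),
      labels = man$label[tr_idx],
      augmentation = config$augmentation, input_px = config$input_px,
      batch_size = config$batch_size, max_epochs = config$max_epochs,
      lr = config$lr, momentum = config$momentum,
      seed = config$seed + 100L + f)
    for (i in te_idx) {
      p <- prep[[i]]
      x <- standardize_input(p$roi$image_roi, config$input_px)
      gc_map <- gradcam_raw(model$net, x)
      pred <- model$classes[gc_map$target_class]
      aligned <- align_map(normalize_map(gc_map$raw),
                           dim(p$sample$image), p$roi)
      cres <- ccl(confidence_map(aligned, p$slm))
      res_rows[[i]] <- tibble::tibble(
        id = p$sample$id, patient_id = p$sample$patient_id, fold = f,
        label = p$sample$label, pred = pred,
        correct = pred == p$sample$label, ccl = cres$t, M = cres$M)
    }
    fold_res <- dplyr::bind_rows(res_rows[te_idx])
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n = nrow(fold_res),
      accuracy = mean(fold_res$correct))
  }
  results <- dplyr::bind_rows(res_rows)
  ev <- evaluate_model(results$ccl, results$correct,
                       method = config$percentile_method)
  full_cm <- confusion_and_accuracy(results$pred, results$label)
  kept <- results$ccl > ev$t_opt
  popt_cm <- if (any(kept))
    confusion_and_accuracy(results$pred[kept], results$label[kept])
  else list(confusion = matrix(0L, 4, 4,
                               dimnames = list(true = CLASS_LEVELS,
                                               pred = CLASS_LEVELS)),
            accuracy = NA_real_)
  structure(list(results = results, eval = ev,
                 fold_accuracy = dplyr::bind_rows(fold_rows),
                 confusion = full_cm$confusion,
                 confusion_popt = popt_cm$confusion,
                 accuracy = full_cm$accuracy,
                 accuracy_popt = popt_cm$accuracy,
                 mean_ccl = mean(results$ccl),
                 skipped = if (length(skipped)) dplyr::bind_rows(skipped)
                           else tibble::tibble(id = character(),
                                               reason = character()),
                 config = config),
            class = "usconf_experiment")
}

#' @export
print.usconf_experiment <- function(x, ...) {
  cat(sprintf(paste0("<usconf_experiment> %d samples, ROI mode %d, %s\n",
                     "  accuracy %.3f | mean CCL %.3f | m = %.4f at p_opt = ",
                     "%d (a = %.3f over %.1f%%, t = %.3f)\n"),
              nrow(x$results), x$config$roi_mode, x$config$augmentation,
              x$accuracy, x$mean_ccl, x$eval$m, x$eval$p_opt, x$eval$a_opt,
              100 * x$eval$coverage, x$eval$t_opt))
  invisible(x)
}

#' Tidy per-sample experiment results
#'
#' @param x a `usconf_experiment`.
#' @param ... unused.
#' @return the per-sample results tibble.
#' @export
tidy.usconf_experiment <- function(x, ...) x$results

#' One-row experiment summary
#'
#' @param x a `usconf_experiment`.
#' @param ... unused.
#' @return a one-row tibble: `accuracy`, `mean_ccl`, `m`, `p_opt`, `a_opt`,
#'   `coverage`, `t_opt`, `accuracy_popt`, `n`, `n_skipped`.
#' @export
glance.usconf_experiment <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, mean_ccl = x$mean_ccl,
                 m = x$eval$m, p_opt = x$eval$p_opt, a_opt = x$eval$a_opt,
                 coverage = x$eval$coverage, t_opt = x$eval$t_opt,
                 accuracy_popt = x$accuracy_popt, n = nrow(x$results),
                 n_skipped = nrow(x$skipped))
}

#' Plot the experiment's percentile sweep
#'
#' @param object a `usconf_experiment`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.usconf_experiment <- function(object, ...) {
  autoplot.usconf_eval(object$eval) +
    ggplot2::labs(subtitle = sprintf("ROI mode %d, %s, %d samples",
                                     object$config$roi_mode,
                                     object$config$augmentation,
                                     nrow(object$results)))
}

#' Write experiment report files
#'
#' Writes `accuracy.csv` (per fold), `ccl.csv` (per sample), `sweep.csv`,
#' `summary.json`, `confusion_full.csv`, `confusion_popt.csv` and a sweep
#' figure `sweep.png` into `dir`.
#'
#' @param experiment a `usconf_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(experiment, dir) {
  stopifnot(inherits(experiment, "usconf_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(experiment$fold_accuracy,
                   file.path(dir, "accuracy.csv"), row.names = FALSE)
  utils::write.csv(experiment$results, file.path(dir, "ccl.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$eval$sweep, file.path(dir, "sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$confusion),
                   file.path(dir, "confusion_full.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$confusion_popt),
                   file.path(dir, "confusion_popt.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(glance(experiment)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  p <- autoplot.usconf_experiment(experiment)
  grDevices::png(file.path(dir, "sweep.png"), width = 900, height = 700)
  print(p)
  grDevices::dev.off()
  invisible(dir)
}
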