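#' Tier-1 incomplete-wing classifier
#'
#' The first tier is a binary classifier that labels a wing image 1 when it
#' is incomplete (missing landmark 4 or 6, or the wing absent) and 0 when
#' complete, so that only complete wings reach landmark localisation. The
#' network ends in a single fully connected output unit with a sigmoid, and
#' is trained with binary cross-entropy under Adam (learning rate 1e-4,
#' 30 epochs, batch size 50 in the reference protocol), keeping the weights
#' at the lowest validation loss. `tiny_test_net` — a few convolution blocks
#' — runs the whole protocol on a CPU; the named ImageNet backbones
#' (`vgg16_bn`, `resnet18`, `inception_v3`) are heavy configurations that
#' require pretrained weights and are accepted by the config surface only.
#'
#' @param backbone one of `"tiny_test_net"`, `"vgg16_bn"`, `"resnet18"`,
#'   `"inception_v3"`.
#' @param input_size square model input size in pixels; defaults to 32 for
#'   `tiny_test_net`, 224 for `vgg16_bn`/`resnet18`, 299 for `inception_v3`.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param pretrained use ImageNet-pretrained weights (unsupported for
#'   `tiny_test_net`).
#' @param augment an [aug_config()]; augmentation is always available for
#'   tier-1 training and reuses the tier-2 intervals.
#' @param seed integer seed fixing initialisation, shuffling and
#'   augmentation draws.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(backbone = "tiny_test_net", input_size = NULL,
                              lr = 1e-4, epochs = 30L, batch_size = 50L,
                              pretrained = FALSE, augment = aug_config(),
                              seed = NULL) {
  backbone <- match.arg(backbone,
                        c("tiny_test_net", "vgg16_bn", "resnet18", "inception_v3"))
  default_size <- switch(backbone, tiny_test_net = 32L, inception_v3 = 299L, 224L)
  input_size <- as.integer(input_size %||% default_size)
  if (backbone == "inception_v3" && input_size != 299L) {
    stop_wingmark("inception_v3 requires a 299 x 299 input")
  }
  if (backbone %in% c("vgg16_bn", "resnet18") && input_size != 224L) {
    stop_wingmark("%s requires a 224 x 224 input", backbone)
  }
  structure(list(backbone = backbone, input_size = input_size, lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 pretrained = pretrained, augment = augment, seed = seed),
            class = "classifier_config")
}

#' @rdname classifier_config
#' @param config a `classifier_config`.
#' @return `build_classifier()`: an untrained model mapping a 3-channel
#'   square input to a single logit (a sigmoid gives a score in (0, 1)).
#' @export
build_classifier <- function(config = classifier_config()) {
  if (config$backbone != "tiny_test_net") {
    stop_wingmark(paste0(
      "backbone '%s' needs pretrained ImageNet weights, which this build ",
      "does not ship; use backbone = 'tiny_test_net'"), config$backbone)
  }
  s <- config$input_size
  if (s %% 8 != 0) stop_wingmark("tiny_test_net input_size must be divisible by 8")
  with_seed(config$seed, tn_model(
    tn_conv(3, 8, 3, 2, 1), tn_relu(),
    tn_conv(8, 16, 3, 2, 1), tn_relu(),
    tn_conv(16, 16, 3, 2, 1), tn_relu(),
    tn_flatten(),
    tn_dense((s / 8)^2 * 16, 1)
  ))
}

# Resize a list of grayscale images to model resolution.
prep_model_images <- function(images, input_size) {
  lapply(images, function(img) resize_image(img, input_size, input_size))
}

# Stack resized grayscale images into an (s, s, 3, B) tensor, replicating
# the single channel (3-channel ingestion contract).
stack_3ch <- function(imgs) {
  s <- nrow(imgs[[1]])
  b <- length(imgs)
  x <- array(0, c(s, s, 3, b))
  for (i in seq_len(b)) {
    x[, , 1, i] <- imgs[[i]]
    x[, , 2, i] <- imgs[[i]]
    x[, , 3, i] <- imgs[[i]]
  }
  x
}

#' Train the tier-1 classifier
#'
#' @param model an untrained model from [build_classifier()].
#' @param train,val tibbles with list-column `image` and column `label`
#'   (1 incomplete, 0 complete); the splits must be disjoint and each
#'   contain both classes (training data is curated to an even class
#'   balance).
#' @param config the `classifier_config` used to build the model.
#' @return a `wing_classifier_fit` with elements `model`, `history`
#'   (per-epoch train/val loss), `best_val` and `config`. The checkpoint is
#'   the minimum-validation-loss weights.
#' @export
train_classifier <- function(model, train, val, config = classifier_config()) {
  if (nrow(train) == 0 || nrow(val) == 0) stop_wingmark("empty train or val split")
  if (length(unique(train$label)) < 2) {
    stop_wingmark("training set contains a single class; need both complete and incomplete wings")
  }
  s <- config$input_size
  tr_imgs <- prep_model_images(train$image, s)
  val_x <- stack_3ch(prep_model_images(val$image, s))
  val_y <- array(rep(val$label, each = 1), c(1, nrow(val)))
  y <- matrix(train$label, 1)
  aug_on <- isTRUE(config$augment$enabled)
  batch_fn <- function(idx) {
    imgs <- tr_imgs[idx]
    if (aug_on) {
      imgs <- lapply(imgs, function(img) {
        a <- sample_augmentation(config$augment)
        warp_affine(img, augmentation_matrix(a, ncol(img), nrow(img)))
      })
    }
    list(x = stack_3ch(imgs), y = y[, idx, drop = FALSE])
  }
  fit <- with_seed(config$seed, tn_fit(
    model, x = NULL, y = NULL, val_x = val_x, val_y = val_y,
    loss = "bce",
    schedule = list(list(epochs = config$epochs, lr = config$lr)),
    batch_size = config$batch_size, batch_fn = batch_fn, n = nrow(train)
  ))
  structure(list(model = fit$model, history = fit$history,
                 best_val = fit$best_val, config = config),
            class = "wing_classifier_fit")
}

#' @rdname train_classifier
#' @param fit a `wing_classifier_fit`.
#' @param images list of H x W image matrices (left-oriented).
#' @param names optional image names.
#' @param threshold sigmoid score threshold for the incomplete label.
#' @return `predict_classifier()`: tibble `(name, score, label)`.
#' @export
predict_classifier <- function(fit, images, names = NULL, threshold = 0.5) {
  x <- stack_3ch(prep_model_images(images, fit$config$input_size))
  z <- tn_predict(fit$model, x)
  score <- as.numeric(tn_sigmoid_fn(z))
  tibble::tibble(
    name = names %||% sprintf("img%04d", seq_along(images)),
    score = score,
    label = as.integer(score >= threshold)
  )
}

#' @exportS3Method generics::tidy
tidy.wing_classifier_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.wing_classifier_fit <- function(x, ...) {
  tibble::tibble(
    backbone = x$config$backbone,
    epochs = nrow(x$history),
    best_val_loss = x$best_val,
    n_params = tn_n_params(x$model)
  )
}

binary_counts <- function(pred, lab) {
  c(tp = sum(pred == 1 & lab == 1), tn = sum(pred == 0 & lab == 0),
    fp = sum(pred == 1 & lab == 0), fn = sum(pred == 0 & lab == 1))
}

metrics_from_counts <- function(tp, tn, fp, fn) {
  div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), NA_real_)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  cbind(sensitivity = sens, specificity = spec, precision = prec,
        f1 = f1, accuracy = acc)
}

#' Bootstrap confidence intervals for classification metrics
#'
#' Sensitivity, specificity, precision, F1 and accuracy with percentile 95%
#' confidence intervals obtained by resampling the test-set predictions with
#' replacement (by default 205 draws, 5000 times). Resamples in which a
#' metric is undefined (e.g. precision with no predicted positives) are
#' excluded from that metric's percentiles rather than imputed.
#'
#' @param predictions predicted scores (thresholded at `threshold`) or hard
#'   0/1 labels.
#' @param labels true 0/1 labels.
#' @param n_boot number of bootstrap resamples.
#' @param resample_size draws per resample.
#' @param threshold score threshold.
#' @param conf confidence level for the percentile interval.
#' @param seed integer seed for the resampling.
#' @return a `classification_metrics` tibble:
#'   `(metric, estimate, lower, upper, n_defined)`.
#' @export
bootstrap_metrics <- function(predictions, labels, n_boot = 5000L,
                              resample_size = 205L, threshold = 0.5,
                              conf = 0.95, seed = NULL) {
  stopifnot(length(predictions) == length(labels), length(labels) >= 1)
  pred <- as.integer(predictions >= threshold)
  lab <- as.integer(labels)
  n <- length(lab)
  point <- do.call(metrics_from_counts, as.list(binary_counts(pred, lab)))
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * resample_size, replace = TRUE),
                  resample_size, n_boot)
    pm <- matrix(pred[idx], resample_size, n_boot)
    lm_ <- matrix(lab[idx], resample_size, n_boot)
    tp <- colSums(pm == 1 & lm_ == 1)
    tn <- colSums(pm == 0 & lm_ == 0)
    fp <- colSums(pm == 1 & lm_ == 0)
    fn <- colSums(pm == 0 & lm_ == 1)
    metrics_from_counts(tp, tn, fp, fn)
  })
  a <- (1 - conf) / 2
  out <- tibble::tibble(
    metric = colnames(point),
    estimate = as.numeric(point[1, ]),
    lower = vapply(colnames(point), function(m) {
      v <- boot[, m]; v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else as.numeric(quantile(v, a))
    }, numeric(1)),
    upper = vapply(colnames(point), function(m) {
      v <- boot[, m]; v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else as.numeric(quantile(v, 1 - a))
    }, numeric(1)),
    n_defined = vapply(colnames(point), function(m) sum(!is.na(boot[, m])),
                       numeric(1))
  )
  structure(out, class = c("classification_metrics", class(out)),
            n_boot = n_boot, resample_size = resample_size, conf = conf)
}
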