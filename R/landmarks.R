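#' Tier-2 landmark localisation heads
#'
#' Two heads localise the 11 landmarks on complete, left-oriented wings.
#' The *regression* head maps the image to 22 outputs (an x and y per
#' landmark, normalised to `[0, 1]` by the model input dimensions) and is
#' trained with MSE over two sessions (reference schedule: 100 epochs at
#' lr 0.001, then 100 at 0.0001). The *segmentation* head predicts 11
#' activation maps at input resolution, trained from scratch with the
#' average of binary cross-entropy and dice loss against binary disk
#' targets (a filled disk of radius R centred on each landmark); a
#' coordinate is read off each map as the unweighted centroid of all pixels
#' whose value is at least the seventh-highest pixel value. Both heads keep
#' the minimum-validation-loss checkpoint, and predictions are rescaled to
#' native image space with per-axis factors.
#'
#' @name landmark_models
NULL

#' Configuration for the tier-2 heads
#'
#' @param head `"regression"` or `"segmentation"`.
#' @param input_size square model input size (reference 224; tiny default 32).
#' @param backbone `"tiny_test_net"` (CPU-scale) or `"resnet50"` (requires
#'   pretrained weights; config surface only).
#' @param schedule list of training sessions `list(epochs =, lr =)`;
#'   defaults follow the reference protocol scaled to the tiny setting.
#' @param batch_size minibatch size (reference protocol leaves it open;
#'   default 16).
#' @param disk_radius segmentation disk radius R in model-space pixels.
#' @param dice_eps smoothing constant in the dice loss.
#' @param augment an [aug_config()]; set `enabled = FALSE` to train without
#'   augmentation.
#' @param pretrained use ImageNet-pretrained backbone weights (regression
#'   only in the reference protocol; unsupported for `tiny_test_net`).
#' @param seed integer seed.
#' @return a `landmark_config` list.
#' @export
landmark_config <- function(head = c("regression", "segmentation"),
                            input_size = 32L, backbone = "tiny_test_net",
                            schedule = NULL, batch_size = 16L,
                            disk_radius = 5, dice_eps = 1,
                            augment = aug_config(), pretrained = FALSE,
                            seed = NULL) {
  head <- match.arg(head)
  backbone <- match.arg(backbone, c("tiny_test_net", "resnet50"))
  if (is.null(schedule)) {
    schedule <- if (head == "regression") {
      list(list(epochs = 30L, lr = 1e-3), list(epochs = 10L, lr = 1e-4))
    } else {
      list(list(epochs = 30L, lr = 1e-3))
    }
  }
  structure(list(head = head, input_size = as.integer(input_size),
                 backbone = backbone, schedule = schedule,
                 batch_size = as.integer(batch_size),
                 disk_radius = disk_radius, dice_eps = dice_eps,
                 augment = augment, pretrained = pretrained, seed = seed),
            class = "landmark_config")
}

#' @rdname landmark_config
#' @param config a `landmark_config`.
#' @return `build_landmark_model()`: an untrained model. The regression
#'   head ends in one convolutional layer followed by a fully connected
#'   layer of 22 outputs; the segmentation head is fully convolutional with
#'   11 output channels at input resolution.
#' @export
build_landmark_model <- function(config) {
  if (config$backbone != "tiny_test_net") {
    stop_wingmark(paste0(
      "backbone '%s' needs pretrained ImageNet weights, which this build ",
      "does not ship; use backbone = 'tiny_test_net'"), config$backbone)
  }
  s <- config$input_size
  if (s %% 4 != 0) stop_wingmark("input_size must be divisible by 4")
  with_seed(config$seed, {
    if (config$head == "regression") {
      tn_model(
        tn_conv(3, 8, 3, 2, 1), tn_relu(),
        tn_conv(8, 16, 3, 2, 1), tn_relu(),
        tn_conv(16, 16, 3, 1, 1), tn_relu(),   # the added conv layer
        tn_flatten(),
        tn_dense((s / 4)^2 * 16, 22)
      )
    } else {
      tn_model(
        tn_conv(3, 8, 3, 2, 1), tn_relu(),
        tn_conv(8, 16, 3, 2, 1), tn_relu(),
        tn_conv(16, 16, 3, 1, 1), tn_relu(),
        tn_upsample(2),
        tn_conv(16, 8, 3, 1, 1), tn_relu(),
        tn_upsample(2),
        tn_conv(8, 11, 3, 1, 1)
      )
    }
  })
}

#' Binary disk segmentation targets
#'
#' Builds the 11-channel training label for the segmentation head: each
#' channel is a binary image (at model resolution) with value 1 exactly on
#' the pixels within distance R of that landmark's model-space position.
#' Disks at the frame edge are clipped; disks of different landmarks may
#' overlap across channels.
#'
#' @param landmarks a landmark set in native pixel space.
#' @param native_size `(H, W)` of the native image.
#' @param model_size `(H, W)` of the model input.
#' @param R disk radius in model-space pixels (must be >= 1).
#' @return array `(H_model, W_model, 11)` of 0/1 values.
#' @export
make_disk_targets <- function(landmarks, native_size, model_size = c(224L, 224L),
                              R = 5) {
  if (R < 1) stop_wingmark("disk radius R must be at least 1 pixel")
  pts <- rescale_points(landmarks, from = native_size, to = model_size)
  h <- model_size[1]; w <- model_size[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  maps <- array(0, c(h, w, 11))
  for (k in 1:11) {
    maps[, , k] <- ((xs - pts[k, 1])^2 + (ys - pts[k, 2])^2 <= R^2) * 1
  }
  maps
}

#' Map-to-coordinate inference: seventh-highest-value centroid
#'
#' Converts one activation map into a coordinate: let v7 be the seventh
#' value of the map's pixel multiset sorted in decreasing order (duplicates
#' counted); the landmark is the unweighted centroid of all pixels with
#' value >= v7. The rule always produces a coordinate, even when no
#' landmark is present — a constant map yields the centroid of the full
#' pixel grid, `((W-1)/2, (H-1)/2)`.
#'
#' @param map numeric H x W matrix of finite activations.
#' @return length-2 vector `(x, y)` in 0-based model space.
#' @export
infer_landmark_from_map <- function(map) {
  stopifnot(all(is.finite(map)))
  v <- as.vector(map)
  v7 <- sort(v, decreasing = TRUE)[min(7L, length(v))]
  sel <- which(map >= v7, arr.ind = TRUE)
  c(x = mean(sel[, 2]) - 1, y = mean(sel[, 1]) - 1)
}

#' Averaged BCE + dice loss on probability maps
#'
#' `(BCE + dice)/2` where dice loss is
#' `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` computed per channel
#' and averaged. This is the reporting-side counterpart of the training
#' loss (which works on logits); both agree on probability inputs.
#'
#' @param pred_maps,target_maps arrays `(H, W, C)` or `(H, W, C, B)` with
#'   predictions in `[0, 1]` and binary targets.
#' @param eps dice smoothing constant.
#' @return scalar loss.
#' @export
combined_loss <- function(pred_maps, target_maps, eps = 1) {
  if (!identical(dim(pred_maps), dim(target_maps))) {
    stop_wingmark("prediction and target map shapes differ")
  }
  p <- clamp(pred_maps, 1e-12, 1 - 1e-12)
  bce <- -mean(target_maps * log(p) + (1 - target_maps) * log(1 - p))
  d <- dim(pred_maps)
  pm <- matrix(pred_maps, nrow = d[1] * d[2])
  tm <- matrix(target_maps, nrow = d[1] * d[2])
  dice <- mean(1 - (2 * colSums(pm * tm) + eps) /
                 (colSums(pm) + colSums(tm) + eps))
  (bce + dice) / 2
}

encode_regression_targets <- function(landmarks_list, native_size, model_size) {
  t(vapply(landmarks_list, function(l) {
    p <- rescale_points(l, from = native_size, to = model_size)
    c(p[, 1] / model_size[2], p[, 2] / model_size[1])
  }, numeric(22)))
}

decode_regression_output <- function(out, native_size, model_size) {
  # out: 22-vector (x1..x11, y1..y11 in normalised model space)
  pts <- cbind(out[1:11] * model_size[2], out[12:22] * model_size[1])
  landmark_set(rescale_points(pts, from = model_size, to = native_size))
}

#' Train a tier-2 landmark model
#'
#' @param train,val tibbles with list-columns `image` and `landmarks`
#'   (complete wings only; all landmarks valid and in-frame).
#' @param config a [landmark_config()].
#' @return a `landmark_fit` with elements `model`, `history`, `best_val`,
#'   `config` and `native_size`.
#' @export
train_landmark_model <- function(train, val, config) {
  if (nrow(train) == 0 || nrow(val) == 0) stop_wingmark("empty train or val split")
  model <- build_landmark_model(config)
  s <- config$input_size
  native_size <- dim(train$image[[1]])
  model_size <- c(s, s)
  tr_imgs <- prep_model_images(train$image, s)
  # landmarks in model space, kept as matrices for per-batch augmentation
  tr_lmk <- lapply(train$landmarks, function(l) {
    rescale_points(l, from = native_size, to = model_size)
  })
  val_x <- stack_3ch(prep_model_images(val$image, s))
  aug_on <- isTRUE(config$augment$enabled)
  augment_pair <- function(img, lmk) {
    # resample once if a landmark leaves the frame, then fall back to the
    # untransformed pair
    for (attempt in 1:2) {
      a <- sample_augmentation(config$augment)
      A <- augmentation_matrix(a, ncol(img), nrow(img))
      pts <- aff_apply(A, lmk)
      if (all(pts[, 1] >= 0 & pts[, 1] <= ncol(img) - 1 &
                pts[, 2] >= 0 & pts[, 2] <= nrow(img) - 1)) {
        return(list(image = warp_affine(img, A), lmk = pts))
      }
    }
    list(image = img, lmk = lmk)
  }
  if (config$head == "regression") {
    enc_y <- function(lmks) {
      t(vapply(lmks, function(p) c(p[, 1] / s, p[, 2] / s), numeric(22)))
    }
    val_y <- t(enc_y(lapply(val$landmarks, function(l) {
      rescale_points(l, from = native_size, to = model_size)
    })))
    batch_fn <- function(idx) {
      imgs <- tr_imgs[idx]; lmks <- tr_lmk[idx]
      if (aug_on) {
        pairs <- Map(augment_pair, imgs, lmks)
        imgs <- lapply(pairs, `[[`, "image")
        lmks <- lapply(pairs, `[[`, "lmk")
      }
      list(x = stack_3ch(imgs), y = t(enc_y(lmks)))
    }
    loss <- "mse"
  } else {
    disk_y <- function(lmks) {
      arr <- array(0, c(s, s, 11, length(lmks)))
      for (i in seq_along(lmks)) {
        arr[, , , i] <- make_disk_targets(
          landmark_set(lmks[[i]]), native_size = model_size,
          model_size = model_size, R = config$disk_radius)
      }
      arr
    }
    val_y <- disk_y(lapply(val$landmarks, function(l) {
      rescale_points(l, from = native_size, to = model_size)
    }))
    batch_fn <- function(idx) {
      imgs <- tr_imgs[idx]; lmks <- tr_lmk[idx]
      if (aug_on) {
        pairs <- Map(augment_pair, imgs, lmks)
        imgs <- lapply(pairs, `[[`, "image")
        lmks <- lapply(pairs, `[[`, "lmk")
      }
      list(x = stack_3ch(imgs), y = disk_y(lmks))
    }
    loss <- "bce_dice"
  }
  fit <- with_seed(config$seed, tn_fit(
    model, x = NULL, y = NULL, val_x = val_x, val_y = val_y, loss = loss,
    schedule = config$schedule, batch_size = config$batch_size,
    batch_fn = batch_fn, dice_eps = config$dice_eps, n = nrow(train)
  ))
  structure(list(model = fit$model, history = fit$history,
                 best_val = fit$best_val, config = config,
                 native_size = native_size),
            class = "landmark_fit")
}

#' Predict landmarks with a trained tier-2 model
#'
#' Model outputs are mapped back to native image coordinates (per-axis
#' factors `W_native/W_model`, `H_native/H_model`). The segmentation head
#' first passes each output map through a sigmoid and applies
#' [infer_landmark_from_map()] per channel.
#'
#' @param fit a `landmark_fit`.
#' @param images list of H x W native-space image matrices.
#' @param names optional image names.
#' @return a landmark table (`name, x1..x11, y1..y11`) in native space.
#' @export
predict_landmarks <- function(fit, images, names = NULL) {
  s <- fit$config$input_size
  native_size <- dim(images[[1]])
  x <- stack_3ch(prep_model_images(images, s))
  out <- tn_predict(fit$model, x)
  lmks <- if (fit$config$head == "regression") {
    lapply(seq_len(ncol(out)), function(i) {
      decode_regression_output(out[, i], native_size, c(s, s))
    })
  } else {
    p <- tn_sigmoid_fn(out)
    lapply(seq_len(dim(p)[4]), function(i) {
      pts <- t(vapply(1:11, function(k) infer_landmark_from_map(p[, , k, i]),
                      numeric(2)))
      landmark_set(rescale_points(pts, from = c(s, s), to = native_size))
    })
  }
  landmark_table(lmks, names %||% sprintf("img%04d", seq_along(images)))
}

#' @exportS3Method generics::tidy
tidy.landmark_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.landmark_fit <- function(x, ...) {
  tibble::tibble(
    head = x$config$head,
    sessions = length(x$config$schedule),
    epochs = nrow(x$history),
    best_val_loss = x$best_val,
    n_params = tn_n_params(x$model)
  )
}

#' Mean-location baseline predictor
#'
#' The reference baseline predicts, for every test image, the per-landmark
#' mean position over the training annotations (native space). Its error
#' reflects the pose variation of the wings and is the bar both trained
#' heads must beat.
#'
#' @param train_landmarks list of landmark sets (native space), or a
#'   landmark table.
#' @return a `baseline_predictor`; call [predict_baseline()] to apply it.
#' @export
baseline_mean_location <- function(train_landmarks) {
  if (is.data.frame(train_landmarks)) {
    train_landmarks <- table_to_landmarks(train_landmarks)
  }
  if (!length(train_landmarks)) stop_wingmark("need at least one training example")
  mean_lmk <- Reduce(`+`, train_landmarks) / length(train_landmarks)
  structure(list(mean = landmark_set(mean_lmk),
                 n_train = length(train_landmarks)),
            class = "baseline_predictor")
}

#' @rdname baseline_mean_location
#' @param baseline a `baseline_predictor`.
#' @param names image names for the output rows.
#' @return `predict_baseline()`: a landmark table repeating the mean
#'   location for every name.
#' @export
predict_baseline <- function(baseline, names) {
  landmark_table(rep(list(baseline$mean), length(names)), names)
}
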