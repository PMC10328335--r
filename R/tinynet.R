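#' @keywords internal
#' @name tinynet
#' @title Minimal neural-network engine
#'
#' @description
#' A small, self-contained neural-network engine used by the tier-1 classifier
#' and the tier-2 landmark heads. It supports 2-D convolutions, dense layers,
#' ReLU, nearest-neighbour upsampling and flattening, trained with Adam under
#' binary cross-entropy, mean-squared-error, or averaged BCE+dice losses.
#' Image tensors use dimension order (H, W, C, B); dense activations are
#' (features, B) matrices. All parameters live in plain R arrays so that
#' checkpoints are ordinary R objects and every gradient can be checked
#' numerically (see the test suite).
NULL

tn_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  sd <- sqrt(2 / (kernel * kernel * in_ch))
  list(
    type = "conv",
    W = array(stats::rnorm(kernel * kernel * in_ch * out_ch, sd = sd),
              dim = c(kernel, kernel, in_ch, out_ch)),
    b = numeric(out_ch),
    kernel = as.integer(kernel), stride = as.integer(stride),
    pad = as.integer(pad)
  )
}

tn_dense <- function(n_in, n_out) {
  list(
    type = "dense",
    W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
    b = numeric(n_out)
  )
}

tn_relu <- function() list(type = "relu")
tn_flatten <- function() list(type = "flatten")
tn_gap <- function() list(type = "gap")   # global average pooling -> (C, B)
tn_upsample <- function(factor = 2L) list(type = "upsample", factor = as.integer(factor))

tn_model <- function(...) {
  structure(list(layers = list(...)), class = "tn_model")
}

tn_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# Convolution via a loop over the kernel offsets: each offset contributes one
# (oh*ow*B, C_in) x (C_in, C_out) matrix product.
tn_conv_forward <- function(layer, x) {
  d <- dim(x)
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  xp <- tn_pad(x, p)
  oh <- (d[1] + 2 * p - k) %/% s + 1L
  ow <- (d[2] + 2 * p - k) %/% s + 1L
  cin <- d[3]; b <- d[4]; cout <- length(layer$b)
  acc <- matrix(rep(layer$b, each = oh * ow * b), oh * ow * b, cout)
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = s, length.out = oh)
    for (kj in seq_len(k)) {
      rj <- seq.int(kj, by = s, length.out = ow)
      xs <- xp[ri, rj, , , drop = FALSE]
      m <- matrix(aperm(xs, c(1, 2, 4, 3)), ncol = cin)
      wk <- matrix(layer$W[ki, kj, , ], nrow = cin)
      acc <- acc + m %*% wk
    }
  }
  out <- aperm(array(acc, c(oh, ow, b, cout)), c(1, 2, 4, 3))
  list(out = out, cache = list(x = x, xp_dim = dim(xp)))
}

tn_conv_backward <- function(layer, cache, dout) {
  d <- dim(cache$x)
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  xp <- tn_pad(cache$x, p)
  od <- dim(dout)
  oh <- od[1]; ow <- od[2]; cout <- od[3]; b <- od[4]
  cin <- d[3]
  dout2 <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = cout)
  dW <- array(0, dim(layer$W))
  dxp <- array(0, dim(xp))
  for (ki in seq_len(k)) {
    ri <- seq.int(ki, by = s, length.out = oh)
    for (kj in seq_len(k)) {
      rj <- seq.int(kj, by = s, length.out = ow)
      xs <- xp[ri, rj, , , drop = FALSE]
      m <- matrix(aperm(xs, c(1, 2, 4, 3)), ncol = cin)
      wk <- matrix(layer$W[ki, kj, , ], nrow = cin)
      dW[ki, kj, , ] <- crossprod(m, dout2)
      dm <- dout2 %*% t(wk)
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] +
        aperm(array(dm, c(oh, ow, b, cin)), c(1, 2, 4, 3))
    }
  }
  dx <- if (p > 0L) {
    dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = colSums(dout2))
}

tn_layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = tn_conv_forward(layer, x),
    dense = list(out = layer$W %*% x + layer$b, cache = list(x = x)),
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    flatten = {
      d <- dim(x)
      list(out = matrix(x, ncol = d[4]), cache = list(dim = d))
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, nrow = d[1] * d[2])           # (HW, C*B)
      list(out = matrix(colMeans(m), d[3], d[4]), cache = list(dim = d))
    },
    upsample = {
      d <- dim(x); f <- layer$factor
      out <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
               drop = FALSE]
      list(out = out, cache = list(dim = d))
    },
    stop("unknown layer type: ", layer$type)
  )
}

tn_layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = tn_conv_backward(layer, cache, dout),
    dense = list(
      dx = crossprod(layer$W, dout),
      dW = tcrossprod(dout, cache$x),
      db = rowSums(dout)
    ),
    relu = list(dx = dout * cache$mask),
    flatten = list(dx = array(dout, cache$dim)),
    gap = {
      d <- cache$dim
      dx <- array(rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx)
    },
    upsample = {
      d <- cache$dim; f <- layer$factor
      dx <- array(0, d)
      for (i in seq_len(f)) for (j in seq_len(f)) {
        dx <- dx + dout[seq.int(i, by = f, length.out = d[1]),
                        seq.int(j, by = f, length.out = d[2]), , ,
                        drop = FALSE]
      }
      list(dx = dx)
    }
  )
}

tn_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    step <- tn_layer_forward(model$layers[[i]], x)
    x <- step$out
    if (keep_cache) caches[[i]] <- step$cache
  }
  list(out = x, caches = caches)
}

tn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    g <- tn_layer_backward(model$layers[[i]], caches[[i]], dout)
    dout <- g$dx
    g$dx <- NULL
    grads[[i]] <- g
  }
  grads
}

tn_sigmoid_fn <- function(z) 1 / (1 + exp(-z))

# Numerically stable BCE on logits; value is the mean over all elements.
tn_loss_bce <- function(z, y) {
  n <- length(z)
  value <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  list(value = value, grad = (tn_sigmoid_fn(z) - y) / n)
}

tn_loss_mse <- function(pred, y) {
  n <- length(pred)
  list(value = sum((pred - y)^2) / n, grad = 2 * (pred - y) / n)
}

# Average of BCE and dice loss on logits; dice is computed per channel and
# per sample, then averaged ((1 - (2*sum(p*t)+eps)/(sum(p)+sum(t)+eps))).
tn_loss_bce_dice <- function(z, y, eps = 1) {
  d <- dim(z)
  stopifnot(length(d) == 4L)
  p <- tn_sigmoid_fn(z)
  n <- length(z)
  bce <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  pm <- matrix(p, nrow = d[1] * d[2])   # columns index (channel, sample)
  ym <- matrix(y, nrow = d[1] * d[2])
  s1 <- colSums(pm * ym)
  s2 <- colSums(pm) + colSums(ym)
  dice_cb <- 1 - (2 * s1 + eps) / (s2 + eps)
  dice <- mean(dice_cb)
  ncb <- ncol(pm)
  # d(dice_cb)/dp_i = -(2*y_i*(s2+eps) - (2*s1+eps)) / (s2+eps)^2
  num <- sweep(2 * ym, 2, s2 + eps, `*`)
  ddice_dp <- -sweep(num, 2, 2 * s1 + eps, `-`) / rep((s2 + eps)^2, each = d[1] * d[2])
  ddice_dp <- ddice_dp / ncb
  grad_p <- array(ddice_dp, d)
  grad <- 0.5 * (p - y) / n + 0.5 * grad_p * p * (1 - p)
  list(value = (bce + dice) / 2, grad = grad)
}

tn_loss <- function(kind, pred, y, eps = 1) {
  switch(kind,
    bce = tn_loss_bce(pred, y),
    mse = tn_loss_mse(pred, y),
    bce_dice = tn_loss_bce_dice(pred, y, eps = eps),
    stop("unknown loss: ", kind)
  )
}

tn_adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = array(0, dim(l$W) %||% length(l$W)), vW = array(0, dim(l$W) %||% length(l$W)),
           mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    } else NULL
  })
}

tn_adam_step <- function(model, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    if (is.null(state[[i]])) next
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mW_hat <- s$mW / (1 - beta1^t); vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t); vb_hat <- s$vb / (1 - beta2^t)
    model$layers[[i]]$W <- model$layers[[i]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

tn_slice_batch <- function(x, idx) {
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[, , , idx, drop = FALSE]
}

#' Train a tinynet model with Adam and min-validation-loss checkpointing
#'
#' Runs one or more training sessions (each a number of epochs at a fixed
#' learning rate). The weights achieving the lowest validation loss seen so
#' far are kept as the checkpoint; each new session starts from the best
#' weights of the previous one.
#'
#' @param model a `tn_model`.
#' @param x,y training inputs/targets ((H, W, C, B) arrays or (features, B)
#'   matrices).
#' @param val_x,val_y validation inputs/targets.
#' @param loss one of `"bce"`, `"mse"`, `"bce_dice"`.
#' @param schedule list of sessions, each `list(epochs =, lr =)`.
#' @param batch_size minibatch size.
#' @param batch_fn optional `function(idx)` returning `list(x =, y =)` for a
#'   minibatch; used for on-the-fly augmentation. Defaults to slicing `x`/`y`.
#' @param dice_eps smoothing constant for the dice term.
#' @return list with `model` (best checkpoint), `history` tibble
#'   (session, epoch, lr, train_loss, val_loss) and `best_val`.
#' @keywords internal
tn_fit <- function(model, x, y, val_x, val_y, loss = "mse",
                   schedule = list(list(epochs = 10, lr = 1e-3)),
                   batch_size = 16L, batch_fn = NULL, dice_eps = 1,
                   n = NULL, verbose = FALSE) {
  n <- n %||% (if (is.matrix(x)) ncol(x) else dim(x)[4])
  if (is.null(batch_fn)) {
    batch_fn <- function(idx) list(x = tn_slice_batch(x, idx),
                                   y = tn_slice_batch(y, idx))
  }
  history <- list()
  best <- list(model = model, val = Inf)
  state <- tn_adam_init(model)
  t_step <- 0L
  for (si in seq_along(schedule)) {
    sess <- schedule[[si]]
    model <- best$model   # sessions resume from the best checkpoint
    for (ep in seq_len(sess$epochs)) {
      ord <- sample.int(n)
      splits <- split(ord, ceiling(seq_along(ord) / batch_size))
      tr_loss <- 0
      for (idx in splits) {
        batch <- batch_fn(idx)
        fw <- tn_forward(model, batch$x, keep_cache = TRUE)
        l <- tn_loss(loss, fw$out, batch$y, eps = dice_eps)
        grads <- tn_backward(model, fw$caches, l$grad)
        t_step <- t_step + 1L
        upd <- tn_adam_step(model, grads, state, sess$lr, t_step)
        model <- upd$model; state <- upd$state
        tr_loss <- tr_loss + l$value * length(idx)
      }
      tr_loss <- tr_loss / n
      val_out <- tn_forward(model, val_x)$out
      val_loss <- tn_loss(loss, val_out, val_y, eps = dice_eps)$value
      if (val_loss < best$val) best <- list(model = model, val = val_loss)
      history[[length(history) + 1L]] <- tibble::tibble(
        session = si, epoch = ep, lr = sess$lr,
        train_loss = tr_loss, val_loss = val_loss
      )
      if (verbose) {
        message(sprintf("session %d epoch %3d  train %.5f  val %.5f",
                        si, ep, tr_loss, val_loss))
      }
    }
  }
  list(model = best$model, history = dplyr::bind_rows(history),
       best_val = best$val)
}

tn_predict <- function(model, x) tn_forward(model, x)$out

tn_n_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}
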