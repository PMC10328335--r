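test_that("disk targets contain exactly the lattice points within R of the landmark", {
  lmk <- landmark_set(cbind(x = seq(30, 80, length.out = 11),
                            y = seq(30, 80, length.out = 11)))
  # lattice-point enumeration oracle for an interior disk
  for (R in c(1, 5)) {
    tg <- make_disk_targets(lmk, native_size = c(128, 128),
                            model_size = c(128, 128), R = R)
    oracle <- sum(outer(-R:R, -R:R, function(dx, dy) dx^2 + dy^2 <= R^2))
    expect_equal(sum(tg[, , 1]), oracle)
  }
  expect_equal(sum(make_disk_targets(lmk, c(128, 128), c(128, 128), 1)[, , 1]), 5)
  expect_equal(sum(make_disk_targets(lmk, c(128, 128), c(128, 128), 5)[, , 1]), 81)
})

test_that("disks at the frame corner are clipped and R < 1 errors", {
  lmk <- landmark_set(cbind(c(0, seq(30, 80, length.out = 10)),
                            c(0, seq(30, 80, length.out = 10))))
  tg <- make_disk_targets(lmk, c(96, 96), c(96, 96), R = 5)
  expect_lt(sum(tg[, , 1]), 81)
  expect_gt(sum(tg[, , 1]), 0)
  expect_error(make_disk_targets(lmk, c(96, 96), c(96, 96), R = 0.5), "R")
})

test_that("seventh-highest-value inference recovers symmetric activations exactly", {
  # a filled binary disk: v7 = 1 selects the whole disk, centroid = centre
  m <- matrix(0, 100, 200)
  for (dx in -2:2) for (dy in -2:2) {
    if (dx^2 + dy^2 <= 4) m[51 + dy, 101 + dx] <- 1
  }
  expect_equal(unname(infer_landmark_from_map(m)), c(100, 50))
  # a constant map yields the full-grid centroid
  expect_equal(unname(infer_landmark_from_map(matrix(3, 10, 20))), c(9.5, 4.5))
})

test_that("inference equals a brute-force sort-select-average oracle on random maps", {
  brute <- function(map) {
    v7 <- sort(as.vector(map), decreasing = TRUE)[7]
    hits <- which(map >= v7)
    rows <- (hits - 1) %% nrow(map) + 1
    cols <- (hits - 1) %/% nrow(map) + 1
    c(mean(cols) - 1, mean(rows) - 1)
  }
  set.seed(11)
  for (i in 1:200) {
    map <- matrix(runif(24 * 30), 24, 30)
    expect_identical(unname(infer_landmark_from_map(map)), brute(map))
  }
  # off-lattice Gaussian bump: inferred point within 1 px of the true centre
  for (i in 1:20) {
    cx <- runif(1, 8, 22); cy <- runif(1, 8, 16)
    xs <- matrix(rep(0:29, each = 24), 24, 30)
    ys <- matrix(rep(0:23, 30), 24, 30)
    bump <- exp(-((xs - cx)^2 + (ys - cy)^2) / 4)
    got <- infer_landmark_from_map(bump)
    expect_identical(unname(got), brute(bump))
    expect_lt(sqrt((got[1] - cx)^2 + (got[2] - cy)^2), 1)
  }
})

test_that("inference is equivariant to integer translations and stays in the map", {
  set.seed(12)
  map <- matrix(0, 40, 50)
  map[10:20, 15:25] <- matrix(runif(121), 11, 11)
  p0 <- infer_landmark_from_map(map)
  shifted <- matrix(0, 40, 50)
  shifted[(10:20) + 7, (15:25) + 9] <- map[10:20, 15:25]
  p1 <- infer_landmark_from_map(shifted)
  expect_equal(unname(p1 - p0), c(9, 7))
  expect_true(p0[1] >= 0 && p0[1] <= 49 && p0[2] >= 0 && p0[2] <= 39)
})

test_that("combined loss matches an independent formula evaluation", {
  set.seed(13)
  d <- c(8, 8, 11)
  target <- array((runif(prod(d)) > 0.9) * 1, d)
  pred <- array(runif(prod(d)), d)
  # independent hand computation
  eps <- 1
  bce <- -mean(target * log(pred) + (1 - target) * log(1 - pred))
  dice <- mean(vapply(1:11, function(k) {
    p <- pred[, , k]; t <- target[, , k]
    1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1)))
  expect_equal(combined_loss(pred, target), (bce + dice) / 2, tolerance = 1e-12)
  expect_equal(combined_loss(target, target), 0, tolerance = 1e-6)
  expect_error(combined_loss(pred, target[, , 1:5]), "shape")
})

test_that("combined loss decreases monotonically from complement to exact target", {
  set.seed(14)
  target <- array(0, c(12, 12, 11))
  for (k in 1:11) target[sample(144, 8) + 144 * (k - 1)] <- 1
  lambdas <- seq(0, 1, by = 0.25)
  losses <- vapply(lambdas, function(l) {
    pred <- clamp((1 - l) * (1 - target) + l * target, 1e-6, 1 - 1e-6)
    combined_loss(pred, target)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # complement: the dice term alone approaches 1
  comp <- clamp(1 - target, 1e-9, 1 - 1e-9)
  pm <- matrix(comp, nrow = 144); tm <- matrix(target, nrow = 144)
  dice <- mean(1 - (2 * colSums(pm * tm) + 1) / (colSums(pm) + colSums(tm) + 1))
  expect_gt(dice, 0.98)
})

test_that("regression targets encode and decode as exact inverses", {
  wings <- landmark_wings()
  lmk <- wings$landmarks[[1]]
  native <- c(96, 120)
  enc <- wingmark:::encode_regression_targets(list(lmk), native, c(32, 32))
  dec <- wingmark:::decode_regression_output(as.numeric(enc), native, c(32, 32))
  expect_lt(max(abs(dec[, 1:2] - lmk[, 1:2])), 1e-6)
})

test_that("a zeroed regression head predicts the coordinate origin everywhere", {
  cfg <- landmark_config("regression", seed = 15)
  model <- build_landmark_model(cfg)
  nl <- length(model$layers)
  model$layers[[nl]]$W[] <- 0
  model$layers[[nl]]$b[] <- 0
  fit <- structure(list(model = model, config = cfg, native_size = c(96, 120)),
                   class = "landmark_fit")
  pred <- predict_landmarks(fit, list(matrix(0.2, 96, 120)), "a")
  expect_true(all(as.matrix(pred[, -1]) == 0))
})

test_that("a model emitting exact disk targets recovers the landmarks within half a pixel", {
  wings <- landmark_wings()
  lmk <- wings$landmarks[[2]]
  ms <- c(48, 48)
  pts <- rescale_points(lmk, from = c(96, 120), to = ms)
  maps <- make_disk_targets(lmk, native_size = c(96, 120), model_size = ms, R = 5)
  rec <- t(vapply(1:11, function(k) infer_landmark_from_map(maps[, , k]),
                  numeric(2)))
  expect_lt(max(sqrt(rowSums((rec - pts)^2))), 0.5)
})

test_that("the mean-location baseline averages the training coordinates", {
  wings <- landmark_wings()
  one <- baseline_mean_location(wings$landmarks[1])
  pred1 <- predict_baseline(one, "a")
  expect_equal(as_landmark_set(pred1[1, ])[1:11, 1:2],
               wings$landmarks[[1]][1:11, 1:2], ignore_attr = TRUE)
  expect_equal(glance(distance_errors(
    pred1, landmark_table(wings$landmarks[1], "a")))$mae, 0)
  two <- baseline_mean_location(wings$landmarks[1:2])
  mid <- (wings$landmarks[[1]] + wings$landmarks[[2]]) / 2
  expect_equal(two$mean[1:11, 1:2], mid[1:11, 1:2], ignore_attr = TRUE)
  expect_error(baseline_mean_location(list()), "at least one")
})

test_that("landmark fits expose a tidy training history", {
  fit <- regression_fit()
  h <- tidy(fit)
  expect_true(all(c("session", "epoch", "train_loss", "val_loss") %in% names(h)))
  expect_equal(glance(fit)$best_val_loss, min(h$val_loss))
  expect_equal(glance(fit)$head, "regression")
})
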