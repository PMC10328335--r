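test_that("generation is deterministic under a fixed seed", {
  s <- wing_spec(canvas_height = 96, canvas_width = 120, rng_seed = 7)
  w1 <- generate_wing(s)
  w2 <- generate_wing(s)
  expect_identical(w1$image, w2$image)
  expect_identical(w1$landmarks, w2$landmarks)
  w3 <- generate_wing(wing_spec(canvas_height = 96, canvas_width = 120,
                                rng_seed = 8))
  expect_false(identical(w1$image, w3$image))
})

test_that("rotation relates ground-truth landmarks by an exact rotation about the canvas centre", {
  s0 <- wing_spec(canvas_height = 128, canvas_width = 160, rotation = 0,
                  rng_seed = 1)
  sr <- wing_spec(canvas_height = 128, canvas_width = 160, rotation = 33,
                  rng_seed = 1)
  l0 <- generate_wing(s0, render = FALSE)$landmarks
  lr <- generate_wing(sr, render = FALSE)$landmarks
  th <- 33 * pi / 180
  centre <- c((160 - 1) / 2, (128 - 1) / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expected <- sweep(sweep(l0, 2, centre) %*% t(R), 2, centre, `+`)
  expect_equal(lr[1:11, 1:2], expected[1:11, 1:2], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("complete wings keep all landmarks strictly inside the canvas; impossible specs error", {
  w <- generate_wing(wing_spec(canvas_height = 96, canvas_width = 120,
                               rng_seed = 2))
  expect_true(all(w$landmarks[, 1] > 0 & w$landmarks[, 1] < 119))
  expect_true(all(w$landmarks[, 2] > 0 & w$landmarks[, 2] < 95))
  expect_error(
    generate_wing(wing_spec(canvas_height = 96, canvas_width = 120,
                            scale_factor = 1, shift = c(60, 0))),
    "landmark"
  )
  expect_error(wing_spec(canvas_height = 32, canvas_width = 120), "64")
  expect_error(wing_spec(scale_factor = 0), "scale_factor")
})

test_that("every landmark of a rendered complete wing lies on a vein", {
  spec <- wing_spec(canvas_height = 128, canvas_width = 160, noise_sd = 0,
                    rng_seed = 3)
  w <- generate_wing(spec)
  at_lmk <- vapply(1:11, function(k) {
    w$image[round(w$landmarks[k, 2]) + 1, round(w$landmarks[k, 1]) + 1]
  }, numeric(1))
  expect_true(all(at_lmk - spec$brightness >= spec$contrast * 0.9))
})

test_that("damage modes invalidate exactly the advertised landmarks and set the label", {
  specs <- list(none = 0L, missing_lm4 = 1L, missing_lm6 = 1L, torn = 0L,
                stained = 0L, absent_wing = 1L)
  for (dmg in names(specs)) {
    w <- generate_wing(wing_spec(canvas_height = 96, canvas_width = 120,
                                 damage = dmg, rng_seed = 4))
    expect_equal(w$label, specs[[dmg]])
    v <- attr(w$landmarks, "valid")
    if (dmg == "missing_lm4") expect_equal(which(!v), 4L)
    else if (dmg == "missing_lm6") expect_equal(which(!v), 6L)
    else if (dmg == "absent_wing") expect_false(any(v))
    else expect_true(all(v))
  }
})

test_that("the occlusion really removes the missing landmark's vein signal", {
  spec <- wing_spec(canvas_height = 128, canvas_width = 160, noise_sd = 0,
                    damage = "missing_lm6", rng_seed = 5)
  w <- generate_wing(spec)
  expect_equal(w$image[round(w$landmarks[6, 2]) + 1, round(w$landmarks[6, 1]) + 1],
               spec$brightness)
  # landmark 1 (far from the damage) is untouched
  expect_gte(w$image[round(w$landmarks[1, 2]) + 1, round(w$landmarks[1, 1]) + 1],
             spec$brightness + spec$contrast * 0.9)
})

test_that("batch incomplete fraction is consistent with its binomial sampling margin", {
  batch <- generate_wing_batch(200, canvas = c(96, 120), p_incomplete = 0.13,
                               seed = 99, render = FALSE)
  p_hat <- mean(batch$label)   # brute-force count of labels
  margin <- binomial_margin(0.13, 200, 14354)
  expect_lte(abs(p_hat - 0.13), margin)
  expect_true(all(batch$label[batch$damage %in%
                                c("missing_lm4", "missing_lm6", "absent_wing")] == 1))
  expect_true(all(batch$label[batch$damage %in% c("none", "torn", "stained")] == 0))
})

test_that("pages respect the 20-line cap and record wlm = 0.007 x landmark 1-6 distance", {
  expect_error(generate_page(n_lines = 21), "20")
  pg <- generate_page(n_lines = 5, rng_seed = 31, wlm_noise_sd = 0)
  left <- pg$images[pg$images$side == "L", ]
  lens <- vapply(seq_len(nrow(left)), function(i) {
    wing_length_mm(left$landmarks[[i]])
  }, numeric(1))
  expect_equal(pg$records$wlm[left$line], lens, tolerance = 1e-12)
  expect_equal(pg$records$wlm, pg$records$true_wlm)
})

test_that("skipped-image pages associate images one line behind, dropping the last line", {
  pg <- generate_page(n_lines = 20, misalignment = "skipped_image",
                      error_line = 1, rng_seed = 32)
  expect_true(all(pg$images$true_line == pg$images$line + 1))
  expect_false(20 %in% pg$images$line)
  # every surviving record-image pair is mismatched
  expect_true(all(pg$images$true_line != pg$images$line))
  expect_error(generate_page(20, "skipped_image", error_line = 25), "error_line")
})

test_that("duplicated-image pages repeat the error line's images and shift one step ahead", {
  pg <- generate_page(n_lines = 20, misalignment = "duplicated_image",
                      error_line = 5, rng_seed = 33, render = TRUE,
                      canvas = c(96, 120))
  imgs <- pg$images
  lmL5 <- imgs$image[[which(imgs$line == 5 & imgs$side == "L")]]
  lmL6 <- imgs$image[[which(imgs$line == 6 & imgs$side == "L")]]
  expect_identical(lmL5, lmL6)
  expect_true(all(imgs$true_line[imgs$line > 5] == imgs$line[imgs$line > 5] - 1))
  expect_true(all(imgs$true_line[imgs$line < 5] == imgs$line[imgs$line < 5]))
})

test_that("a clean zero-noise page has page R-squared exactly 1", {
  pg <- generate_page(n_lines = 10, rng_seed = 34, wlm_noise_sd = 0)
  preds <- pg$images
  lens <- vapply(preds$landmarks, wing_length_mm, numeric(1))
  pred_tbl <- dplyr::mutate(
    dplyr::select(preds, "name", "volume", "page", "line", "side"),
    pred_length_mm = lens)
  rep <- page_r_squared(pg$records, pred_tbl)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_false(rep$flagged)
})

test_that("a synthetic page round-trips through the on-disk formats", {
  dir <- withr::local_tempdir()
  pg <- generate_page(n_lines = 3, rng_seed = 35, canvas = c(96, 120),
                      render = TRUE)
  write_page(pg, dir)
  expect_true(file.exists(file.path(dir, "V20P001L01L.png")))
  lmk <- read_landmark_csv(file.path(dir, "landmarks.csv"))
  expect_equal(nrow(lmk), 6)
  img <- read_wing_png(file.path(dir, "V20P001L02R.png"))
  orig <- pg$images$image[[which(pg$images$name == "V20P001L02R")]]
  expect_lt(max(abs(img - orig)), 1 / 255)
  bio <- read_bio_csv(file.path(dir, "bio.csv"))
  expect_equal(bio$wlm, round(pg$records$wlm, 3))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_lines, 3)
})
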