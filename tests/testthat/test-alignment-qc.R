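test_that("the FPC margin reproduces the published sample-statistic margins", {
  expect_equal(round(100 * binomial_margin(0.13, 200, 14354), 2), 4.63)
  expect_equal(round(100 * binomial_margin(0.10, 200, 14354), 2), 4.13)
  expect_equal(round(100 * binomial_margin(0.02, 100, 770), 2), 2.56)
})

test_that("the margin behaves correctly at its limits", {
  expect_equal(binomial_margin(0, 50, 1000), 0)
  # N -> Inf converges to the uncorrected normal margin
  p <- 0.3; n <- 120
  uncorrected <- 1.96 * sqrt(p * (1 - p) / n)
  expect_equal(binomial_margin(p, n, Inf), uncorrected)
  expect_equal(binomial_margin(p, n, 1e9), uncorrected, tolerance = 1e-6)
  # census: margin vanishes as n -> N
  expect_lt(binomial_margin(p, 999, 1000), uncorrected / 10)
  expect_error(binomial_margin(0.5, 200, 100), "n <= N")
  expect_error(binomial_margin(1.2, 10, 100), "p_hat")
  est <- sample_estimate(0.13, 200, 14354)
  expect_equal(est$lower, 0.13 - est$margin)
  expect_equal(est$upper, 0.13 + est$margin)
})

test_that("page R-squared is invariant to wing order and degenerate pages are surfaced", {
  pg <- generate_page(n_lines = 12, rng_seed = 50)
  preds <- simulate_page_predictions(pg, error_sd_px = 3)
  r1 <- page_r_squared(pg$records, preds)$r_squared
  set.seed(1)
  r2 <- page_r_squared(pg$records[sample(12), ], preds[sample(24), ])$r_squared
  expect_equal(r1, r2)
  # one-line page: too few points
  tiny <- generate_page(n_lines = 1, rng_seed = 51)
  rep_tiny <- page_r_squared(tiny$records, simulate_page_predictions(tiny))
  expect_true(rep_tiny$degenerate)
  expect_false(rep_tiny$flagged)
  # zero variance in wlm
  flat <- pg$records
  flat$wlm <- 6.5
  rep_flat <- page_r_squared(flat, preds)
  expect_true(rep_flat$degenerate)
  expect_error(page_r_squared(pg$records[0, ], preds), "no records")
})

test_that("fully misaligned pages are flagged at close to the analytic rate, clean pages almost never", {
  # a page misaligned from line 1 pairs every record with the wrong fly, so
  # its R^2 is a squared correlation of independent pairs; with ~19
  # effectively distinct points the null P(R^2 < 0.1) is about
  # pbeta(0.1, 0.5, 8.5) ~ 0.82, not certainty
  set.seed(52)
  n_rep <- 120
  flags_bad <- flags_clean <- logical(n_rep)
  for (i in 1:n_rep) {
    bad <- generate_page(20, "skipped_image", error_line = 1,
                         rng_seed = 1000 + i)
    rb <- page_r_squared(bad$records, simulate_page_predictions(bad, 4))
    flags_bad[i] <- rb$flagged
    cln <- generate_page(20, rng_seed = 3000 + i)
    rc <- page_r_squared(cln$records, simulate_page_predictions(cln, 4))
    flags_clean[i] <- rc$flagged
  }
  analytic <- stats::pbeta(0.1, 0.5, 8.5)
  expect_lt(abs(mean(flags_bad) - analytic), 0.12)
  expect_lt(mean(flags_clean), 0.05)
})

test_that("errors earlier in a page depress R-squared more", {
  set.seed(53)
  mean_r2 <- vapply(c(2, 10, 18), function(el) {
    mean(vapply(1:40, function(i) {
      pg <- generate_page(20, "skipped_image", error_line = el,
                          rng_seed = 5000 + 100 * el + i)
      page_r_squared(pg$records, simulate_page_predictions(pg, 4))$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) > 0))
})

test_that("length agreement is exact for perfect predictions and matches the OLS oracle", {
  pg <- generate_page(n_lines = 20, rng_seed = 54, wlm_noise_sd = 0)
  perfect <- simulate_page_predictions(pg, error_sd_px = 0)
  la <- length_agreement(pg$records, perfect)
  expect_equal(la$r_squared, 1, tolerance = 1e-12)
  expect_equal(nrow(la$outliers), 0)
  noisy <- simulate_page_predictions(pg, error_sd_px = 4)
  la2 <- length_agreement(pg$records, noisy)
  j <- la2$data
  X <- cbind(1, j$wlm)
  beta <- solve(t(X) %*% X, t(X) %*% j$pred_length_mm)
  expect_equal(la2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(la2$slope, beta[2], tolerance = 1e-10)
  expect_error(length_agreement(pg$records[1, ], noisy), "3 usable")
})

test_that("gross record swaps surface as outliers at about the injected rate", {
  set.seed(55)
  pages <- lapply(1:25, function(p) generate_page(20, rng_seed = 600 + p,
                                                  page = p))
  records <- dplyr::bind_rows(lapply(pages, `[[`, "records"))
  preds <- dplyr::bind_rows(lapply(pages, simulate_page_predictions,
                                   error_sd_px = 2))
  # swap 2% of records' wlm with a far-away partner
  n <- nrow(records)
  swap <- sample(n, round(0.02 * n) * 2)
  half <- length(swap) / 2
  tmp <- records$wlm[swap[1:half]]
  records$wlm[swap[1:half]] <- records$wlm[swap[(half + 1):(2 * half)]]
  records$wlm[swap[(half + 1):(2 * half)]] <- tmp
  la <- length_agreement(records, preds)
  frac <- nrow(la$outliers) / la$n
  # swapped records mostly fall outside the band; allow binomial slack around
  # the injected 2% (some swaps exchange similar lengths and stay inside)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.06)
})

test_that("excluded hatchet-cell records are dropped from the agreement fit", {
  pg <- generate_page(n_lines = 10, rng_seed = 56, wlm_noise_sd = 0)
  preds <- simulate_page_predictions(pg, error_sd_px = 0)
  excl <- vpn_string(20, 1, 1:3)
  la <- length_agreement(pg$records, preds, excluded = excl)
  expect_equal(la$n, 14)   # 7 remaining records x 2 wings
})

test_that("an empty correction log changes nothing and unknown pages error", {
  pg <- generate_page(n_lines = 5, rng_seed = 57)
  empty <- tibble::tibble(volume = integer(), page = integer(),
                          action = character(), param = integer(),
                          from_line = integer(), note = character())
  out <- reconcile(pg$images, empty)
  expect_identical(out$images, pg$images)
  bad <- tibble::tibble(volume = 99L, page = 1L, action = "remove_page",
                        param = NA_integer_, from_line = NA_integer_, note = "")
  expect_error(reconcile(pg$images, bad), "unknown page")
})

test_that("shifting the association undoes a skipped-image error exactly", {
  pg <- generate_page(20, "skipped_image", error_line = 4, rng_seed = 58,
                      wlm_noise_sd = 0)
  fix <- tibble::tibble(volume = 20L, page = 1L, action = "shift_association",
                        param = 1L, from_line = 4L, note = "skip at line 4")
  corrected <- reconcile(pg$images, fix)$images
  expect_true(all(corrected$true_line == corrected$line))
  lens <- vapply(corrected$landmarks, wing_length_mm, numeric(1))
  pred_tbl <- dplyr::mutate(
    dplyr::select(corrected, "volume", "page", "line", "side"),
    pred_length_mm = lens)
  rep <- page_r_squared(pg$records, pred_tbl)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
})

test_that("flag -> suggest -> reconcile recovers injected misalignments on a small volume", {
  vol <- generate_volume(n_pages = 60, p_misaligned = 0.05, rng_seed = 59)
  records <- dplyr::bind_rows(lapply(vol$page_data, `[[`, "records"))
  preds <- dplyr::bind_rows(lapply(vol$page_data, simulate_page_predictions,
                                   error_sd_px = 4))
  report <- page_r_squared(records, preds)
  fixes <- suggest_corrections(report, records, preds)
  expect_true(all(fixes$page %in% report$page[report$flagged | report$degenerate]))
  if (nrow(fixes) > 0) {
    images <- dplyr::bind_rows(lapply(vol$page_data, function(p) {
      dplyr::select(p$images, "name", "volume", "page", "line", "side",
                    "true_line", "landmarks")
    }))
    corrected <- reconcile(images, fixes)$images
    shifted <- fixes$page[fixes$action == "shift_association"]
    for (p in shifted) {
      pp <- corrected[corrected$page == p, ]
      expect_true(mean(pp$true_line == pp$line) > 0.9)
    }
  }
})
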