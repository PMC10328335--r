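#' Synthetic tsetse-like wing images with known landmark ground truth
#'
#' The generator renders a stylised wing: a fixed skeleton of smooth
#' quadratic Bezier vein curves whose intersections and junctions define the
#' 11 ordered landmarks (landmark 1 at the wing base, 6 at the tip, 7 and 11
#' spanning the hatchet cell). Wings vary in size, rotation, position,
#' brightness, contrast and noise, and can carry damage: occlusion of
#' landmark 4 or 6 (the incomplete classes the classifier targets), tears or
#' stains that leave all landmarks intact, or a fully absent wing. Every
#' generated wing comes with exact landmark coordinates, so all downstream
#' stages are testable without real data.
#'
#' @name synthetic_wings
NULL

# Template landmark coordinates in unit wing space (x rightwards, y down).
# Implementer-chosen constants; landmark 1 = base, 6 = tip, 7/11 = hatchet
# cell, 8-10 along the trailing region.
.wing_template <- matrix(c(
  0.030, 0.270,
  0.200, 0.120,
  0.330, 0.300,
  0.450, 0.110,
  0.660, 0.090,
  0.970, 0.230,
  0.450, 0.280,
  0.290, 0.420,
  0.480, 0.400,
  0.620, 0.350,
  0.640, 0.250
), ncol = 2, byrow = TRUE)

# Vein skeleton: edges between landmark indices, each a quadratic Bezier
# whose control point sits at the chord midpoint offset perpendicularly by
# `bow` (fraction of the unit span). Every landmark has >= 2 incident veins,
# so each ground-truth point lies on a curve intersection.
.wing_veins <- data.frame(
  a = c(1, 2, 4, 5, 1, 3, 7, 11, 1, 8, 9, 10, 2, 4, 9, 10),
  b = c(2, 4, 5, 6, 3, 7, 11, 6, 8, 9, 10, 6, 3, 7, 7, 11),
  bow = c(0.06, 0.05, 0.03, 0.04, -0.04, 0.03, -0.04, 0.03,
          -0.05, -0.05, -0.04, -0.06, 0.02, 0.02, 0.02, 0.02)
)

.damage_levels <- c("none", "missing_lm4", "missing_lm6", "torn", "stained",
                    "absent_wing")

#' @rdname synthetic_wings
#' @param canvas_height,canvas_width canvas size in pixels (native archive
#'   resolution is 1024 x 1280; tests use smaller canvases).
#' @param scale_factor wing span as a fraction of canvas width.
#' @param rotation wing rotation in degrees (about the canvas centre).
#' @param shift 2-vector, pixel offset of the wing from the canvas centre.
#' @param vein_width rendered vein thickness in pixels.
#' @param brightness background intensity in `[0, 1]`.
#' @param contrast vein intensity above background, in `[0, 1]`.
#' @param noise_sd additive Gaussian pixel noise SD (intensity units).
#' @param damage one of `"none"`, `"missing_lm4"`, `"missing_lm6"`,
#'   `"torn"`, `"stained"`, `"absent_wing"`.
#' @param rng_seed integer seed making the rendered image reproducible.
#' @return `wing_spec()`: a validated spec list.
#' @export
wing_spec <- function(canvas_height = 1024L, canvas_width = 1280L,
                      scale_factor = 0.72, rotation = 0, shift = c(0, 0),
                      vein_width = max(2, round(canvas_width / 420)),
                      brightness = 0.25, contrast = 0.55, noise_sd = 0.02,
                      damage = "none", rng_seed = NULL) {
  damage <- match.arg(damage, .damage_levels)
  if (canvas_height < 64 || canvas_width < 64) {
    stop_wingmark("canvas must be at least 64 x 64 pixels")
  }
  if (scale_factor <= 0 || scale_factor > 1) {
    stop_wingmark("scale_factor must lie in (0, 1]")
  }
  structure(list(
    canvas_height = as.integer(canvas_height),
    canvas_width = as.integer(canvas_width),
    scale_factor = scale_factor, rotation = rotation, shift = shift,
    vein_width = vein_width, brightness = brightness, contrast = contrast,
    noise_sd = noise_sd, damage = damage, rng_seed = rng_seed
  ), class = "wing_spec")
}

# Ground-truth landmark coordinates for a spec (0-based pixel space).
wing_template_landmarks <- function(spec) {
  s <- spec$scale_factor * spec$canvas_width
  centred <- sweep(.wing_template, 2, c(0.5, 0.26))
  q <- centred * s
  th <- spec$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- q %*% t(R)
  centre <- c((spec$canvas_width - 1) / 2, (spec$canvas_height - 1) / 2)
  sweep(q, 2, centre + spec$shift, `+`)
}

bezier_points <- function(p0, p1, bow, span, n = NULL) {
  mid <- (p0 + p1) / 2
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  perp <- c(-d[2], d[1]) / max(len, 1e-9)
  ctrl <- mid + perp * bow * span
  if (is.null(n)) n <- max(16L, ceiling(2 * len))
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 %o% p0[1] + 2 * t * (1 - t) %o% ctrl[1] + t^2 %o% p1[1],
        (1 - t)^2 %o% p0[2] + 2 * t * (1 - t) %o% ctrl[2] + t^2 %o% p1[2])
}

stamp_points <- function(img, pts, radius, value) {
  h <- nrow(img); w <- ncol(img)
  r <- max(0L, floor(radius))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
  px <- round(pts[, 1]); py <- round(pts[, 2])
  rows <- rep(py, each = nrow(off)) + off$dy + 1
  cols <- rep(px, each = nrow(off)) + off$dx + 1
  ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  img[cbind(rows[ok], cols[ok])] <- value
  img
}

#' Generate one synthetic wing
#'
#' @param spec a [wing_spec()].
#' @param render if `FALSE`, skip pixel rendering (geometry and labels only;
#'   used for large alignment-QC simulations).
#' @return list with `image` (H x W matrix or `NULL`), `landmarks`
#'   (a [landmark_set()] whose `valid` attribute marks landmarks invalidated
#'   by damage), `label` (1 for incomplete wings — missing landmark 4 or 6,
#'   or absent wing — else 0), and `spec`.
#' @export
generate_wing <- function(spec, render = TRUE) {
  lmk <- wing_template_landmarks(spec)
  valid <- rep(TRUE, 11L)
  if (spec$damage == "missing_lm4") valid[4] <- FALSE
  if (spec$damage == "missing_lm6") valid[6] <- FALSE
  if (spec$damage == "absent_wing") valid[] <- FALSE
  required <- which(valid)
  outside <- required[lmk[required, 1] <= 0 | lmk[required, 1] >= spec$canvas_width - 1 |
                        lmk[required, 2] <= 0 | lmk[required, 2] >= spec$canvas_height - 1]
  if (length(outside)) {
    stop_wingmark("landmark%s %s outside the canvas for this spec",
                  if (length(outside) > 1) "s" else "",
                  paste(outside, collapse = ", "))
  }
  label <- as.integer(spec$damage %in% c("missing_lm4", "missing_lm6",
                                         "absent_wing"))
  image <- if (render) {
    with_seed(spec$rng_seed, render_wing(spec, lmk))
  }
  list(image = image, landmarks = landmark_set(lmk, valid),
       label = label, spec = spec)
}

render_wing <- function(spec, lmk) {
  h <- spec$canvas_height; w <- spec$canvas_width
  img <- matrix(spec$brightness, h, w)
  vein_level <- min(1, spec$brightness + spec$contrast)
  span <- spec$scale_factor * w
  if (spec$damage != "absent_wing") {
    for (i in seq_len(nrow(.wing_veins))) {
      e <- .wing_veins[i, ]
      pts <- bezier_points(lmk[e$a, ], lmk[e$b, ], e$bow, span)
      img <- stamp_points(img, pts, spec$vein_width / 2, vein_level)
    }
  }
  if (spec$damage %in% c("missing_lm4", "missing_lm6")) {
    # a torn-off piece of wing containing the landmark: everything within
    # a generous radius of the missing landmark reverts to background
    k <- if (spec$damage == "missing_lm4") 4L else 6L
    img <- stamp_points(img, matrix(lmk[k, ], 1), 0.20 * span, spec$brightness)
  }
  if (spec$damage == "torn") {
    # a notch on the trailing margin, kept clear of every landmark
    centre <- (lmk[10, ] + lmk[6, ]) / 2 + c(0, 0.10 * span)
    img <- stamp_points(img, matrix(centre, 1), 0.03 * span, spec$brightness)
  }
  if (spec$damage == "stained") {
    centre <- colMeans(lmk[c(5, 11), ]) + c(0, -0.02 * span)
    d <- sqrt(rowSums(sweep(lmk, 2, centre)^2))
    r <- min(0.035 * span, max(1, min(d) - spec$vein_width - 1))
    img <- stamp_points(img, matrix(centre, 1), r, spec$brightness * 0.3)
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  clamp(img, 0, 1)
}

#' Generate a batch of synthetic wings
#'
#' Draws independent wings with randomised pose and photometry; a fraction
#' `p_incomplete` carry damage that removes landmark 4 or 6 (or the whole
#' wing), and a small fraction of the complete wings carry tears/stains that
#' do not invalidate any landmark (defects within complete wings).
#'
#' @param n number of wings.
#' @param canvas `(H, W)` canvas size.
#' @param p_incomplete probability of an incomplete wing.
#' @param p_defect probability that a complete wing is torn or stained.
#' @param scale_range,rotation_range,shift_frac,brightness_range,contrast_range
#'   pose/photometry variation (uniform draws).
#' @param noise_sd pixel noise SD.
#' @param seed integer seed; the batch is reproducible.
#' @param render render pixels (`FALSE` for geometry-only batches).
#' @return tibble with columns `name`, `image` (list), `landmarks` (list),
#'   `label`, `damage`.
#' @export
generate_wing_batch <- function(n, canvas = c(128L, 160L), p_incomplete = 0,
                                p_defect = 0.06,
                                scale_range = c(0.58, 0.80),
                                rotation_range = c(-15, 15),
                                shift_frac = 0.06,
                                brightness_range = c(0.2, 0.3),
                                contrast_range = c(0.45, 0.65),
                                noise_sd = 0.02, seed = NULL, render = TRUE) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      damage <- "none"
      if (runif(1) < p_incomplete) {
        damage <- sample(c("missing_lm4", "missing_lm6", "absent_wing"),
                         1, prob = c(0.4, 0.4, 0.2))
      } else if (runif(1) < p_defect) {
        damage <- sample(c("torn", "stained"), 1)
      }
      spec <- wing_spec(
        canvas_height = canvas[1], canvas_width = canvas[2],
        scale_factor = runif(1, scale_range[1], scale_range[2]),
        rotation = runif(1, rotation_range[1], rotation_range[2]),
        shift = runif(2, -shift_frac, shift_frac) * c(canvas[2], canvas[1]),
        brightness = runif(1, brightness_range[1], brightness_range[2]),
        contrast = runif(1, contrast_range[1], contrast_range[2]),
        noise_sd = noise_sd, damage = damage,
        rng_seed = sample.int(2^30, 1)
      )
      wing <- generate_wing(spec, render = render)
      list(image = wing$image, landmarks = wing$landmarks,
           label = wing$label, damage = damage)
    })
    tibble::tibble(
      name = sprintf("SYN%05d", seq_len(n)),
      image = lapply(rows, `[[`, "image"),
      landmarks = lapply(rows, `[[`, "landmarks"),
      label = vapply(rows, `[[`, integer(1), "label"),
      damage = vapply(rows, `[[`, character(1), "damage")
    )
  })
}

#' Synthetic archive pages with injected misalignments
#'
#' A page holds up to 20 wing pairs, one fly per line: a left wing and its
#' mirrored right wing. Each line's biological record carries the measured
#' wing length `wlm` (0.007 mm/px times the landmark 1-6 distance, plus
#' dissector measurement noise). Misalignments emulate photographing errors:
#' `"duplicated_image"` repeats one line's images so all later images are
#' associated one line ahead; `"skipped_image"` drops one line's images so
#' all later images are associated with the record of the line before the
#' one they belong to (one step behind), and the last line's images are
#' missing.
#'
#' @param n_lines number of wing pairs (1-20).
#' @param misalignment `"none"`, `"duplicated_image"` or `"skipped_image"`.
#' @param error_line line (1-based) at which the error is injected.
#' @param rng_seed integer seed.
#' @param volume,page identifiers used in image names and `vpn`.
#' @param canvas `(H, W)` canvas; geometry defaults to native 1024 x 1280.
#' @param render render pixel images (geometry-only pages are cheap and are
#'   what the alignment-QC simulations use).
#' @param wlm_noise_sd SD of the dissector measurement noise, mm.
#' @param mm_per_px digitisation scale.
#' @return a `synthetic_page`: list with `records` (tibble
#'   `vpn, volume, page, line, wlm, true_wlm, lmkl, lmkr`), `images` (tibble
#'   `name, volume, page, line, side, true_line, image, landmarks`; `line` is
#'   the association after any injected error, `true_line` the generating
#'   fly), `misalignment`, `error_line`, `page_id`.
#' @export
generate_page <- function(n_lines = 20L, misalignment = "none",
                          error_line = NA_integer_, rng_seed = NULL,
                          volume = 20L, page = 1L,
                          canvas = c(1024L, 1280L), render = FALSE,
                          wlm_noise_sd = 0.02, mm_per_px = 0.007) {
  misalignment <- match.arg(misalignment,
                            c("none", "duplicated_image", "skipped_image"))
  if (n_lines < 1 || n_lines > 20) {
    stop_wingmark("a page holds between 1 and 20 wing pairs")
  }
  if (misalignment != "none" &&
      (is.na(error_line) || error_line < 1 || error_line > n_lines)) {
    stop_wingmark("error_line must lie in 1..n_lines when injecting a misalignment")
  }
  with_seed(rng_seed, {
    flies <- lapply(seq_len(n_lines), function(i) {
      spec <- wing_spec(
        canvas_height = canvas[1], canvas_width = canvas[2],
        scale_factor = runif(1, 0.60, 0.80),
        rotation = runif(1, -12, 12),
        shift = runif(2, -0.05, 0.05) * c(canvas[2], canvas[1]),
        noise_sd = 0.02, rng_seed = sample.int(2^30, 1)
      )
      left <- generate_wing(spec, render = render)
      right_lmk <- left$landmarks
      right_lmk[, 1] <- canvas[2] - 1 - right_lmk[, 1]
      right <- list(
        image = if (render) left$image[, rev(seq_len(canvas[2])), drop = FALSE],
        landmarks = landmark_set(right_lmk, lm_valid(left$landmarks))
      )
      true_len <- mm_per_px *
        sqrt(sum((left$landmarks[1, ] - left$landmarks[6, ])^2))
      list(left = left, right = right, true_wlm = true_len)
    })
    true_wlm <- vapply(flies, `[[`, numeric(1), "true_wlm")
    records <- tibble::tibble(
      vpn = vpn_string(volume, page, seq_len(n_lines)),
      volume = as.integer(volume), page = as.integer(page),
      line = seq_len(n_lines),
      true_wlm = true_wlm,
      wlm = true_wlm + rnorm(n_lines, sd = wlm_noise_sd),
      lmkl = 0L, lmkr = 0L
    )
    # line-level association: which fly's images carry each line's name
    assoc <- seq_len(n_lines)
    if (misalignment == "skipped_image") {
      e <- error_line
      assoc[e:n_lines] <- (e:n_lines) + 1L   # one step behind
      assoc[assoc > n_lines] <- NA_integer_  # last line left unphotographed
    } else if (misalignment == "duplicated_image") {
      e <- error_line
      if (e < n_lines) assoc[(e + 1):n_lines] <- e:(n_lines - 1L)  # one step ahead
    }
    img_rows <- list()
    for (ln in seq_len(n_lines)) {
      tl <- assoc[ln]
      if (is.na(tl)) next
      for (side in c("L", "R")) {
        wing <- if (side == "L") flies[[tl]]$left else flies[[tl]]$right
        img_rows[[length(img_rows) + 1L]] <- tibble::tibble(
          name = wing_id_string(volume, page, ln, side),
          volume = as.integer(volume), page = as.integer(page),
          line = ln, side = side, true_line = tl,
          image = list(wing$image), landmarks = list(wing$landmarks)
        )
      }
    }
    structure(list(
      page_id = c(volume = as.integer(volume), page = as.integer(page)),
      records = records,
      images = dplyr::bind_rows(img_rows),
      misalignment = misalignment,
      error_line = if (misalignment == "none") NA_integer_ else as.integer(error_line)
    ), class = "synthetic_page")
  })
}

#' @rdname generate_page
#' @param n_pages number of pages in the volume.
#' @param p_misaligned fraction of pages receiving an injected misalignment.
#' @param early_lines candidate (1-based) error lines for injected errors;
#'   photographing errors near the top of a page misalign most of it.
#' @param n_lines,volume,rng_seed,... passed to `generate_page()`.
#' @return `generate_volume()`: tibble with columns `page`, `misaligned`
#'   (logical), and `page_data` (list of `synthetic_page`).
#' @export
generate_volume <- function(n_pages = 770L, p_misaligned = 0.02,
                            early_lines = 1:4, n_lines = 20L, volume = 20L,
                            rng_seed = NULL, ...) {
  with_seed(rng_seed, {
    inject <- runif(n_pages) < p_misaligned
    pages <- lapply(seq_len(n_pages), function(p) {
      if (inject[p]) {
        generate_page(
          n_lines = n_lines,
          misalignment = sample(c("duplicated_image", "skipped_image"), 1),
          error_line = sample(early_lines, 1),
          rng_seed = sample.int(2^30, 1),
          volume = volume, page = p, ...
        )
      } else {
        generate_page(n_lines = n_lines, rng_seed = sample.int(2^30, 1),
                      volume = volume, page = p, ...)
      }
    })
    tibble::tibble(page = seq_len(n_pages), misaligned = inject,
                   page_data = pages)
  })
}

#' Emulate landmark-prediction error
#'
#' Adds isotropic Gaussian error to every landmark coordinate, emulating a
#' trained localiser's residual error at deployment scale (the regression
#' model's error on real data is a few pixels). Used by the alignment-QC
#' simulations, where training a model for every page would be pointless —
#' the QC statistic only sees predicted lengths.
#'
#' @param landmarks a landmark set.
#' @param error_sd_px per-coordinate error SD, pixels.
#' @return a perturbed landmark set.
#' @export
perturb_landmarks <- function(landmarks, error_sd_px = 4) {
  out <- landmarks + matrix(rnorm(22, sd = error_sd_px), 11, 2)
  landmark_set(out, lm_valid(landmarks))
}

#' @rdname generate_page
#' @param page_obj a `synthetic_page`.
#' @param error_sd_px emulated localisation error SD in pixels.
#' @param mm_per_px digitisation scale.
#' @return `simulate_page_predictions()`: tibble
#'   `name, volume, page, line, side, pred_length_mm` — the predicted wing
#'   length for every image on the page.
#' @export
simulate_page_predictions <- function(page_obj, error_sd_px = 4,
                                      mm_per_px = 0.007) {
  imgs <- page_obj$images
  pred <- vapply(imgs$landmarks, function(l) {
    wing_length_mm(perturb_landmarks(l, error_sd_px), scale = mm_per_px)
  }, numeric(1))
  dplyr::mutate(
    dplyr::select(imgs, "name", "volume", "page", "line", "side"),
    pred_length_mm = pred
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes rendered wing images as PNG (named by the archive convention),
#' the ground-truth landmark table and biological records as CSV, and a
#' manifest JSON capturing the generation parameters, so synthetic data
#' round-trips through the same I/O paths as real data.
#'
#' @param page_obj a rendered `synthetic_page`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_page <- function(page_obj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- page_obj$images
  has_pixels <- vapply(imgs$image, Negate(is.null), logical(1))
  for (i in which(has_pixels)) {
    write_wing_png(imgs$image[[i]], file.path(dir, paste0(imgs$name[i], ".png")))
  }
  write_landmark_csv(landmark_table(imgs$landmarks, imgs$name),
                     file.path(dir, "landmarks.csv"))
  write_bio_csv(dplyr::select(page_obj$records, "vpn", "wlm", "lmkl", "lmkr"),
                file.path(dir, "bio.csv"))
  manifest <- list(
    page_id = as.list(page_obj$page_id),
    misalignment = page_obj$misalignment,
    error_line = page_obj$error_line,
    n_lines = nrow(page_obj$records)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
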