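#' Affine augmentation of wing images and landmarks
#'
#' Training-time augmentation samples a random similarity transform —
#' scaling and per-axis shifting from a \[-5%, +5%\] interval and rotation
#' from \[-22 deg, +22 deg\] — and applies the *same* map to the pixel grid
#' and to every landmark, so image and coordinates stay consistent. The
#' transform order is rotation about the image centre, then scaling, then
#' shifting (a declared convention).
#'
#' @param scale_pct half-width of the scaling interval, percent.
#' @param shift_pct half-width of the shift interval, percent of each image
#'   dimension (sampled independently per axis).
#' @param rotation_deg half-width of the rotation interval, degrees.
#' @param enabled logical; a disabled config always yields the identity.
#' @return an `aug_config` list.
#' @export
aug_config <- function(scale_pct = 5, shift_pct = 5, rotation_deg = 22,
                       enabled = TRUE) {
  structure(list(scale_pct = scale_pct, shift_pct = shift_pct,
                 rotation_deg = rotation_deg, enabled = enabled),
            class = "aug_config")
}

#' @rdname aug_config
#' @param config an `aug_config`.
#' @return `sample_augmentation()`: a list with `scale` (multiplicative
#'   factor), `shift` (fractions of width/height) and `rotation` (degrees),
#'   drawn independently and uniformly from their intervals.
#' @export
sample_augmentation <- function(config = aug_config()) {
  if (!config$enabled) {
    return(list(scale = 1, shift = c(0, 0), rotation = 0))
  }
  list(
    scale = 1 + runif(1, -config$scale_pct, config$scale_pct) / 100,
    shift = runif(2, -config$shift_pct, config$shift_pct) / 100,
    rotation = runif(1, -config$rotation_deg, config$rotation_deg)
  )
}

aff_translate <- function(tx, ty) {
  matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
}

aff_scale <- function(sx, sy = sx) diag(c(sx, sy, 1))

aff_rotate <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

aff_apply <- function(A, pts) {
  out <- cbind(pts[, 1], pts[, 2], 1) %*% t(A)
  out[, 1:2, drop = FALSE]
}

#' @rdname aug_config
#' @param aug a sampled augmentation (see `sample_augmentation()`).
#' @param width,height image dimensions in pixels.
#' @return `augmentation_matrix()`: the 3 x 3 homogeneous coordinate map
#'   (0-based pixel coordinates, x = column, y = row).
#' @export
augmentation_matrix <- function(aug, width, height) {
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  aff_translate(cx + aug$shift[1] * width, cy + aug$shift[2] * height) %*%
    aff_scale(aug$scale) %*%
    aff_rotate(aug$rotation) %*%
    aff_translate(-cx, -cy)
}

# Bilinear gather at fractional source coordinates (0-based); out-of-frame
# samples take `fill`.
bilinear_sample <- function(image, sx, sy, fill) {
  h <- nrow(image); w <- ncol(image)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
  x0c <- clamp(x0, 0, w - 1); x1c <- clamp(x0 + 1, 0, w - 1)
  y0c <- clamp(y0, 0, h - 1); y1c <- clamp(y0 + 1, 0, h - 1)
  gather <- function(yy, xx) image[yy + 1 + xx * h]
  val <- (1 - fx) * (1 - fy) * gather(y0c, x0c) +
    fx * (1 - fy) * gather(y0c, x1c) +
    (1 - fx) * fy * gather(y1c, x0c) +
    fx * fy * gather(y1c, x1c)
  val[!inside] <- fill
  val
}

#' Warp an image by a homogeneous affine coordinate map
#'
#' The matrix `A` maps input (source) pixel coordinates to output
#' coordinates; pixels are resampled by inverse mapping with bilinear
#' interpolation. Landmarks transform exactly (no interpolation) via
#' the same matrix.
#'
#' @param image numeric H x W matrix.
#' @param A 3 x 3 homogeneous matrix in 0-based (x = column, y = row)
#'   coordinates.
#' @param fill intensity used outside the source frame; defaults to the
#'   image median (background).
#' @return warped H x W matrix.
#' @export
warp_affine <- function(image, A, fill = stats::median(image)) {
  h <- nrow(image); w <- ncol(image)
  Ainv <- solve(A)
  ox <- 0:(w - 1); oy <- 0:(h - 1)
  sx <- outer(Ainv[1, 2] * oy, Ainv[1, 1] * ox, `+`) + Ainv[1, 3]
  sy <- outer(Ainv[2, 2] * oy, Ainv[2, 1] * ox, `+`) + Ainv[2, 3]
  matrix(bilinear_sample(image, sx, sy, fill), h, w)
}

#' @rdname aug_config
#' @param image numeric H x W matrix.
#' @param landmarks landmark set in the same space.
#' @return `apply_augmentation()`: list with the transformed `image`,
#'   `landmarks`, and `in_frame` (logical(11); landmarks leaving the frame
#'   are flagged, not dropped).
#' @export
apply_augmentation <- function(image, landmarks, aug) {
  A <- augmentation_matrix(aug, ncol(image), nrow(image))
  warped <- warp_affine(image, A)
  pts <- aff_apply(A, landmarks)
  in_frame <- pts[, 1] >= 0 & pts[, 1] <= ncol(image) - 1 &
    pts[, 2] >= 0 & pts[, 2] <= nrow(image) - 1
  list(image = warped,
       landmarks = landmark_set(pts, lm_valid(landmarks)),
       in_frame = in_frame)
}

#' Resize an image between native and model resolutions
#'
#' Coordinate rescaling between native and model space uses plain per-axis
#' factors (`W_native / W_model`, `H_native / H_model`); the image resampler
#' uses the same pure-scale map with bilinear interpolation so that encoded
#' and decoded coordinates round-trip exactly.
#'
#' @param image numeric H x W matrix.
#' @param out_h,out_w output dimensions.
#' @return resized matrix.
#' @export
resize_image <- function(image, out_h, out_w) {
  sx <- ncol(image) / out_w
  sy <- nrow(image) / out_h
  ox <- (0:(out_w - 1)) * sx
  oy <- (0:(out_h - 1)) * sy
  sxg <- outer(rep(0, out_h), ox, `+`)
  syg <- outer(oy, rep(0, out_w), `+`)
  matrix(bilinear_sample(image, sxg, syg, fill = stats::median(image)),
         out_h, out_w)
}

#' @rdname resize_image
#' @param pts an n x 2 coordinate matrix (x, y), 0-based.
#' @param from,to `(H, W)` dimension pairs of the source and target spaces.
#' @return `rescale_points()`: coordinates mapped with per-axis factors.
#' @export
rescale_points <- function(pts, from, to) {
  out <- pts
  out[, 1] <- pts[, 1] * to[2] / from[2]
  out[, 2] <- pts[, 2] * to[1] / from[1]
  out
}
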