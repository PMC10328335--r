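#' Wing image identifiers
#'
#' Wing images are named by their physical location in the archive:
#' volume, page, line and side, e.g. `"V20P076L08R"` is volume 20, page 76,
#' line 8, right wing. The biological record key (`vpn`) uses the same
#' convention without the side letter.
#'
#' @param volume,page,line integer vectors.
#' @param side `"L"` or `"R"` (recycled).
#' @return `wing_id_string()`: a character vector of image names.
#' @examples
#' wing_id_string(20, 76, 8, "R")
#' parse_wing_id("V20P076L08R")
#' @export
wing_id_string <- function(volume, page, line, side) {
  stopifnot(all(side %in% c("L", "R")))
  sprintf("V%02dP%03dL%02d%s", as.integer(volume), as.integer(page),
          as.integer(line), side)
}

#' @rdname wing_id_string
#' @param x character vector of image names (`"V..P...L..L|R"`).
#' @return `parse_wing_id()`: a tibble with columns `name`, `volume`, `page`,
#'   `line`, `side`.
#' @export
parse_wing_id <- function(x) {
  m <- regmatches(x, regexec("^V([0-9]+)P([0-9]+)L([0-9]+)([LR])$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop_wingmark("not parseable as wing image names: %s",
                  paste(x[bad], collapse = ", "))
  }
  tibble::tibble(
    name = x,
    volume = as.integer(vapply(m, `[`, "", 2)),
    page = as.integer(vapply(m, `[`, "", 3)),
    line = as.integer(vapply(m, `[`, "", 4)),
    side = vapply(m, `[`, "", 5)
  )
}

#' @rdname wing_id_string
#' @return `vpn_string()`: the record key without the side letter.
#' @export
vpn_string <- function(volume, page, line) {
  sprintf("V%02dP%03dL%02d", as.integer(volume), as.integer(page),
          as.integer(line))
}

#' Landmark coordinate containers
#'
#' A landmark set is an 11 x 2 numeric matrix with columns `x` (column index)
#' and `y` (row index), 0-based, in native image pixel space, plus a logical
#' `valid` attribute marking landmarks whose ground truth exists (damaged
#' wings invalidate individual landmarks). Landmark tables (the CSV dialect)
#' are tibbles with columns `name`, `x1..x11`, `y1..y11`.
#'
#' @param xy an 11 x 2 matrix (or anything coercible) of landmark coordinates.
#' @param valid logical(11); defaults to all `TRUE`.
#' @return `landmark_set()`: the validated matrix with a `valid` attribute.
#' @export
landmark_set <- function(xy, valid = NULL) {
  xy <- as.matrix(xy)
  if (!all(dim(xy) == c(11L, 2L))) {
    stop_wingmark("a landmark set holds exactly 11 (x, y) points")
  }
  colnames(xy) <- c("x", "y")
  attr(xy, "valid") <- if (is.null(valid)) rep(TRUE, 11L) else as.logical(valid)
  xy
}

lm_valid <- function(lmk) attr(lmk, "valid") %||% rep(TRUE, 11L)

#' @rdname landmark_set
#' @param landmarks a list of landmark sets.
#' @param names image names for the `name` column.
#' @return `landmark_table()`: the wide one-row-per-image tibble.
#' @export
landmark_table <- function(landmarks, names) {
  if (inherits(landmarks, "matrix")) landmarks <- list(landmarks)
  xs <- t(vapply(landmarks, function(l) l[, 1], numeric(11)))
  ys <- t(vapply(landmarks, function(l) l[, 2], numeric(11)))
  colnames(xs) <- paste0("x", 1:11)
  colnames(ys) <- paste0("y", 1:11)
  dplyr::bind_cols(tibble::tibble(name = names),
                   tibble::as_tibble(xs), tibble::as_tibble(ys))
}

#' @rdname landmark_set
#' @param row a one-row landmark table (or a row of one).
#' @return `as_landmark_set()`: the 11 x 2 matrix for one image.
#' @export
as_landmark_set <- function(row) {
  if (is.matrix(row)) return(landmark_set(row, attr(row, "valid")))
  landmark_set(cbind(
    x = as.numeric(row[paste0("x", 1:11)]),
    y = as.numeric(row[paste0("y", 1:11)])
  ))
}

table_to_landmarks <- function(tbl) {
  lapply(seq_len(nrow(tbl)), function(i) {
    landmark_set(cbind(
      x = as.numeric(tbl[i, paste0("x", 1:11)]),
      y = as.numeric(tbl[i, paste0("y", 1:11)])
    ))
  })
}

#' Flip a right-wing image (and landmarks) into left orientation
#'
#' All analyses run on left-oriented wings; right wings are mirrored
#' horizontally. Pixel columns are reversed and each landmark `x` becomes
#' `W - 1 - x` (0-based); `y` and the landmark ordering are unchanged.
#' Applying the flip twice is the identity.
#'
#' @param image numeric H x W matrix (grayscale intensities in `[0, 1]`).
#' @param landmarks optional landmark set in the same image space.
#' @return list with `image` and `landmarks` (the latter `NULL` if not given).
#' @export
flip_to_left <- function(image, landmarks = NULL) {
  w <- ncol(image)
  flipped <- image[, rev(seq_len(w)), drop = FALSE]
  if (!is.null(landmarks)) {
    out <- landmarks
    out[, 1] <- w - 1 - landmarks[, 1]
    landmarks <- landmark_set(out, lm_valid(landmarks))
  }
  list(image = flipped, landmarks = landmarks)
}

#' Wing length from landmark coordinates
#'
#' The standard wing-length measure is the Euclidean distance between
#' landmarks 1 and 6, converted to millimetres at the digitisation scale of
#' 0.007 mm per pixel. The hatchet-cell measure uses landmarks 7 and 11
#' (`from = 7, to = 11`).
#'
#' @param landmarks a landmark set (11 x 2 matrix, native pixel space).
#' @param scale mm per pixel.
#' @param from,to landmark indices (1-based, numbering as on the wing).
#' @return length in mm.
#' @examples
#' pts <- cbind(x = c(0, 10, 20, 30, 40, 300, 60, 70, 80, 90, 100),
#'              y = c(0, 10, 20, 30, 40, 400, 60, 70, 80, 90, 100))
#' wing_length_mm(landmark_set(pts))  # 500 px -> 3.5 mm
#' @export
wing_length_mm <- function(landmarks, scale = 0.007, from = 1L, to = 6L) {
  v <- lm_valid(landmarks)
  if (!v[from] || !v[to]) {
    stop_wingmark("landmark %d or %d is flagged invalid; cannot measure length",
                  from, to)
  }
  scale * sqrt(sum((landmarks[from, ] - landmarks[to, ])^2))
}

#' Join wing images to biological records
#'
#' Each image is keyed to at most one biological record by
#' (volume, page, line); the two images of a pair share one record.
#' Unmatched images and unmatched records are reported separately rather
#' than dropped silently.
#'
#' @param images character vector of image names, or a tibble containing a
#'   `name` column (other columns are carried through).
#' @param records tibble with columns `volume`, `page`, `line` (or a `vpn`
#'   column in the `"V20P076L08"` form) plus record fields such as `wlm`.
#' @return list of tibbles: `matched`, `unmatched_images`,
#'   `unmatched_records`.
#' @export
join_records <- function(images, records) {
  if (is.character(images)) images <- tibble::tibble(name = images)
  if (anyDuplicated(images$name)) {
    dup <- unique(images$name[duplicated(images$name)])
    stop_wingmark("duplicate wing image names: %s", paste(dup, collapse = ", "))
  }
  ids <- parse_wing_id(images$name)
  images <- dplyr::left_join(images, ids, by = "name")
  if (!is.null(records[["vpn"]]) && is.null(records[["volume"]])) {
    m <- regmatches(records$vpn, regexec("^V([0-9]+)P([0-9]+)L([0-9]+)$", records$vpn))
    records$volume <- as.integer(vapply(m, `[`, "", 2))
    records$page <- as.integer(vapply(m, `[`, "", 3))
    records$line <- as.integer(vapply(m, `[`, "", 4))
  }
  key <- c("volume", "page", "line")
  matched <- dplyr::inner_join(images, records, by = key)
  unmatched_images <- dplyr::anti_join(images, records, by = key)
  unmatched_records <- dplyr::anti_join(records, images, by = key)
  list(matched = matched,
       unmatched_images = unmatched_images,
       unmatched_records = unmatched_records)
}

#' Read and write the landmark and biological CSV dialects
#'
#' Landmark tables are written as `name, x1..x11, y1..y11` with full float
#' precision; biological tables carry at least `vpn, wlm, lmkl, lmkr`, with
#' `wlm` rounded to 3 decimals (0.001 mm, well below measurement error).
#' All files are UTF-8 with a header row.
#'
#' @param path file path.
#' @param tbl tibble to write.
#' @return the tibble (readers), or `path` invisibly (writers).
#' @export
read_landmark_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_landmark_csv
#' @export
write_landmark_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname read_landmark_csv
#' @export
read_bio_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_landmark_csv
#' @export
write_bio_csv <- function(tbl, path) {
  if (!is.null(tbl[["wlm"]])) tbl$wlm <- round(tbl$wlm, 3)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read and write wing images as PNG
#'
#' Images are stored as grayscale PNG; in memory they are numeric H x W
#' matrices with intensities in `[0, 1]`. RGB files are converted to
#' grayscale by channel averaging on read (models replicate the single
#' channel back to 3 channels at ingestion).
#'
#' @param path PNG path.
#' @param image numeric matrix in `[0, 1]`.
#' @return the image matrix (reader) or `path` invisibly (writer).
#' @export
read_wing_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_wing_png
#' @export
write_wing_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}
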