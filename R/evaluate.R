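#' Pixel-distance error summaries
#'
#' Prediction error is the Euclidean pixel distance between predicted and
#' true landmark positions in native image space. The summary reports MAE
#' (mean distance), RMSE, and — because landmark error distributions are
#' skewed — the empirical 2.5th/50th/97.5th percentiles of the distance
#' distribution (LB / median / UB), overall and per landmark.
#'
#' @param pred,truth landmark tables (`name, x1..x11, y1..y11`) or lists of
#'   landmark sets of equal length. Tables are matched by `name`.
#' @return an `error_summary`: list with `per_pair` (tibble
#'   `name, landmark, distance`), `overall` (one-row tibble
#'   `mae, rmse, lb, median, ub, n`), and `per_landmark` (the same statistics
#'   by landmark). `tidy()` returns the per-landmark table, `glance()` the
#'   overall row, and `autoplot()` draws the per-landmark box plot.
#' @export
distance_errors <- function(pred, truth) {
  pl <- normalise_landmark_input(pred)
  tl <- normalise_landmark_input(truth)
  if (length(pl$landmarks) != length(tl$landmarks)) {
    stop_wingmark("prediction and truth have different numbers of images")
  }
  if (!is.null(pl$names) && !is.null(tl$names)) {
    ord <- match(tl$names, pl$names)
    if (anyNA(ord)) stop_wingmark("prediction and truth names do not match")
    pl$landmarks <- pl$landmarks[ord]
    pl$names <- pl$names[ord]
  }
  nm <- tl$names %||% sprintf("img%04d", seq_along(tl$landmarks))
  per_pair <- dplyr::bind_rows(lapply(seq_along(nm), function(i) {
    d <- sqrt(rowSums((pl$landmarks[[i]] - tl$landmarks[[i]])^2))
    tibble::tibble(name = nm[i], landmark = 1:11, distance = d)
  }))
  summarise_dist <- function(d) {
    q <- quantile(d, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(mae = mean(d), rmse = sqrt(mean(d^2)),
                   lb = q[1], median = q[2], ub = q[3], n = length(d))
  }
  per_landmark <- dplyr::group_modify(
    dplyr::group_by(per_pair, .data$landmark),
    ~summarise_dist(.x$distance)
  )
  structure(list(
    per_pair = per_pair,
    overall = summarise_dist(per_pair$distance),
    per_landmark = dplyr::ungroup(per_landmark)
  ), class = "error_summary")
}

normalise_landmark_input <- function(x) {
  if (is.data.frame(x)) {
    list(landmarks = table_to_landmarks(x), names = x$name)
  } else if (is.matrix(x)) {
    list(landmarks = list(x), names = NULL)
  } else {
    list(landmarks = x, names = names(x))
  }
}

#' @rdname distance_errors
#' @return `per_image_mean_error()`: tibble `(name, mean_error)` — the mean
#'   of the 11 per-landmark distances for each image (the dependent variable
#'   of the shape-bias regression).
#' @export
per_image_mean_error <- function(pred, truth) {
  es <- distance_errors(pred, truth)
  dplyr::summarise(dplyr::group_by(es$per_pair, .data$name),
                   mean_error = mean(.data$distance), .groups = "drop")
}

#' @exportS3Method generics::tidy
tidy.error_summary <- function(x, ...) x$per_landmark

#' @exportS3Method generics::glance
glance.error_summary <- function(x, ...) x$overall

#' @export
print.error_summary <- function(x, ...) {
  cat("Landmark pixel-distance errors (native space)\n")
  cat(sprintf("  images: %d   distances: %d\n",
              length(unique(x$per_pair$name)), nrow(x$per_pair)))
  cat(sprintf("  MAE %.2f px   RMSE %.2f px   95%% interval [%.1f, %.1f], median %.1f\n",
              x$overall$mae, x$overall$rmse, x$overall$lb, x$overall$ub,
              x$overall$median))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.error_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_pair,
                  ggplot2::aes(x = factor(.data$landmark), y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "landmark", y = "pixel distance error") +
    ggplot2::theme_minimal()
}
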