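#' Generalized Procrustes analysis and shape-bias regression
#'
#' To check that a landmark model is not biased toward particular wing
#' shapes, each specimen's Procrustes disparity (its Procrustes distance
#' from the sample mean shape after removing translation, scale and
#' rotation) is regressed against the specimen's mean pixel-distance
#' prediction error. A clear positive relationship would mean the model
#' localises unusual shapes less accurately, which would bias downstream
#' morphometrics.
#'
#' Alignment is full Procrustes (with scaling) and without reflection —
#' wings have fixed chirality once right wings are flipped.
#'
#' @name shape_bias
NULL

centre_scale_shape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(sum(x^2))
  if (s < 1e-12) stop_wingmark("degenerate shape: all points coincide")
  x / s
}

# Optimal rotation (and full-Procrustes scale) of unit-size shape x onto m.
rotate_to <- function(x, m) {
  sv <- svd(crossprod(x, m))
  d <- sign(det(sv$u %*% t(sv$v)))
  adj <- c(1, d)
  R <- sv$u %*% diag(adj) %*% t(sv$v)
  s <- sum(sv$d * adj)      # ||x||_F = 1, so scale = sum of adjusted svals
  s * x %*% R
}

#' Generalized Procrustes alignment
#'
#' Iteratively centres and scales every shape to unit centroid size,
#' rotates (and scales) each onto the current mean shape, and re-estimates
#' the mean until it changes by less than `tol` (the mean is renormalised
#' to unit centroid size each round). Reflections are never allowed.
#'
#' @param shapes a list of k x 2 landmark matrices (or a landmark table);
#'   at least two shapes.
#' @param tol convergence tolerance on the mean-shape change.
#' @param max_iter iteration cap.
#' @return a `gpa` object: `mean_shape` (unit centroid size, centred),
#'   `aligned` (list), `disparities` (per-specimen Procrustes distance from
#'   the mean shape), `n_iter`. `tidy()` returns a tibble of disparities.
#' @export
generalized_procrustes <- function(shapes, tol = 1e-8, max_iter = 100L) {
  if (is.data.frame(shapes)) {
    nm <- shapes$name
    shapes <- table_to_landmarks(shapes)
    names(shapes) <- nm
  }
  if (length(shapes) < 2) stop_wingmark("need at least two shapes")
  xs <- lapply(shapes, function(s) centre_scale_shape(unclass(s[, 1:2])))
  m <- xs[[1]]
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    aligned <- lapply(xs, rotate_to, m = m)
    m_new <- Reduce(`+`, aligned) / length(aligned)
    m_new <- m_new / sqrt(sum(m_new^2))
    delta <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (delta < tol || n_iter >= max_iter) break
  }
  aligned <- lapply(xs, rotate_to, m = m)
  disparities <- vapply(aligned, function(a) sqrt(sum((a - m)^2)), numeric(1))
  structure(list(mean_shape = m, aligned = aligned,
                 disparities = disparities, n_iter = n_iter),
            class = "gpa")
}

#' @exportS3Method generics::tidy
tidy.gpa <- function(x, ...) {
  tibble::tibble(
    name = names(x$disparities) %||% sprintf("shape%04d", seq_along(x$disparities)),
    disparity = unname(x$disparities)
  )
}

#' @exportS3Method generics::glance
glance.gpa <- function(x, ...) {
  tibble::tibble(n_shapes = length(x$aligned), n_iter = x$n_iter,
                 mean_disparity = mean(x$disparities))
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("Generalized Procrustes alignment: %d shapes, %d iterations\n",
              length(x$aligned), x$n_iter))
  cat(sprintf("  disparity: mean %.4g, range [%.4g, %.4g]\n",
              mean(x$disparities), min(x$disparities), max(x$disparities)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gpa <- function(object, ...) {
  pts <- dplyr::bind_rows(lapply(seq_along(object$aligned), function(i) {
    a <- object$aligned[[i]]
    tibble::tibble(shape = i, landmark = seq_len(nrow(a)),
                   x = a[, 1], y = a[, 2])
  }))
  mean_pts <- tibble::tibble(landmark = seq_len(nrow(object$mean_shape)),
                             x = object$mean_shape[, 1],
                             y = object$mean_shape[, 2])
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_point(data = mean_pts, colour = "red", size = 2) +
    ggplot2::geom_text(data = mean_pts, ggplot2::aes(label = .data$landmark),
                       vjust = -1, size = 3, colour = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Shape-bias regression
#'
#' Ordinary least squares of the per-image mean pixel error on the
#' Procrustes disparity, after removing points more than 2 standard
#' deviations from the mean of either variable (marginal rule, union
#' removed) — the regression line is sensitive to outliers. The R-squared
#' before removal is reported alongside.
#'
#' @param disparities numeric vector of Procrustes disparities (or a `gpa`
#'   object).
#' @param mean_errors per-image mean pixel errors, same length/order (or the
#'   tibble from [per_image_mean_error()]).
#' @param sd_cut outlier cut in standard deviations.
#' @return a `bias_regression`: `slope`, `intercept`, `r_squared`,
#'   `r_squared_all`, `outlier_mask` (TRUE = removed), `n_used`, `data`.
#' @export
bias_regression <- function(disparities, mean_errors, sd_cut = 2) {
  if (inherits(disparities, "gpa")) disparities <- disparities$disparities
  if (is.data.frame(mean_errors)) mean_errors <- mean_errors$mean_error
  d <- as.numeric(disparities); e <- as.numeric(mean_errors)
  if (length(d) != length(e)) stop_wingmark("disparities and errors differ in length")
  if (length(d) < 3) stop_wingmark("need at least 3 points")
  out_mask <- abs(d - mean(d)) > sd_cut * sd(d) |
    abs(e - mean(e)) > sd_cut * sd(e)
  if (sum(!out_mask) < 3) stop_wingmark("fewer than 3 points remain after trimming")
  fit <- lm(e[!out_mask] ~ d[!out_mask])
  r2 <- cor(d[!out_mask], e[!out_mask])^2
  r2_all <- cor(d, e)^2
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, r_squared_all = r2_all,
    outlier_mask = out_mask, n_used = sum(!out_mask),
    data = tibble::tibble(disparity = d, mean_error = e,
                          inlier = !out_mask)
  ), class = "bias_regression")
}

#' @exportS3Method generics::tidy
tidy.bias_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "disparity"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.bias_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, r_squared_all = x$r_squared_all,
                 n_used = x$n_used, n_removed = sum(x$outlier_mask))
}

#' @export
print.bias_regression <- function(x, ...) {
  cat(sprintf(
    "Shape-bias regression: slope %.3g, R^2 %.3f (%.3f before outlier removal), n = %d (%d removed)\n",
    x$slope, x$r_squared, x$r_squared_all, x$n_used, sum(x$outlier_mask)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.bias_regression <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$disparity, .data$mean_error,
                               colour = .data$inlier)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "royalblue") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30", `FALSE` = "orange")) +
    ggplot2::labs(x = "Procrustes disparity", y = "mean pixel distance error",
                  colour = "inlier") +
    ggplot2::theme_minimal()
}
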