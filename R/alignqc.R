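#' Finite-population sample statistics
#'
#' Margin of error for an estimated proportion under the normal
#' approximation with finite-population correction (FPC):
#' `z * sqrt(p(1-p)/n) * sqrt((N-n)/(N-1))`. With `N = Inf` the FPC factor
#' is 1 and the ordinary binomial margin is returned. These margins size the
#' manual samples used to estimate the proportion of incomplete wings and of
#' misaligned pages.
#'
#' @param p_hat estimated proportion.
#' @param n sample size.
#' @param N population size (may be `Inf`).
#' @param z normal quantile (1.96 for a 95% interval).
#' @return `binomial_margin()`: the half-width of the interval, on the
#'   proportion scale.
#' @examples
#' binomial_margin(0.13, 200, 14354)  # ~0.0463
#' @export
binomial_margin <- function(p_hat, n, N = Inf, z = 1.96) {
  if (p_hat < 0 || p_hat > 1) stop_wingmark("p_hat must lie in [0, 1]")
  if (n < 1 || n > N) stop_wingmark("need 1 <= n <= N")
  fpc <- if (is.finite(N)) sqrt((N - n) / (N - 1)) else 1
  z * sqrt(p_hat * (1 - p_hat) / n) * fpc
}

#' @rdname binomial_margin
#' @return `sample_estimate()`: a one-row tibble
#'   `(p_hat, n, N, z, margin, lower, upper)`.
#' @export
sample_estimate <- function(p_hat, n, N = Inf, z = 1.96) {
  m <- binomial_margin(p_hat, n, N, z)
  tibble::tibble(p_hat = p_hat, n = n, N = N, z = z, margin = m,
                 lower = max(0, p_hat - m), upper = min(1, p_hat + m))
}

resolve_predicted_lengths <- function(predictions, mm_per_px = 0.007) {
  if (!is.null(predictions[["pred_length_mm"]])) {
    if (is.null(predictions[["volume"]]) && !is.null(predictions[["name"]])) {
      predictions <- dplyr::left_join(predictions, parse_wing_id(predictions$name),
                                      by = "name")
    }
    return(predictions)
  }
  if (!is.null(predictions[["x1"]])) {
    lmks <- table_to_landmarks(predictions)
    lens <- vapply(lmks, wing_length_mm, numeric(1), scale = mm_per_px)
    ids <- parse_wing_id(predictions$name)
    return(dplyr::mutate(ids, pred_length_mm = lens))
  }
  stop_wingmark("predictions must carry pred_length_mm or landmark columns x1..y11")
}

#' Page-level alignment QC via the wing-length quasi-identifier
#'
#' For every archive page, regress the predicted wing length (landmark 1-6
#' distance at 0.007 mm/px) against the recorded measured length `wlm` of
#' the associated biological record. Well-aligned pages show a strong
#' linear relationship; pages whose R-squared (squared Pearson correlation)
#' falls below the threshold (default 0.1) are flagged as likely misaligned
#' and routed to review. Pages with too few usable wings or no length
#' variance are marked degenerate — surfaced, never silently passed.
#'
#' @param records tibble with `volume, page, line, wlm`.
#' @param predictions tibble with image identities and either a
#'   `pred_length_mm` column or landmark columns `x1..y11` plus `name`.
#' @param threshold R-squared below which a page is flagged.
#' @param min_points minimum usable wings per page.
#' @param mm_per_px digitisation scale used when lengths are derived from
#'   landmarks.
#' @return a `page_alignment_report` tibble:
#'   `(volume, page, n_wings, r_squared, flagged, degenerate)`.
#' @export
page_r_squared <- function(records, predictions, threshold = 0.1,
                           min_points = 3L, mm_per_px = 0.007) {
  if (nrow(records) == 0) stop_wingmark("no records supplied")
  preds <- resolve_predicted_lengths(predictions, mm_per_px)
  joined <- dplyr::inner_join(
    dplyr::select(records, "volume", "page", "line", "wlm"),
    dplyr::select(preds, "volume", "page", "line", "side", "pred_length_mm"),
    by = c("volume", "page", "line"),
    relationship = "one-to-many"
  )
  if (nrow(joined) == 0) stop_wingmark("records and predictions share no pages")
  out <- dplyr::group_modify(
    dplyr::group_by(joined, .data$volume, .data$page),
    function(df, key) {
      ok <- is.finite(df$wlm) & is.finite(df$pred_length_mm)
      df <- df[ok, ]
      degenerate <- nrow(df) < min_points ||
        sd(df$wlm) < 1e-12 || sd(df$pred_length_mm) < 1e-12
      r2 <- if (degenerate) NA_real_ else cor(df$wlm, df$pred_length_mm)^2
      tibble::tibble(n_wings = nrow(df), r_squared = r2,
                     flagged = isFALSE(degenerate) && !is.na(r2) && r2 < threshold,
                     degenerate = degenerate)
    }
  )
  out <- dplyr::ungroup(out)
  structure(out, class = c("page_alignment_report", class(out)),
            threshold = threshold)
}

#' Measured vs predicted wing-length agreement
#'
#' After misalignment correction, the predicted lengths are regressed on
#' the dissector-measured `wlm` over the whole data set. The residual
#' standard error defines a global prediction band (fit +/- z * SE); points
#' outside it are flagged as outliers with their image identities for
#' manual review (remaining misalignments, missed incomplete wings, or
#' dissector errors). Hatchet-cell measurement cases must be excluded by
#' the caller via `excluded`.
#'
#' @param records tibble with `volume, page, line, wlm`.
#' @param predictions as in [page_r_squared()].
#' @param excluded optional logical vector over records (or vector of `vpn`
#'   strings) marking records measured on the hatchet cell rather than
#'   landmarks 1-6.
#' @param z band half-width in residual standard errors.
#' @param mm_per_px digitisation scale.
#' @return a `length_agreement` object: `slope`, `intercept`, `r_squared`,
#'   `sigma` (residual SE), `outliers` (tibble of flagged wings), `data`,
#'   `n`.
#' @export
length_agreement <- function(records, predictions, excluded = NULL,
                             z = 1.96, mm_per_px = 0.007) {
  if (!is.null(excluded)) {
    if (is.character(excluded)) {
      keep <- !(vpn_string(records$volume, records$page, records$line) %in% excluded)
    } else {
      keep <- !excluded
    }
    records <- records[keep, ]
  }
  preds <- resolve_predicted_lengths(predictions, mm_per_px)
  joined <- dplyr::inner_join(
    dplyr::select(records, "volume", "page", "line", "wlm"),
    dplyr::select(preds, "volume", "page", "line", "side", "pred_length_mm"),
    by = c("volume", "page", "line"),
    relationship = "one-to-many"
  )
  joined <- joined[is.finite(joined$wlm) & is.finite(joined$pred_length_mm), ]
  n <- nrow(joined)
  if (n < 3) stop_wingmark("need at least 3 usable points")
  fit <- lm(pred_length_mm ~ wlm, data = joined)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  joined$residual <- stats::residuals(fit)
  # guard against flagging pure floating-point noise on exact fits
  joined$outlier <- abs(joined$residual) > pmax(z * sigma, 1e-9)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = cor(joined$wlm, joined$pred_length_mm)^2, sigma = sigma, z = z,
    outliers = joined[joined$outlier, ], data = joined, n = n
  ), class = "length_agreement")
}

#' @exportS3Method generics::glance
glance.length_agreement <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, sigma = x$sigma, n = x$n,
                 n_outliers = nrow(x$outliers),
                 outlier_frac = nrow(x$outliers) / x$n)
}

#' @exportS3Method generics::tidy
tidy.length_agreement <- function(x, ...) x$data

#' @export
print.length_agreement <- function(x, ...) {
  cat(sprintf(
    "Measured vs predicted wing length: R^2 %.3f, slope %.3f, residual SE %.4f mm\n",
    x$r_squared, x$slope, x$sigma))
  cat(sprintf("  %d/%d points outside the %.2f-SE prediction band (%.2f%%)\n",
              nrow(x$outliers), x$n, x$z, 100 * nrow(x$outliers) / x$n))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.length_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$wlm, .data$pred_length_mm,
                               colour = .data$outlier)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = object$intercept + object$slope * .data$wlm - object$z * object$sigma,
      ymax = object$intercept + object$slope * .data$wlm + object$z * object$sigma),
      fill = "lightcyan", colour = NA) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "royalblue") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "measured wing length wlm (mm)",
                  y = "predicted wing length (mm)", colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Apply a correction log to an image-record association
#'
#' Flagged pages are reviewed and corrected through a machine-readable log
#' with one action per page: `shift_association` (relink images at and
#' after `from_line` to the record `param` lines ahead — +1 undoes a
#' skipped-image error, -1 a duplication), `remove_line`, or `remove_page`.
#' Exact duplicate associations arising from a -1 shift are dropped with a
#' note.
#'
#' @param images association tibble with at least
#'   `(name, volume, page, line, side)`.
#' @param corrections tibble `(volume, page, action, param, from_line, note)`;
#'   `param`/`from_line` may be `NA` for removals.
#' @return list with the corrected `images` tibble and the applied `log`.
#' @export
reconcile <- function(images, corrections) {
  if (nrow(corrections) == 0) return(list(images = images, log = corrections))
  known <- unique(paste(images$volume, images$page))
  asked <- paste(corrections$volume, corrections$page)
  if (any(!asked %in% known)) {
    stop_wingmark("correction references unknown page(s): %s",
                  paste(unique(asked[!asked %in% known]), collapse = ", "))
  }
  for (i in seq_len(nrow(corrections))) {
    cr <- corrections[i, ]
    on_page <- images$volume == cr$volume & images$page == cr$page
    if (cr$action == "remove_page") {
      images <- images[!on_page, ]
    } else if (cr$action == "remove_line") {
      images <- images[!(on_page & images$line == cr$param), ]
    } else if (cr$action == "shift_association") {
      from <- if (is.na(cr$from_line)) 1L else cr$from_line
      sel <- on_page & images$line >= from
      images$line[sel] <- images$line[sel] + cr$param
      images <- images[!(images$volume == cr$volume & images$page == cr$page &
                           images$line < 1), ]
      images <- images[!duplicated(images[, c("volume", "page", "line", "side")]), ]
    } else {
      stop_wingmark("unknown correction action: %s", cr$action)
    }
  }
  list(images = images, log = corrections)
}

#' @rdname reconcile
#' @param report a `page_alignment_report`.
#' @param records,predictions as in [page_r_squared()].
#' @param r2_accept minimum post-correction R-squared for a shift to be
#'   proposed; otherwise the page is proposed for removal.
#' @param threshold,mm_per_px as in [page_r_squared()].
#' @return `suggest_corrections()`: a correction-log tibble for the flagged
#'   and degenerate pages, found by searching candidate association shifts
#'   and keeping the one maximising the page R-squared.
#' @export
suggest_corrections <- function(report, records, predictions,
                                r2_accept = 0.8, threshold = 0.1,
                                mm_per_px = 0.007) {
  preds <- resolve_predicted_lengths(predictions, mm_per_px)
  bad <- report[report$flagged | report$degenerate, ]
  logs <- list()
  for (i in seq_len(nrow(bad))) {
    v <- bad$volume[i]; p <- bad$page[i]
    rec <- records[records$volume == v & records$page == p, ]
    prd <- preds[preds$volume == v & preds$page == p, ]
    lines <- sort(unique(prd$line))
    best <- list(r2 = -Inf, param = NA_integer_, from = NA_integer_)
    for (from in lines) {
      for (k in c(1L, -1L)) {
        shifted <- prd
        sel <- shifted$line >= from
        shifted$line[sel] <- shifted$line[sel] + k
        shifted <- shifted[!duplicated(shifted[, c("line", "side")]) &
                             shifted$line >= 1, ]
        j <- dplyr::inner_join(rec, shifted[, c("line", "pred_length_mm")],
                               by = "line", relationship = "one-to-many")
        if (nrow(j) < 3 || sd(j$wlm) < 1e-12) next
        r2 <- cor(j$wlm, j$pred_length_mm)^2
        if (is.finite(r2) && r2 > best$r2) best <- list(r2 = r2, param = k, from = from)
      }
    }
    logs[[length(logs) + 1L]] <- if (is.finite(best$r2) && best$r2 >= r2_accept) {
      tibble::tibble(volume = v, page = p, action = "shift_association",
                     param = best$param, from_line = best$from,
                     note = sprintf("post-correction R^2 = %.3f", best$r2))
    } else {
      tibble::tibble(volume = v, page = p, action = "remove_page",
                     param = NA_integer_, from_line = NA_integer_,
                     note = "no association shift restores agreement")
    }
  }
  if (!length(logs)) {
    return(tibble::tibble(volume = integer(), page = integer(),
                          action = character(), param = integer(),
                          from_line = integer(), note = character()))
  }
  dplyr::bind_rows(logs)
}
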