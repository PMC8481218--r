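#' Loess trend with pointwise standard errors
#'
#' Fits a locally weighted polynomial regression of the indicator against
#' the axis and returns, per sample, the smoothed value and the standard
#' error of that fitted value, plus a single effective-degrees-of-freedom
#' estimate from the smoother-matrix trace corrections. The fit uses exact
#' (non-interpolated) evaluation so that it agrees with an explicit
#' weighted-least-squares hat matrix to numerical precision. Invalid samples
#' are excluded from the fit and stay masked in the result.
#'
#' @param x an `indicator_series` (or anything [rolling_ar1()] accepts).
#' @param span smoothing span: fraction of samples in each local
#'   neighbourhood, `0 < span <= 1`; default 1 (every point sees the whole
#'   series through tricube weights).
#' @param degree local polynomial degree (default 2).
#' @param axis axis positions when `x` is a bare vector.
#' @return An object of class `loess_band_fit`: a tibble `(axis, value,
#'   fitted, se, valid)` with attributes `edf`, `span`, `degree`,
#'   `residual_scale`, `indicator`.
#' @seealso [confidence_band()], [small_scale_signals()], [large_scale_signals()]
#' @export
loess_fit_with_se <- function(x, span = 1, degree = 2, axis = NULL) {
  s <- as_indicator(x, axis)
  if (!(span > 0 && span <= 1)) abort("`span` must be in (0, 1]")
  ok <- s$valid & !is.na(s$value)
  if (sum(ok) < degree + 2) {
    abort(paste0("loess needs at least ", degree + 2, " valid samples; have ",
                 sum(ok)))
  }
  df <- data.frame(pos = s$axis[ok], val = s$value[ok])
  fit <- suppressWarnings(loess(
    val ~ pos, data = df, span = span, degree = degree,
    control = loess.control(surface = "direct", statistics = "exact")
  ))
  pr <- suppressWarnings(predict(fit, se = TRUE))
  fitted <- rep(NA_real_, nrow(s))
  se <- rep(NA_real_, nrow(s))
  fitted[ok] <- as.numeric(pr$fit)
  se[ok] <- as.numeric(pr$se.fit)
  # exactly reproduced data give residual variance 0; clip the numerical dust
  se[ok][!is.finite(se[ok])] <- 0
  structure(tibble(axis = s$axis, value = s$value, fitted = fitted, se = se,
                   valid = ok),
            class = c("loess_band_fit", class(tibble())),
            edf = as.numeric(pr$df), span = span, degree = degree,
            residual_scale = as.numeric(pr$residual.scale),
            indicator = indicator_name(s), loess = fit)
}

#' @export
print.loess_band_fit <- function(x, ...) {
  cat("<loess_band_fit> ", attr(x, "indicator"), ": span ", attr(x, "span"),
      ", degree ", attr(x, "degree"), ", edf ",
      format(attr(x, "edf"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' @method glance loess_band_fit
#' @export
glance.loess_band_fit <- function(x, ...) {
  tibble(indicator = attr(x, "indicator"), n = sum(x$valid),
         span = attr(x, "span"), degree = attr(x, "degree"),
         edf = attr(x, "edf"), residual_scale = attr(x, "residual_scale"))
}

#' Pointwise confidence band around a loess trend
#'
#' Band edges are `fitted +/- qt(quantile_prob, edf) * se`, the construction
#' used for flagging statistically notable excursions of an indicator. Note
#' that with the default `quantile_prob = 0.95` the multiplier is the
#' one-sided 0.95 Student-t quantile even though the band is conventionally
#' labelled a "95% pointwise confidence band"; pass `quantile_prob = 0.975`
#' for a true two-sided 95% band.
#'
#' @param fit a [loess_fit_with_se()] result.
#' @param quantile_prob probability for the Student-t quantile (default 0.95).
#' @return A `confidence_band` tibble `(axis, value, fitted, se, lower,
#'   upper, valid)` with attributes `quantile_prob`, `edf`, `level_label`.
#' @export
confidence_band <- function(fit, quantile_prob = 0.95) {
  stopifnot(inherits(fit, "loess_band_fit"))
  tq <- qt(quantile_prob, attr(fit, "edf"))
  out <- dplyr::mutate(as_tibble(fit),
                       lower = .data$fitted - tq * .data$se,
                       upper = .data$fitted + tq * .data$se)
  structure(out, class = c("confidence_band", class(tibble())),
            quantile_prob = quantile_prob, edf = attr(fit, "edf"),
            t_multiplier = tq, indicator = attr(fit, "indicator"),
            level_label = paste0(format(100 * (2 * quantile_prob - 1)),
                                 "% pointwise confidence band"))
}

new_signal_set <- function(small, large, indicator) {
  structure(list(small = small, large = large, indicator = indicator),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set> ", x$indicator, ": ", nrow(x$small), " small-scale, ",
      nrow(x$large), " large-scale signal(s)\n", sep = "")
  if (nrow(x$small)) print(x$small)
  if (nrow(x$large)) print(x$large)
  invisible(x)
}

#' Small-scale signals: excursions outside the confidence band
#'
#' A valid sample strictly above the upper band edge is a peak; strictly
#' below the lower edge, a trough. Boundary ties are not signals.
#'
#' @param band a [confidence_band()].
#' @return A tibble `(sample, axis, kind, value, fitted, lower, upper,
#'   half_width, indicator)` with `kind` in `peak`/`trough`.
#' @export
small_scale_signals <- function(band) {
  stopifnot(inherits(band, "confidence_band"))
  b <- as_tibble(band)
  b$sample <- seq_len(nrow(b))
  out <- dplyr::filter(b, .data$valid,
                       .data$value > .data$upper | .data$value < .data$lower)
  dplyr::transmute(out,
    sample = .data$sample, axis = .data$axis,
    kind = as.character(ifelse(.data$value > .data$upper, "peak", "trough")),
    value = .data$value, fitted = .data$fitted,
    lower = .data$lower, upper = .data$upper,
    half_width = (.data$upper - .data$lower) / 2,
    indicator = attr(band, "indicator"))
}

#' Large-scale signals: persistent trend and slope changes of the fit
#'
#' Works on the first differences (per-axis-unit slopes) of the fitted
#' curve. A *trend change* is an interval boundary where the slope sign
#' flips and the new sign persists for at least `min_run` intervals
#' (direction `up`/`down`). A *slope change* is a boundary without sign flip
#' where the mean absolute slope over the following `min_run` intervals
#' differs from the preceding `min_run` by a factor of at least
#' `slope_factor` (direction `steeper`/`gentler`). Runs of consecutive
#' qualifying boundaries of one kind and direction are reported as a single
#' signal with an axis interval.
#'
#' @param fit a [loess_fit_with_se()] result with at least
#'   `2 * min_run + 1` valid samples.
#' @param min_run persistence length in intervals (default 3).
#' @param slope_factor multiplicative slope-change threshold (default 2).
#' @return A tibble `(kind, direction, start_sample, end_sample, axis_start,
#'   axis_end, indicator)`.
#' @export
large_scale_signals <- function(fit, min_run = 3, slope_factor = 2) {
  stopifnot(inherits(fit, "loess_band_fit"), min_run >= 1, slope_factor > 1)
  idx <- which(fit$valid)
  n <- length(idx)
  empty <- tibble(kind = character(), direction = character(),
                  start_sample = integer(), end_sample = integer(),
                  axis_start = numeric(), axis_end = numeric(),
                  indicator = character())
  if (n < 2 * min_run + 1) return(empty)
  pos <- fit$axis[idx]
  slope <- diff(fit$fitted[idx]) / diff(pos)
  ni <- length(slope)
  hits <- list()
  for (i in seq_len(ni - 1)) {            # boundary between interval i, i+1
    s1 <- sign(slope[i]); s2 <- sign(slope[i + 1])
    if (s1 != 0 && s2 != 0 && s1 != s2) {
      if (i + min_run <= ni && all(sign(slope[(i + 1):(i + min_run)]) == s2)) {
        hits[[length(hits) + 1]] <- list(b = i, kind = "trend_change",
                                         direction = if (s2 > 0) "up" else "down")
      }
    } else if (i >= min_run && i + min_run <= ni) {
      pre <- mean(slope[(i - min_run + 1):i])
      post <- mean(slope[(i + 1):(i + min_run)])
      if (pre != 0 && post != 0 && sign(pre) == sign(post)) {
        ratio <- abs(post) / abs(pre)
        if (ratio >= slope_factor || ratio <= 1 / slope_factor) {
          hits[[length(hits) + 1]] <- list(
            b = i, kind = "slope_change",
            direction = if (ratio > 1) "steeper" else "gentler")
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  h <- dplyr::bind_rows(lapply(hits, as_tibble))
  # group runs of adjacent boundaries with identical kind + direction
  h <- dplyr::arrange(h, .data$b)
  grp <- cumsum(c(TRUE, diff(h$b) > 1 |
                    h$kind[-1] != h$kind[-nrow(h)] |
                    h$direction[-1] != h$direction[-nrow(h)]))
  dplyr::summarise(dplyr::group_by(h, grp = grp, kind = .data$kind,
                                   direction = .data$direction),
                   start_sample = idx[min(.data$b) + 1L],
                   end_sample = idx[max(.data$b) + 1L],
                   .groups = "drop") |>
    dplyr::mutate(axis_start = fit$axis[.data$start_sample],
                  axis_end = fit$axis[.data$end_sample],
                  indicator = attr(fit, "indicator")) |>
    dplyr::select(-"grp") |>
    dplyr::arrange(.data$start_sample)
}

#' Extract all signals of one indicator
#'
#' Convenience wrapper: loess fit, band, small- and large-scale signals in
#' one call.
#'
#' @inheritParams loess_fit_with_se
#' @inheritParams confidence_band
#' @inheritParams large_scale_signals
#' @return A `signal_set` list with tibbles `small` and `large`.
#' @export
extract_signals <- function(x, span = 1, degree = 2, quantile_prob = 0.95,
                            min_run = 3, slope_factor = 2, axis = NULL) {
  fit <- loess_fit_with_se(x, span = span, degree = degree, axis = axis)
  band <- confidence_band(fit, quantile_prob)
  new_signal_set(small_scale_signals(band),
                 large_scale_signals(fit, min_run, slope_factor),
                 attr(fit, "indicator"))
}

#' Write a combined signals table as TSV
#'
#' @param signal_sets list of `signal_set` objects.
#' @param path output file path.
#' @export
write_signals_tsv <- function(signal_sets, path) {
  small <- dplyr::bind_rows(lapply(signal_sets, function(s) s$small))
  large <- dplyr::bind_rows(lapply(signal_sets, function(s) s$large))
  rows <- dplyr::bind_rows(
    if (nrow(small)) dplyr::transmute(small, axis = .data$axis,
      indicator = .data$indicator, kind = .data$kind,
      direction = NA_character_, half_width = .data$half_width),
    if (nrow(large)) dplyr::transmute(large, axis = .data$axis_start,
      indicator = .data$indicator, kind = .data$kind,
      direction = .data$direction, half_width = NA_real_)
  )
  if (is.null(rows)) rows <- tibble(axis = numeric(), indicator = character(),
                                    kind = character(), direction = character(),
                                    half_width = numeric())
  utils::write.table(as.data.frame(rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
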