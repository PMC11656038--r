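trend_value <- function(trial_id, method, scale_ms, eye, value_px, quality,
                        eyes_used = eye) {
  data.frame(trial_id = trial_id, method = method, scale_ms = scale_ms,
             eye = eye, value_px = value_px, quality = quality,
             eyes_used = eyes_used, stringsAsFactors = FALSE)
}

series_index <- function(series, t_ms) {
  period <- 1000 / series$sample_rate
  as.integer(round((t_ms - series$t[1]) / period)) + 1L
}

#' Centered moving average of a pupil series
#'
#' Smooths the series with a centered boxcar of `window_s` seconds: the
#' value at sample `i` is the mean over samples `i - h .. i + h` with
#' `h = round(window_s * sample_rate / 2)`. Positions whose window exceeds
#' the recording are returned as `NA` rather than partially averaged.
#'
#' @param series A `clean_series`.
#' @param window_s Window length in seconds.
#' @return A `clean_series` whose `value` holds the smoothed diameters
#'   (`NA` where unavailable).
#' @export
moving_average <- function(series, window_s) {
  stopifnot(inherits(series, "clean_series"), window_s > 0)
  x <- series$value
  n <- length(x)
  h <- as.integer(round(window_s * series$sample_rate / 2))
  if (2L * h + 1L > n) stop("window too long: ", window_s, " s exceeds recording")
  # running sum via cumulative sums (long-double accumulator in R)
  cs <- c(0, cumsum(x))
  out <- rep(NA_real_, n)
  idx <- (h + 1L):(n - h)
  out[idx] <- (cs[idx + h + 1L] - cs[idx - h]) / (2 * h + 1)
  res <- series
  res$value <- out
  res
}

window_mean <- function(series, i_lo, i_hi) {
  mean(series$value[i_lo:i_hi])
}

flank_quality <- function(series, i_lo, i0, i_hi, max_interp_frac) {
  f_pre <- mean(series$interpolated[i_lo:i0])
  f_post <- mean(series$interpolated[i0:i_hi])
  if (f_pre > max_interp_frac || f_post > max_interp_frac) "rejected" else "complete"
}

#' Smoothed pupil trend at an event
#'
#' The signed pupil-diameter change over a `window_s`-second span centered
#' on the event: the mean diameter over `[t0, t0 + w]` minus the mean over
#' `[t0 - w, t0]` (equivalently, the centered moving average read at
#' `t0 + w/2` minus at `t0 - w/2`). Positive values indicate dilation
#' across the event.
#'
#' @param series A `clean_series`.
#' @param t0 Event (target onset) time in ms on the recording clock.
#' @param window_s Smoothing window in seconds (analysis uses 5, 10, 15).
#' @param max_interp_frac Maximum tolerated interpolated fraction in either
#'   flanking window before the trial is rejected (default 0.5).
#' @param trial_id Optional trial label carried into the result.
#' @return One-row data.frame: `trial_id`, `method`, `scale_ms`, `eye`,
#'   `value_px`, `quality` (`complete`, `incomplete`, or `rejected`).
#' @export
smoothed_trend <- function(series, t0, window_s, max_interp_frac = 0.5,
                           trial_id = NA) {
  stopifnot(inherits(series, "clean_series"), window_s > 0)
  n <- length(series$t)
  if (t0 < series$t[1] || t0 > series$t[n])
    stop("event outside recording: t0 = ", t0, " ms")
  w <- as.integer(round(window_s * series$sample_rate))
  i0 <- series_index(series, t0)
  i_lo <- i0 - w
  i_hi <- i0 + w
  scale_ms <- window_s * 1000
  if (i_lo < 1L || i_hi > n)
    return(trend_value(trial_id, "smoothed", scale_ms, series$eye,
                       NA_real_, "incomplete"))
  value <- window_mean(series, i0, i_hi) - window_mean(series, i_lo, i0)
  q <- flank_quality(series, i_lo, i0, i_hi, max_interp_frac)
  trend_value(trial_id, "smoothed", scale_ms, series$eye, value, q)
}

#' Conservative pupil trend at an event
#'
#' A phasic-immune variant: the change over a `span_s`-second interval using
#' a `window_s`-second mean on each side, leaving a gap of
#' `(span_s - window_s)/2` seconds around the event. With the defaults
#' (window 10 s, span 14 s) the value is the mean diameter over
#' `[t0 + 2 s, t0 + 12 s]` minus the mean over `[t0 - 12 s, t0 - 2 s]`, so
#' it is exactly insensitive to any signal confined to within 2 s of the
#' event.
#'
#' @inheritParams smoothed_trend
#' @param window_s Averaging window per side in seconds (default 10).
#' @param span_s Total span of the change measurement in seconds
#'   (default 14); must exceed `window_s`.
#' @return One-row trend data.frame as in [smoothed_trend()], with
#'   `method = "conservative"` and `scale_ms = span_s * 1000`.
#' @export
conservative_trend <- function(series, t0, window_s = 10, span_s = 14,
                               max_interp_frac = 0.5, trial_id = NA) {
  stopifnot(inherits(series, "clean_series"), span_s > window_s)
  n <- length(series$t)
  if (t0 < series$t[1] || t0 > series$t[n])
    stop("event outside recording: t0 = ", t0, " ms")
  rate <- series$sample_rate
  gap <- as.integer(round((span_s - window_s) / 2 * rate))
  w <- as.integer(round(window_s * rate))
  i0 <- series_index(series, t0)
  a_lo <- i0 - gap - w; a_hi <- i0 - gap
  b_lo <- i0 + gap;     b_hi <- i0 + gap + w
  scale_ms <- span_s * 1000
  if (a_lo < 1L || b_hi > n)
    return(trend_value(trial_id, "conservative", scale_ms, series$eye,
                       NA_real_, "incomplete"))
  value <- window_mean(series, b_lo, b_hi) - window_mean(series, a_lo, a_hi)
  f_a <- mean(series$interpolated[a_lo:a_hi])
  f_b <- mean(series$interpolated[b_lo:b_hi])
  q <- if (f_a > max_interp_frac || f_b > max_interp_frac) "rejected" else "complete"
  trend_value(trial_id, "conservative", scale_ms, series$eye, value, q)
}

#' Decomposed pupil trend at an event
#'
#' Two-point readout from one dyadic-scale component of the multiresolution
#' decomposition: the component value at `t0 + scale/2` minus the value at
#' `t0 - scale/2`. Readouts whose points fall within one scale-length of a
#' recording boundary are flagged incomplete (boundary effects of the
#' padded transform).
#'
#' @param components A `pupil_mra` from [mra_decompose()].
#' @param t0 Event time in ms.
#' @param scale_ms One of the decomposed scales present in `components`.
#' @param max_interp_frac Maximum tolerated interpolated fraction in either
#'   flanking half-window `[t0 - scale/2, t0]`, `[t0, t0 + scale/2]`.
#' @param trial_id Optional trial label.
#' @return One-row trend data.frame with `method = "decomposed"`.
#' @export
decomposed_trend <- function(components, t0, scale_ms, max_interp_frac = 0.5,
                             trial_id = NA) {
  stopifnot(inherits(components, "pupil_mra"))
  key <- as.character(scale_ms)
  if (!key %in% names(components$details))
    stop("unsupported scale ", scale_ms, " ms; available: ",
         paste(names(components$details), collapse = ", "))
  t <- components$t
  n <- length(t)
  period <- 1000 / components$sample_rate
  half <- scale_ms / 2
  i_minus <- as.integer(round((t0 - half - t[1]) / period)) + 1L
  i_plus <- as.integer(round((t0 + half - t[1]) / period)) + 1L
  i0 <- as.integer(round((t0 - t[1]) / period)) + 1L
  if (i_minus < 1L || i_plus > n)
    return(trend_value(trial_id, "decomposed", scale_ms, components$eye,
                       NA_real_, "incomplete"))
  # within one scale-length of a boundary: transform padding dominates
  guard <- as.integer(round(scale_ms / period))
  if (i_minus - 1L < guard || n - i_plus < guard)
    return(trend_value(trial_id, "decomposed", scale_ms, components$eye,
                       NA_real_, "incomplete"))
  d <- components$details[[key]]
  value <- d[i_plus] - d[i_minus]
  f_pre <- mean(components$interpolated[i_minus:i0])
  f_post <- mean(components$interpolated[i0:i_plus])
  q <- if (f_pre > max_interp_frac || f_post > max_interp_frac)
    "rejected" else "complete"
  trend_value(trial_id, "decomposed", scale_ms, components$eye, value, q)
}

#' Combine per-eye trend values into a binocular index
#'
#' Binocular trend = arithmetic mean of the two per-eye values when both
#' are complete. If exactly one eye is complete its value is returned and
#' flagged monocular (`eyes_used` names the eye); if neither is complete
#' the result is rejected.
#'
#' @param left,right One-row trend data.frames for the same trial, method,
#'   and scale.
#' @return One-row trend data.frame with `eye = "binocular"`.
#' @export
binocular_trend <- function(left, right) {
  same <- function(f) identical(left[[f]], right[[f]]) ||
    (is.na(left[[f]]) && is.na(right[[f]]))
  if (!same("trial_id") || !same("method") || !same("scale_ms"))
    stop("binocular_trend: mismatched trial, method, or scale")
  lc <- left$quality == "complete"
  rc <- right$quality == "complete"
  if (lc && rc) {
    trend_value(left$trial_id, left$method, left$scale_ms, "binocular",
                (left$value_px + right$value_px) / 2, "complete", "both")
  } else if (lc) {
    trend_value(left$trial_id, left$method, left$scale_ms, "binocular",
                left$value_px, "complete", left$eye)
  } else if (rc) {
    trend_value(left$trial_id, left$method, left$scale_ms, "binocular",
                right$value_px, "complete", right$eye)
  } else {
    trend_value(left$trial_id, left$method, left$scale_ms, "binocular",
                NA_real_, "rejected", "none")
  }
}

#' Convert a pixel trend value to millimetres
#'
#' Linear calibration through a single correspondence point: a diameter of
#' `calib_px` pixels maps to `calib_mm` mm (default 3,300 px = 4.5 mm, a
#' typical dark-adapted pupil against a dark background).
#'
#' @param value_px Value(s) in tracker pixels.
#' @param calib_px Calibration diameter in pixels (> 0).
#' @param calib_mm Calibration diameter in mm.
#' @return Value(s) in mm.
#' @export
px_to_mm <- function(value_px, calib_px = 3300, calib_mm = 4.5) {
  if (!is.numeric(calib_px) || calib_px <= 0)
    stop("calibration pixel size must be positive")
  value_px * calib_mm / calib_px
}

#' Compute the full trend table for one session
#'
#' Runs every requested trend method at every event for each available eye
#' and adds the binocular (eye-averaged) rows used by the group analyses.
#'
#' @param clean_left A `clean_series` for the left eye, or `NULL`.
#' @param clean_right A `clean_series` for the right eye, or `NULL`.
#' @param events Event table with at least `trial_id` (or `trial_index`)
#'   and `t_target_ms`.
#' @param windows_s Smoothing windows in seconds (default `c(5, 10, 15)`).
#' @param conservative List with `window_s` and `span_s` (defaults 10, 14),
#'   or `NULL` to skip.
#' @param scales_ms Decomposed dyadic scales in ms (default
#'   `c(4096, 8192, 16384, 32768)`), or `NULL` to skip the decomposition.
#' @param max_interp_frac Per-trial quality gate (see [smoothed_trend()]).
#' @return data.frame: `participant`, `trial_id`, `method`, `scale_ms`,
#'   `eye`, `value_px`, `quality`, `eyes_used`.
#' @export
compute_trend_table <- function(clean_left, clean_right, events,
                                windows_s = c(5, 10, 15),
                                conservative = list(window_s = 10, span_s = 14),
                                scales_ms = c(4096, 8192, 16384, 32768),
                                max_interp_frac = 0.5) {
  eyes <- list()
  if (!is.null(clean_left)) eyes$left <- clean_left
  if (!is.null(clean_right)) eyes$right <- clean_right
  if (!length(eyes)) stop("at least one eye's clean series is required")
  trial_ids <- if ("trial_id" %in% names(events)) events$trial_id else
    events$trial_index
  participant <- eyes[[1]]$participant_id

  mras <- lapply(eyes, function(s)
    if (is.null(scales_ms)) NULL else mra_decompose(s, scales_ms))

  one_eye <- function(series, mra) {
    rows <- list()
    for (k in seq_along(trial_ids)) {
      t0 <- events$t_target_ms[k]
      id <- trial_ids[k]
      for (w in windows_s)
        rows[[length(rows) + 1L]] <-
          smoothed_trend(series, t0, w, max_interp_frac, id)
      if (!is.null(conservative))
        rows[[length(rows) + 1L]] <-
          conservative_trend(series, t0, conservative$window_s,
                             conservative$span_s, max_interp_frac, id)
      if (!is.null(mra))
        for (sc in scales_ms)
          rows[[length(rows) + 1L]] <-
            decomposed_trend(mra, t0, sc, max_interp_frac, id)
    }
    do.call(rbind, rows)
  }

  per_eye <- Map(one_eye, eyes, mras[names(eyes)])
  tab <- do.call(rbind, per_eye)

  if (length(eyes) == 2L) {
    l <- per_eye$left; r <- per_eye$right
    bino <- do.call(rbind, lapply(seq_len(nrow(l)), function(i)
      binocular_trend(l[i, ], r[i, ])))
  } else {
    # monocular session: the single eye stands in for the binocular index
    bino <- per_eye[[1]]
    bino$eyes_used <- bino$eye
    bino$eye <- "binocular"
  }
  out <- rbind(tab, bino)
  out <- cbind(participant = participant, out)
  rownames(out) <- NULL
  out
}

# Vectorized event readouts used by the recovery experiments: same sample
# conventions as smoothed_trend()/decomposed_trend(), evaluated for many
# events at once via cumulative sums.
smoothed_trend_vec <- function(series, t0s, window_s, max_interp_frac = 0.5) {
  n <- length(series$t)
  w <- as.integer(round(window_s * series$sample_rate))
  i0 <- as.integer(round((t0s - series$t[1]) * series$sample_rate / 1000)) + 1L
  cs <- c(0, cumsum(series$value))
  ci <- c(0, cumsum(as.numeric(series$interpolated)))
  rsum <- function(cum, a, b) cum[b + 1L] - cum[a]
  ok <- i0 - w >= 1L & i0 + w <= n & i0 >= 1L & i0 <= n
  value <- rep(NA_real_, length(t0s))
  quality <- rep("incomplete", length(t0s))
  if (any(ok)) {
    a <- i0[ok] - w; b <- i0[ok] + w; c0 <- i0[ok]
    post <- rsum(cs, c0, b) / (w + 1)
    pre <- rsum(cs, a, c0) / (w + 1)
    f_pre <- rsum(ci, a, c0) / (w + 1)
    f_post <- rsum(ci, c0, b) / (w + 1)
    value[ok] <- post - pre
    quality[ok] <- ifelse(f_pre > max_interp_frac | f_post > max_interp_frac,
                          "rejected", "complete")
  }
  data.frame(value_px = value, quality = quality, stringsAsFactors = FALSE)
}

decomposed_trend_vec <- function(components, t0s, scale_ms,
                                 max_interp_frac = 0.5) {
  key <- as.character(scale_ms)
  if (!key %in% names(components$details))
    stop("unsupported scale ", scale_ms, " ms; available: ",
         paste(names(components$details), collapse = ", "))
  t1 <- components$t[1]
  n <- length(components$t)
  period <- 1000 / components$sample_rate
  half <- scale_ms / 2
  guard <- as.integer(round(scale_ms / period))
  i_minus <- as.integer(round((t0s - half - t1) / period)) + 1L
  i_plus <- as.integer(round((t0s + half - t1) / period)) + 1L
  i0 <- as.integer(round((t0s - t1) / period)) + 1L
  ci <- c(0, cumsum(as.numeric(components$interpolated)))
  rsum <- function(a, b) ci[b + 1L] - ci[a]
  ok <- i_minus - 1L >= guard & n - i_plus >= guard
  value <- rep(NA_real_, length(t0s))
  quality <- rep("incomplete", length(t0s))
  if (any(ok)) {
    d <- components$details[[key]]
    value[ok] <- d[i_plus[ok]] - d[i_minus[ok]]
    f_pre <- rsum(i_minus[ok], i0[ok]) / (i0[ok] - i_minus[ok] + 1L)
    f_post <- rsum(i0[ok], i_plus[ok]) / (i_plus[ok] - i0[ok] + 1L)
    quality[ok] <- ifelse(f_pre > max_interp_frac | f_post > max_interp_frac,
                          "rejected", "complete")
  }
  data.frame(value_px = value, quality = quality, stringsAsFactors = FALSE)
}

conservative_trend_vec <- function(series, t0s, window_s = 10, span_s = 14,
                                   max_interp_frac = 0.5) {
  n <- length(series$t)
  rate <- series$sample_rate
  gap <- as.integer(round((span_s - window_s) / 2 * rate))
  w <- as.integer(round(window_s * rate))
  i0 <- as.integer(round((t0s - series$t[1]) * rate / 1000)) + 1L
  cs <- c(0, cumsum(series$value))
  ci <- c(0, cumsum(as.numeric(series$interpolated)))
  rsum <- function(cum, a, b) cum[b + 1L] - cum[a]
  ok <- i0 - gap - w >= 1L & i0 + gap + w <= n
  value <- rep(NA_real_, length(t0s))
  quality <- rep("incomplete", length(t0s))
  if (any(ok)) {
    a_lo <- i0[ok] - gap - w; a_hi <- i0[ok] - gap
    b_lo <- i0[ok] + gap;     b_hi <- i0[ok] + gap + w
    value[ok] <- rsum(cs, b_lo, b_hi) / (w + 1) - rsum(cs, a_lo, a_hi) / (w + 1)
    f_a <- rsum(ci, a_lo, a_hi) / (w + 1)
    f_b <- rsum(ci, b_lo, b_hi) / (w + 1)
    quality[ok] <- ifelse(f_a > max_interp_frac | f_b > max_interp_frac,
                          "rejected", "complete")
  }
  data.frame(value_px = value, quality = quality, stringsAsFactors = FALSE)
}
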