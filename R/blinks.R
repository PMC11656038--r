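#' Detect blink segments in one eye's trace
#'
#' A blink core is any run of samples that is flagged invalid or has a
#' missing/non-positive diameter. Because eyelid closure contaminates the
#' flanking samples before the tracker loses the pupil, each core run is
#' first grown outward while the absolute sample-to-sample difference
#' exceeds `noise_k` times the median absolute deviation (MAD) of
#' sample-to-sample differences over the whole trace (a noise-robust
#' onset/offset criterion). A safety margin of `margin_ms` is then applied
#' on both sides, segments are clamped to the recording bounds, and
#' overlapping segments are merged.
#'
#' @param recording A [pupil_recording()].
#' @param eye `"left"` or `"right"`.
#' @param margin_ms Margin added before and after each detected blink
#'   (default 200 ms).
#' @param noise_k Multiplier on the MAD of first differences used for the
#'   flank-extension criterion (default 5).
#' @return A data.frame with columns `t_start`, `t_end` (ms, closed
#'   interval, margins applied) and `eye`; zero rows when the trace has no
#'   blink evidence.
#' @export
detect_blinks <- function(recording, eye, margin_ms = 200, noise_k = 5) {
  stopifnot(inherits(recording, "pupil_recording"))
  sig <- eye_signal(recording, eye)
  x <- sig$value
  core <- !sig$valid | !is.finite(x) | x <= 0
  n <- length(x)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      eye = character(0), stringsAsFactors = FALSE)
  if (!any(core)) return(empty)

  # noise threshold: noise_k * MAD of first differences, with blink-core
  # samples masked out so the zeros do not inflate the scale estimate
  xx <- x
  xx[core] <- NA_real_
  dm <- abs(diff(xx))
  dfin <- dm[is.finite(dm)]
  thr <- if (length(dfin) >= 10) noise_k * stats::mad(dfin, center = 0) else Inf
  if (!is.finite(thr) || thr <= 0) thr <- Inf

  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]

  # grow each run outward while the candidate flank sample deviates from
  # its outward neighbour by more than the noise threshold (raw diffs;
  # dr[j] is |x[j+1] - x[j]|)
  dr <- abs(diff(x))
  for (i in seq_along(run_start)) {
    a <- run_start[i]
    while (a > 2L && is.finite(dr[a - 2L]) && dr[a - 2L] > thr) a <- a - 1L
    b <- run_end[i]
    while (b < n - 1L && is.finite(dr[b + 1L]) && dr[b + 1L] > thr) b <- b + 1L
    run_start[i] <- a
    run_end[i] <- b
  }

  t <- recording$t
  seg_a <- pmax(t[run_start] - margin_ms, t[1])
  seg_b <- pmin(t[run_end] + margin_ms, t[n])
  merge_segments(seg_a, seg_b, eye)
}

merge_segments <- function(a, b, eye) {
  o <- order(a)
  a <- a[o]; b <- b[o]
  ka <- a[1]; kb <- b[1]
  out_a <- numeric(0); out_b <- numeric(0)
  if (length(a) > 1) {
    for (i in 2:length(a)) {
      if (a[i] <= kb) {
        kb <- max(kb, b[i])
      } else {
        out_a <- c(out_a, ka); out_b <- c(out_b, kb)
        ka <- a[i]; kb <- b[i]
      }
    }
  }
  out_a <- c(out_a, ka); out_b <- c(out_b, kb)
  data.frame(t_start = out_a, t_end = out_b, eye = eye,
             stringsAsFactors = FALSE)
}

#' Interpolate blink segments to a continuous clean series
#'
#' Samples inside the (margin-extended) blink segments are replaced by
#' linear interpolation between the nearest retained samples outside the
#' segments; gaps touching a recording edge are filled with the nearest
#' retained value (constant extension). Samples outside the segments are
#' passed through bitwise unchanged.
#'
#' @param recording A [pupil_recording()].
#' @param segments Segment table from [detect_blinks()] for the same
#'   recording and eye.
#' @param eye `"left"` or `"right"`.
#' @return An object of class `clean_series`: list with `t`, `value`,
#'   `interpolated` (logical mask of replaced samples), `sample_rate`,
#'   `eye`, `participant_id`.
#' @export
interpolate_blinks <- function(recording, segments, eye) {
  stopifnot(inherits(recording, "pupil_recording"))
  sig <- eye_signal(recording, eye)
  t <- recording$t
  x <- sig$value
  inside <- rep(FALSE, length(t))
  if (nrow(segments)) {
    # uniform grid: mark segments by index range
    period <- 1000 / recording$sample_rate
    a <- pmax(ceiling((segments$t_start - t[1]) / period - 1e-9) + 1L, 1L)
    b <- pmin(floor((segments$t_end - t[1]) / period + 1e-9) + 1L, length(t))
    for (i in seq_len(nrow(segments)))
      if (a[i] <= b[i]) inside[a[i]:b[i]] <- TRUE
  }
  keep <- !inside & sig$valid & is.finite(x) & x > 0
  if (!any(keep))
    stop("eye unusable: no valid samples for eye '", eye, "'")
  value <- x
  if (any(!keep)) {
    if (sum(keep) == 1L) {
      value[!keep] <- x[keep]
    } else {
      value[!keep] <- stats::approx(t[keep], x[keep], xout = t[!keep],
                                    method = "linear", rule = 2)$y
    }
  }
  structure(list(
    t = t,
    value = value,
    interpolated = !keep,
    sample_rate = recording$sample_rate,
    eye = eye,
    participant_id = recording$participant_id
  ), class = "clean_series")
}

#' @export
print.clean_series <- function(x, ...) {
  cat(sprintf("<clean_series> %s eye, %d samples @ %g Hz, %.1f%% interpolated\n",
              x$eye, length(x$t), x$sample_rate, 100 * mean(x$interpolated)))
  invisible(x)
}

#' Fraction of interpolated samples in a window
#'
#' Measures data quality around an event: the share of samples in
#' `[t_center - half_span_ms, t_center + half_span_ms]` that were filled by
#' blink interpolation.
#'
#' @param series A `clean_series` from [interpolate_blinks()].
#' @param t_center Window center in ms.
#' @param half_span_ms Half window span in ms.
#' @return List with `fraction` (in \[0, 1\]) and `incomplete` (`TRUE` when
#'   the window was truncated at a recording edge).
#' @export
interpolated_fraction <- function(series, t_center, half_span_ms) {
  stopifnot(inherits(series, "clean_series"))
  lo <- t_center - half_span_ms
  hi <- t_center + half_span_ms
  t <- series$t
  if (hi < t[1] || lo > t[length(t)]) stop("no data: window outside recording")
  in_win <- t >= lo & t <= hi
  list(fraction = mean(series$interpolated[in_win]),
       incomplete = lo < t[1] || hi > t[length(t)])
}
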