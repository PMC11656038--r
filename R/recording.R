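#' Construct a pupil recording
#'
#' Bundles one session's binocular pupil-diameter samples into a validated
#' `pupil_recording` object. Timestamps must be uniformly spaced at
#' `1000 / sample_rate` ms; diameters are in arbitrary tracker pixel units.
#'
#' @param t Numeric vector of sample timestamps in ms, strictly increasing
#'   with a constant step.
#' @param left,right Numeric vectors of pupil diameter per sample (pixels).
#'   `NA` or non-positive values are treated as missing downstream.
#' @param valid_left,valid_right Logical per-sample validity flags. Default
#'   all `TRUE`.
#' @param participant_id Opaque participant label.
#' @param sample_rate Samples per second (default 1000).
#'
#' @return An object of class `pupil_recording`: a list with fields `t`,
#'   `left`, `right`, `valid_left`, `valid_right`, `participant_id`,
#'   `sample_rate`.
#' @export
pupil_recording <- function(t, left, right,
                            valid_left = rep(TRUE, length(t)),
                            valid_right = rep(TRUE, length(t)),
                            participant_id = "P01",
                            sample_rate = 1000) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("recording needs at least two samples")
  if (length(left) != n || length(right) != n)
    stop("left/right must have the same length as t")
  if (length(valid_left) != n || length(valid_right) != n)
    stop("validity flags must have the same length as t")
  step <- 1000 / sample_rate
  dt <- diff(t)
  if (any(dt <= 0) || any(abs(dt - step) > 1e-6 * step))
    stop("timestamps must be strictly increasing with constant step 1000/sample_rate ms")
  structure(list(
    participant_id = as.character(participant_id),
    sample_rate = sample_rate,
    t = t,
    left = as.numeric(left),
    right = as.numeric(right),
    valid_left = as.logical(valid_left),
    valid_right = as.logical(valid_right)
  ), class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  dur <- (x$t[length(x$t)] - x$t[1]) / 1000
  cat(sprintf(
    "<pupil_recording> participant %s: %d samples @ %g Hz (%.1f s)\n",
    x$participant_id, length(x$t), x$sample_rate, dur))
  cat(sprintf("  invalid: left %d, right %d\n",
              sum(!x$valid_left), sum(!x$valid_right)))
  invisible(x)
}

eye_signal <- function(recording, eye) {
  eye <- match.arg(eye, c("left", "right"))
  list(value = recording[[eye]],
       valid = recording[[paste0("valid_", eye)]])
}

#' Read a pupil samples file
#'
#' Reads a delimited samples table with columns `t_ms, left_px, right_px,
#' valid_left, valid_right`. Empty or zero diameter fields are kept as-is
#' and handled by blink detection.
#'
#' @param path Path to a CSV/TSV samples file.
#' @param participant_id Participant label; default the file name stem.
#' @param sample_rate Samples per second; inferred from timestamps when `NULL`.
#' @return A [pupil_recording()].
#' @export
read_samples <- function(path, participant_id = NULL, sample_rate = NULL) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("t_ms", "left_px", "right_px", "valid_left", "valid_right")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("samples file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(sample_rate)) {
    step <- stats::median(diff(dt$t_ms))
    sample_rate <- 1000 / step
  }
  pupil_recording(dt$t_ms, dt$left_px, dt$right_px,
                  as.logical(dt$valid_left), as.logical(dt$valid_right),
                  participant_id = participant_id, sample_rate = sample_rate)
}

#' Write a pupil samples file
#'
#' @param recording A [pupil_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(recording, path) {
  stopifnot(inherits(recording, "pupil_recording"))
  data.table::fwrite(data.table::data.table(
    t_ms = recording$t,
    left_px = recording$left,
    right_px = recording$right,
    valid_left = recording$valid_left,
    valid_right = recording$valid_right
  ), path)
  invisible(path)
}
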