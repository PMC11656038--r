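# Symlet-4 (least-asymmetric Daubechies, 8 taps) quadrature-mirror pair,
# orthonormal normalisation (sum of scaling taps = sqrt(2)).
.sym4_scaling <- c(
  -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
   0.80373875180591614,  0.29785779560527736, -0.09921954357684722,
  -0.01260396726203783,  0.03222310060404270)
.sym4_wavelet <- c(
  -0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
   0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
   0.02963552764599851, -0.07576571478927333)

# circular shift right by k (x[t] <- x[t-k])
circ_shift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# One analysis stage of the maximal-overlap DWT at level j (shift step
# 2^(j-1)), circular boundary. Returns wavelet (W) and scaling (V) outputs.
modwt_stage <- function(v, level) {
  g <- .sym4_scaling / sqrt(2)
  h <- .sym4_wavelet / sqrt(2)
  s <- 2L^(level - 1L)
  w_out <- 0; v_out <- 0
  for (l in seq_along(g)) {
    shifted <- circ_shift(v, (l - 1L) * s)
    w_out <- w_out + h[l] * shifted
    v_out <- v_out + g[l] * shifted
  }
  list(W = w_out, V = v_out)
}

# One synthesis stage (transpose of the analysis stage).
imodwt_stage <- function(w, v, level) {
  g <- .sym4_scaling / sqrt(2)
  h <- .sym4_wavelet / sqrt(2)
  s <- 2L^(level - 1L)
  n <- length(v)
  out <- 0
  for (l in seq_along(g)) {
    k <- (n - (l - 1L) * s) %% n  # shift left by (l-1)*s
    out <- out + h[l] * circ_shift(w, k) + g[l] * circ_shift(v, k)
  }
  out
}

# Full MODWT pyramid to n_levels; returns list of wavelet coefficient
# vectors W[[j]] and the final scaling vector V.
modwt_pyramid <- function(x, n_levels) {
  v <- x
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    st <- modwt_stage(v, j)
    W[[j]] <- st$W
    v <- st$V
  }
  list(W = W, V = v)
}

# Reconstruct the level-j detail (or the level-J smooth when w is NULL)
# by running the synthesis chain from `level` back to level 1.
modwt_component <- function(coef, level, from_wavelet) {
  n <- length(coef)
  zero <- numeric(n)
  v <- if (from_wavelet) imodwt_stage(coef, zero, level) else
    imodwt_stage(zero, coef, level)
  if (level > 1L) {
    for (j in (level - 1L):1L) v <- imodwt_stage(numeric(n), v, j)
  }
  v
}

#' Multiresolution decomposition of a pupil series
#'
#' Additively decomposes a blink-interpolated pupil series into components
#' at dyadic timescales using a shift-invariant (maximal-overlap) discrete
#' wavelet transform with the Symlet-4 filter pair. Level `j` carries
#' fluctuations at scale `2^j` sample periods; at 1,000 Hz the analysis
#' scales are 4,096 / 8,192 / 16,384 / 32,768 ms plus a coarse
#' approximation (65,536 ms and slower, at absolute diameter level). Each
#' detail is the time-aligned (zero-phase) reconstruction of one level, so
#' the approximation plus all requested details reconstructs the input
#' exactly when `full = TRUE`.
#'
#' Boundaries are handled by mirror-padding the series by one coarsest
#' scale-length on each side before the circular transform and cropping
#' afterwards; event readouts near the edges should be treated as
#' incomplete (see [decomposed_trend()]).
#'
#' @param series A `clean_series` from [interpolate_blinks()], uniformly
#'   sampled.
#' @param scales_ms Dyadic detail scales to reconstruct, each equal to
#'   `2^j * 1000 / sample_rate` ms for integer `j`. Default
#'   `c(4096, 8192, 16384, 32768)` (the analysed scales at 1,000 Hz).
#' @param full If `TRUE`, reconstruct every detail level from the finest
#'   (2 sample periods) up to the coarsest requested scale, so that the
#'   exact additive reconstruction property can be checked.
#' @return An object of class `pupil_mra`: list with `t`, `sample_rate`,
#'   `details` (named list, one zero-centred series per scale in ms),
#'   `approximation` (absolute level at the coarsest scale),
#'   `approx_scale_ms`, and the carried-over `interpolated` mask.
#' @export
mra_decompose <- function(series, scales_ms = c(4096, 8192, 16384, 32768),
                          full = FALSE) {
  stopifnot(inherits(series, "clean_series"))
  period <- 1000 / series$sample_rate
  levels <- log2(scales_ms / period)
  bad <- abs(levels - round(levels)) > 1e-9 | levels < 1
  if (any(bad)) {
    stop("unsupported scale(s) ", paste(scales_ms[bad], collapse = ", "),
         " ms at ", series$sample_rate, " Hz; scales must equal 2^j * ",
         period, " ms (j >= 1)")
  }
  levels <- as.integer(round(levels))
  J <- max(levels)
  n <- length(series$value)
  coarsest <- 2L^J
  if (n < 2L * coarsest)
    stop("series too short for scale ", max(scales_ms), " ms (needs at least ",
         2L * coarsest, " samples, has ", n, ")")

  # mirror-pad by one coarsest scale-length per side, then circular MODWT
  pad <- coarsest
  x <- series$value
  xp <- c(x[pad:1], x, x[n:(n - pad + 1L)])
  pyr <- modwt_pyramid(xp, J)
  core <- (pad + 1L):(pad + n)

  want <- if (full) seq_len(J) else sort(levels)
  details <- vector("list", length(want))
  names(details) <- as.character(2^want * period)
  for (i in seq_along(want)) {
    details[[i]] <- modwt_component(pyr$W[[want[i]]], want[i], TRUE)[core]
  }
  approx <- modwt_component(pyr$V, J, FALSE)[core]

  structure(list(
    t = series$t,
    sample_rate = series$sample_rate,
    details = details,
    approximation = approx,
    approx_scale_ms = 2^(J + 1L) * period,
    interpolated = series$interpolated,
    eye = series$eye,
    participant_id = series$participant_id
  ), class = "pupil_mra")
}

#' @export
print.pupil_mra <- function(x, ...) {
  cat(sprintf(
    "<pupil_mra> %d samples @ %g Hz; details at %s ms; approximation %g ms\n",
    length(x$t), x$sample_rate, paste(names(x$details), collapse = "/"),
    x$approx_scale_ms))
  invisible(x)
}
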