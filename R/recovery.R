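#' Preprocess one eye of a recording
#'
#' Convenience wrapper: blink detection followed by linear interpolation.
#'
#' @param recording A [pupil_recording()].
#' @param eye `"left"` or `"right"`.
#' @param margin_ms,noise_k Passed to [detect_blinks()].
#' @return A `clean_series`.
#' @export
preprocess_eye <- function(recording, eye, margin_ms = 200, noise_k = 5) {
  seg <- detect_blinks(recording, eye, margin_ms, noise_k)
  interpolate_blinks(recording, seg, eye)
}

# Binocular trend table for one session via the vectorized readouts.
session_trend_df <- function(session, windows_s = 10, scales_ms = NULL,
                             max_interp_frac = 0.5, conservative = NULL) {
  rec <- session$recording
  ev <- session$events
  cl <- preprocess_eye(rec, "left")
  cr <- preprocess_eye(rec, "right")
  combine <- function(l, r) {
    lc <- l$quality == "complete"
    rc <- r$quality == "complete"
    value <- ifelse(lc & rc, (l$value_px + r$value_px) / 2,
                    ifelse(lc, l$value_px, ifelse(rc, r$value_px, NA_real_)))
    quality <- ifelse(lc | rc, "complete",
                      ifelse(l$quality == "incomplete" &
                               r$quality == "incomplete",
                             "incomplete", "rejected"))
    data.frame(value_px = value, quality = quality, stringsAsFactors = FALSE)
  }
  out <- list()
  for (w in windows_s) {
    b <- combine(smoothed_trend_vec(cl, ev$t_target_ms, w, max_interp_frac),
                 smoothed_trend_vec(cr, ev$t_target_ms, w, max_interp_frac))
    out[[length(out) + 1L]] <- data.frame(
      trial_id = ev$trial_id, method = "smoothed", scale_ms = w * 1000,
      value_px = b$value_px, quality = b$quality, stringsAsFactors = FALSE)
  }
  if (!is.null(conservative)) {
    b <- combine(conservative_trend_vec(cl, ev$t_target_ms,
                                        conservative$window_s,
                                        conservative$span_s, max_interp_frac),
                 conservative_trend_vec(cr, ev$t_target_ms,
                                        conservative$window_s,
                                        conservative$span_s, max_interp_frac))
    out[[length(out) + 1L]] <- data.frame(
      trial_id = ev$trial_id, method = "conservative",
      scale_ms = conservative$span_s * 1000,
      value_px = b$value_px, quality = b$quality, stringsAsFactors = FALSE)
  }
  if (!is.null(scales_ms)) {
    ml <- mra_decompose(cl, scales_ms)
    mr <- mra_decompose(cr, scales_ms)
    for (sc in scales_ms) {
      b <- combine(decomposed_trend_vec(ml, ev$t_target_ms, sc, max_interp_frac),
                   decomposed_trend_vec(mr, ev$t_target_ms, sc, max_interp_frac))
      out[[length(out) + 1L]] <- data.frame(
        trial_id = ev$trial_id, method = "decomposed", scale_ms = sc,
        value_px = b$value_px, quality = b$quality, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Analyse a simulated cohort end to end
#'
#' Runs the standard pipeline on a simulated cohort: per-eye blink
#' preprocessing, binocular trend computation, trial exclusion, RT split,
#' and the paired one-tailed contrast across participants.
#'
#' @param sessions Output of [simulate_cohort()].
#' @param windows_s Smoothing windows in seconds (default 10).
#' @param scales_ms Decomposed scales in ms, or `NULL` to skip.
#' @param scheme RT split scheme (default `"mean_split"`).
#' @param max_interp_frac Per-trial quality gate.
#' @return A `comparison_result` data.frame (see [run_contrast()]).
#' @export
analyze_cohort <- function(sessions, windows_s = 10, scales_ms = NULL,
                           scheme = "mean_split", max_interp_frac = 0.5) {
  events <- do.call(rbind, lapply(sessions, `[[`, "events"))
  rownames(events) <- NULL
  events <- exclude_trials(events)
  trends <- do.call(rbind, lapply(sessions, session_trend_df,
                                  windows_s = windows_s,
                                  scales_ms = scales_ms,
                                  max_interp_frac = max_interp_frac))
  joined <- attach_trends(events, trends)
  assignment <- suppressMessages(split_by_rt(events, scheme))
  run_contrast(joined, assignment, "short", "long",
               paste0(sessions[[1]]$events$task[1], " short-vs-long"))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts under a configuration and records, per
#' replicate, whether the short-vs-long RT contrast on the 10 s smoothed
#' trend (and optionally a decomposed scale) is significant with the
#' expected sign (short below long, one-tailed). With positive RT coupling
#' (`beta > 0`) the rejection rate measures power; with `beta = 0` it
#' measures the empirical type-I rate, which should sit near the nominal
#' alpha.
#'
#' @param config A [synthetic_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param windows_s Smoothing windows in seconds (default 10).
#' @param scales_ms Decomposed scales in ms, or `NULL` (default) to test
#'   only the smoothed trend.
#' @param scheme RT split scheme (default `"mean_split"`).
#' @param alpha_level One-tailed significance level (default 0.05).
#' @return List of class `recovery_report`: `replicates` (one row per
#'   replicate x method x scale with `t`, `p`, `d`, `reject`),
#'   `rejection_rate` (per method x scale), `config`, `alpha_level`.
#' @export
recovery_experiment <- function(config, n_replicates, windows_s = 10,
                                scales_ms = NULL, scheme = "mean_split",
                                alpha_level = 0.05) {
  stopifnot(n_replicates >= 1)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sessions <- simulate_cohort(cfg)
    res <- analyze_cohort(sessions, windows_s, scales_ms, scheme)
    rows[[r]] <- data.frame(replicate = r, method = res$method,
                            scale_ms = res$scale_ms, t = res$t_stat,
                            p = res$p_one_tailed, d = res$cohens_d,
                            reject = res$p_one_tailed < alpha_level,
                            stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  rate <- stats::aggregate(reject ~ method + scale_ms, data = reps, FUN = mean)
  names(rate)[names(rate) == "reject"] <- "rejection_rate"
  structure(list(replicates = reps, rejection_rate = rate,
                 config = config, alpha_level = alpha_level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  n <- max(x$replicates$replicate)
  cat(sprintf("<recovery_report> %d replicate cohorts of %d participants (%s), alpha = %g\n",
              n, x$config$n_participants, x$config$task, x$alpha_level))
  print(x$rejection_rate, row.names = FALSE)
  invisible(x)
}
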