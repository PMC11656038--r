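#' Synthetic session configuration
#'
#' Generative parameters for synthetic eye-tracking sessions with the
#' statistical structure the trend analysis assumes: a slow latent
#' "suboptimality" state s(t) (mean-reverting, autocorrelation time
#' `1/theta`), a tonic pupil component that integrates the state (so
#' window-differenced trends track the state itself), event-locked phasic
#' constrictions to the bright target, blinks, measurement noise, and
#' reaction times positively coupled to the state.
#'
#' Task-dependent reaction-time parameters (`rt_base`, `beta`, `sigma_rt`,
#' error rates) default to values chosen to emulate the published session
#' designs when left `NULL`.
#'
#' @param seed Integer seed; fully determines the generated cohort.
#' @param n_participants Cohort size (default 17).
#' @param task `"PVT"`, `"2BT"`, or `"ANT"`.
#' @param sample_rate Samples per second (default 1000; recovery
#'   experiments use 50 for tractable replicate counts).
#' @param theta Mean-reversion rate of the latent state in 1/s (default
#'   0.05, i.e. a 20 s autocorrelation time so 10 s windows sit within one
#'   state excursion).
#' @param state_sd Stationary standard deviation of the latent state
#'   (dimensionless units; default 1).
#' @param alpha Tonic drift gain in px/s per unit state: the tonic pupil
#'   component is `baseline + alpha * integral of s`.
#' @param beta RT coupling in ms per unit state (positive: suboptimal
#'   states slow responses).
#' @param rt_base Mean RT in ms at state 0.
#' @param sigma_rt RT noise sd in ms.
#' @param rt_min Physiologic floor on RT in ms (default 180).
#' @param phasic_amp Peak amplitude of the event-locked phasic response in
#'   px (negative: luminance-driven constriction to the white target).
#' @param phasic_shape,phasic_scale_ms Gamma-kernel shape and scale; the
#'   kernel is truncated at 2,000 ms so the conservative trend is immune to
#'   it by construction.
#' @param sigma_m Measurement (sensor) noise sd in px.
#' @param baseline_px Baseline pupil diameter in px (default 3300).
#' @param eye_asym_sd Per-eye constant offset sd in px (binocular
#'   asymmetry).
#' @param blink_rate_per_min Blink rate (default 15/min).
#' @param blink_dur_range_ms Blink duration range in ms (uniform; default
#'   100-400).
#' @param fa_rate Per-trial false-alarm probability (vigilance task).
#' @param miss_rate Per-trial no-response probability.
#' @param err_base Baseline error probability (tasks with correctness).
#' @param err_gain Logistic gain of error probability on the latent state.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_participants = 17, task = "PVT",
                             sample_rate = 1000, theta = 0.05, state_sd = 1,
                             alpha = 2, beta = NULL, rt_base = NULL,
                             sigma_rt = NULL, rt_min = 180,
                             phasic_amp = -40, phasic_shape = 2,
                             phasic_scale_ms = 250, sigma_m = 6,
                             baseline_px = 3300, eye_asym_sd = 20,
                             blink_rate_per_min = 15,
                             blink_dur_range_ms = c(100, 400),
                             fa_rate = NULL, miss_rate = NULL,
                             err_base = NULL, err_gain = 0.5) {
  task <- match.arg(task, c("PVT", "2BT", "ANT"))
  # beta defaults calibrated so the default coupled cohort yields a paired
  # effect of d ~ -0.8 on the 10 s smoothed short-vs-long contrast; the
  # 2BT/ANT couplings scale with their larger RT noise
  defaults <- switch(task,
    PVT = list(rt_base = 350, beta = 8, sigma_rt = 70,
               fa_rate = 0.004, miss_rate = 0, err_base = 0),
    "2BT" = list(rt_base = 1050, beta = 35, sigma_rt = 300,
                 fa_rate = 0, miss_rate = 0.0045, err_base = 0.09),
    ANT = list(rt_base = 680, beta = 13, sigma_rt = 110,
               fa_rate = 0, miss_rate = 0.014, err_base = 0.035))
  cfg <- list(
    seed = as.integer(seed), n_participants = n_participants, task = task,
    sample_rate = sample_rate, theta = theta, state_sd = state_sd,
    alpha = alpha,
    beta = if (is.null(beta)) defaults$beta else beta,
    rt_base = if (is.null(rt_base)) defaults$rt_base else rt_base,
    sigma_rt = if (is.null(sigma_rt)) defaults$sigma_rt else sigma_rt,
    rt_min = rt_min, phasic_amp = phasic_amp, phasic_shape = phasic_shape,
    phasic_scale_ms = phasic_scale_ms, sigma_m = sigma_m,
    baseline_px = baseline_px, eye_asym_sd = eye_asym_sd,
    blink_rate_per_min = blink_rate_per_min,
    blink_dur_range_ms = blink_dur_range_ms,
    fa_rate = if (is.null(fa_rate)) defaults$fa_rate else fa_rate,
    miss_rate = if (is.null(miss_rate)) defaults$miss_rate else miss_rate,
    err_base = if (is.null(err_base)) defaults$err_base else err_base,
    err_gain = err_gain)
  stopifnot(cfg$theta > 0, cfg$state_sd >= 0, cfg$sample_rate > 0,
            cfg$n_participants >= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Per-trial task schedule
#'
#' Trial structure matching the published session designs. PVT: 29 latency
#' periods from 1,000 to 8,000 ms in 250 ms steps, 4 trials each (116
#' trials), shuffled. 2BT: 158 trials every 3,500 ms (500 ms target frame +
#' 3,000 ms blank). ANT: 96 trials; cue types none/double/center/spatial at
#' 25% each; targets congruent/neutral/incongruent in equal proportion;
#' initial fixation uniform 400-1,600 ms.
#'
#' @param task `"PVT"`, `"2BT"`, or `"ANT"`.
#' @return data.frame with `trial_index` and the task-specific design
#'   columns (`latency_ms`; or `cue`, `target_type`, `fix_ms`). Uses the
#'   current RNG stream.
#' @export
task_schedule <- function(task = c("PVT", "2BT", "ANT")) {
  task <- match.arg(task)
  if (task == "PVT") {
    lat <- sample(rep(seq(1000, 8000, by = 250), each = 4))
    data.frame(trial_index = seq_along(lat), latency_ms = lat)
  } else if (task == "2BT") {
    n <- 158L
    data.frame(trial_index = seq_len(n), latency_ms = NA_real_)
  } else {
    n <- 96L
    cue <- sample(rep(c("none", "double", "center", "spatial"), each = n / 4))
    target <- sample(rep(c("congruent", "neutral", "incongruent"),
                         length.out = n))
    data.frame(trial_index = seq_len(n), cue = cue, target_type = target,
               fix_ms = stats::runif(n, 400, 1600))
  }
}

#' Generate the latent suboptimality state
#'
#' Exact discretisation of a mean-reverting (Ornstein-Uhlenbeck)
#' process with mean 0, stationary sd `state_sd`, and autocorrelation time
#' `1/theta`, sampled at the pupil rate. Uses the current RNG stream.
#'
#' @param config A [synthetic_config()].
#' @param duration_s Duration in seconds (> 0).
#' @return Numeric vector of `duration_s * sample_rate` state samples.
#' @export
gen_latent_state <- function(config, duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- as.integer(round(duration_s * config$sample_rate))
  dt <- 1 / config$sample_rate
  if (config$state_sd == 0) return(numeric(n))
  a <- exp(-config$theta * dt)
  innov_sd <- config$state_sd * sqrt(1 - a^2)
  e <- stats::rnorm(n, sd = innov_sd)
  e[1] <- stats::rnorm(1, sd = config$state_sd)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

# truncated gamma kernel, peak-normalised, support [0, 2000) ms
phasic_kernel <- function(config) {
  dt_ms <- 1000 / config$sample_rate
  u <- seq(0, 2000 - dt_ms, by = dt_ms)
  k <- stats::dgamma(u, shape = config$phasic_shape,
                     scale = config$phasic_scale_ms)
  if (max(k) > 0) k <- k / max(k)
  config$phasic_amp * k
}

#' Generate reaction times and correctness for a schedule
#'
#' `rt_i = rt_base + beta * s(t_i) + noise`, floored at `rt_min`. For
#' tasks with correctness, the error probability increases logistically in
#' the state. The ANT adds condition main effects (no-cue +30 ms vs
#' center; incongruent +31, congruent -31 ms) reproducing the published RT
#' orderings. Uses the current RNG stream.
#'
#' @param schedule Schedule from [task_schedule()] with a `t_target_ms`
#'   column (assembled onsets).
#' @param s Latent state vector at the pupil sample rate.
#' @param config A [synthetic_config()].
#' @return `schedule` with `rt_ms`, `correct`, `false_alarm` columns added.
#' @export
gen_rts <- function(schedule, s, config) {
  n <- nrow(schedule)
  idx <- pmin(pmax(as.integer(round(
    schedule$t_target_ms * config$sample_rate / 1000)) + 1L, 1L), length(s))
  sv <- s[idx]
  rt <- config$rt_base + config$beta * sv +
    stats::rnorm(n, sd = config$sigma_rt)
  if (config$task == "ANT") {
    rt <- rt + ifelse(schedule$cue == "none", 30, 0) +
      ifelse(schedule$target_type == "incongruent", 31,
             ifelse(schedule$target_type == "congruent", -31, 0))
  }
  rt <- pmax(rt, config$rt_min)
  correct <- rep(NA, n)
  if (config$err_base > 0) {
    p_err <- stats::plogis(stats::qlogis(config$err_base) +
                             config$err_gain * sv)
    correct <- stats::runif(n) >= p_err
  }
  fa <- stats::runif(n) < config$fa_rate
  miss <- !fa & stats::runif(n) < config$miss_rate
  rt[miss] <- NA_real_
  rt[fa] <- 0
  schedule$rt_ms <- rt
  schedule$correct <- correct
  schedule$false_alarm <- fa
  schedule
}

#' Generate one eye-tracking recording for a scheduled session
#'
#' Per eye: `baseline + alpha * integral(s)` (tonic drift) + event-locked
#' phasic kernels at target onsets + white measurement noise + a constant
#' per-eye offset. Blinks (shared across eyes) are injected as zeroed runs
#' with validity flags cleared. Uses the current RNG stream.
#'
#' @param schedule Schedule with assembled `t_target_ms` onsets.
#' @param s Latent state vector covering the recording.
#' @param config A [synthetic_config()].
#' @param participant_id Participant label.
#' @return A [pupil_recording()].
#' @export
gen_pupil_trace <- function(schedule, s, config, participant_id = "S01") {
  rate <- config$sample_rate
  n <- length(s)
  dt <- 1 / rate
  tonic <- config$baseline_px + config$alpha * cumsum(s) * dt
  phasic <- numeric(n)
  kern <- phasic_kernel(config)
  for (t0 in schedule$t_target_ms) {
    i <- as.integer(round(t0 * rate / 1000)) + 1L
    j <- min(i + length(kern) - 1L, n)
    if (i <= n) phasic[i:j] <- phasic[i:j] + kern[seq_len(j - i + 1L)]
  }
  base <- tonic + phasic
  off <- stats::rnorm(2, sd = config$eye_asym_sd)
  left <- base + off[1] + stats::rnorm(n, sd = config$sigma_m)
  right <- base + off[2] + stats::rnorm(n, sd = config$sigma_m)

  valid <- rep(TRUE, n)
  dur_s <- n / rate
  n_blinks <- stats::rpois(1, config$blink_rate_per_min * dur_s / 60)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, dur_s * 1000)
    durs <- stats::runif(n_blinks, config$blink_dur_range_ms[1],
                         config$blink_dur_range_ms[2])
    for (b in seq_len(n_blinks)) {
      i <- min(n, max(1L, as.integer(round(starts[b] * rate / 1000)) + 1L))
      j <- min(n, i + as.integer(round(durs[b] * rate / 1000)))
      valid[i:j] <- FALSE
    }
  }
  if (mean(!valid) > 0.9) stop("blink coverage exceeds 90%; rejecting config")
  left[!valid] <- 0
  right[!valid] <- 0
  pupil_recording(t = (seq_len(n) - 1L) * 1000 / rate,
                  left = left, right = right,
                  valid_left = valid, valid_right = valid,
                  participant_id = participant_id, sample_rate = rate)
}

# Assemble trial onsets on the recording clock. PVT: latency period, then
# target, response, 1,000 ms feedback. 2BT: fixed 3,500 ms pitch. ANT:
# initial fixation + 100 ms cue + 400 ms fixation, post-target period pads
# the trial to 4,100 ms + RT.
assemble_onsets <- function(schedule, config, rt_guess) {
  task <- config$task
  n <- nrow(schedule)
  if (task == "PVT") {
    onsets <- numeric(n)
    clock <- 1000
    for (i in seq_len(n)) {
      onsets[i] <- clock + schedule$latency_ms[i]
      clock <- onsets[i] + rt_guess[i] + 1000
    }
  } else if (task == "2BT") {
    onsets <- 1000 + (seq_len(n) - 1L) * 3500
  } else {
    onsets <- numeric(n)
    clock <- 1000
    for (i in seq_len(n)) {
      onsets[i] <- clock + schedule$fix_ms[i] + 500
      clock <- clock + 4100 + rt_guess[i]
    }
  }
  schedule$t_target_ms <- onsets
  schedule
}

#' Simulate one complete session
#'
#' Generates a schedule, latent state, reaction times and a binocular
#' recording for one participant, in a single deterministic RNG stream.
#' The session is padded by 20 s before the first and after the last
#' target so that every trial has complete trend windows at the analysed
#' scales (minus blink losses).
#'
#' @param config A [synthetic_config()].
#' @param participant_id Participant label.
#' @return List with `recording` (a [pupil_recording()]) and `events`
#'   (data.frame in the standard event-table layout).
#' @export
simulate_session <- function(config, participant_id = "S01") {
  sched <- task_schedule(config$task)
  n_tr <- nrow(sched)
  # provisional RTs only fix the session length; real RTs follow the state
  rt_guess <- rep(config$rt_base, n_tr)
  sched <- assemble_onsets(sched, config, rt_guess)
  pad_ms <- 20000
  sched$t_target_ms <- sched$t_target_ms + pad_ms
  dur_s <- (max(sched$t_target_ms) + config$rt_base + pad_ms + 1000) / 1000
  s <- gen_latent_state(config, dur_s)
  sched <- gen_rts(sched, s, config)
  rec <- gen_pupil_trace(sched, s, config, participant_id)
  ev <- data.frame(participant = participant_id, task = config$task,
                   trial_index = sched$trial_index,
                   t_target_ms = sched$t_target_ms,
                   rt_ms = sched$rt_ms,
                   correct = sched$correct,
                   false_alarm = sched$false_alarm,
                   cue = if ("cue" %in% names(sched)) sched$cue else NA,
                   target_type = if ("target_type" %in% names(sched))
                     sched$target_type else NA,
                   stringsAsFactors = FALSE)
  ev$trial_id <- paste(participant_id, ev$trial_index, sep = ":")
  list(recording = rec, events = ev, latent = s)
}

#' Simulate a cohort of sessions
#'
#' Seeds the RNG from `config$seed` and generates `n_participants`
#' sessions in one stream, so the whole cohort is reproducible from the
#' config alone.
#'
#' @param config A [synthetic_config()].
#' @return List of session lists (see [simulate_session()]), named by
#'   participant id (`S01`, `S02`, ...).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  ids <- sprintf("S%02d", seq_len(config$n_participants))
  stats::setNames(lapply(ids, function(id) simulate_session(config, id)), ids)
}
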