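# In-code fixtures: small uniform recordings and clean series.

make_recording <- function(n = 5000, rate = 1000, value = 100,
                           left = NULL, right = NULL, valid = rep(TRUE, n)) {
  t <- (seq_len(n) - 1) * 1000 / rate
  if (is.null(left)) left <- rep(value, n)
  if (is.null(right)) right <- left
  pupil_recording(t, left, right, valid, valid,
                  participant_id = "T01", sample_rate = rate)
}

make_clean <- function(value, rate = 1000, interpolated = NULL) {
  n <- length(value)
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  structure(list(t = (seq_len(n) - 1) * 1000 / rate, value = value,
                 interpolated = interpolated, sample_rate = rate,
                 eye = "left", participant_id = "T01"),
            class = "clean_series")
}

# random smooth-ish trace: AR(1) plus noise, fixed length
random_trace <- function(n, rho = 0.99, sd = 1) {
  as.numeric(stats::filter(rnorm(n, sd = sd), rho, method = "recursive"))
}

# event table builder for split/exclusion tests
make_events <- function(participant = "P1", rt, task = "PVT",
                        correct = NULL, cue = NULL, target_type = NULL,
                        t_target = NULL) {
  n <- length(rt)
  ev <- data.frame(participant = participant, task = task,
                   trial_index = seq_len(n),
                   t_target_ms = if (is.null(t_target))
                     seq_len(n) * 5000 else t_target,
                   rt_ms = rt, stringsAsFactors = FALSE)
  if (!is.null(correct)) ev$correct <- correct
  if (!is.null(cue)) ev$cue <- cue
  if (!is.null(target_type)) ev$target_type <- target_type
  ev$trial_id <- paste(ev$participant, ev$trial_index, sep = ":")
  ev
}
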