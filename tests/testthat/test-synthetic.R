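# Generator checks run at reduced sample rates; the statistical structure
# (latent state, coupling, kernels) is rate-invariant.

test_that("the same config yields a byte-identical cohort", {
  cfg <- synthetic_config(seed = 7, n_participants = 2, task = "PVT",
                          sample_rate = 50)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(synthetic_config(seed = 8, n_participants = 2,
                                         task = "PVT", sample_rate = 50))
  expect_false(identical(s1[[1]]$recording$left, s3[[1]]$recording$left))
})

test_that("latent state is zero without volatility and mean-reverting with it", {
  cfg <- synthetic_config(seed = 1, sample_rate = 100, state_sd = 0)
  set.seed(1)
  expect_identical(gen_latent_state(cfg, 10), numeric(1000))
  # autocorrelation at lag 1/theta is ~exp(-1)
  cfg2 <- synthetic_config(seed = 1, sample_rate = 100, theta = 0.05)
  set.seed(2)
  s <- gen_latent_state(cfg2, 20000)  # long run for a stable estimate
  lag <- as.integer(round(100 / 0.05))  # 1/theta seconds in samples
  ac <- stats::cor(s[-(1:lag)], s[1:(length(s) - lag)])
  expect_lt(abs(ac - exp(-1)), 0.1)
  expect_lt(abs(stats::sd(s) - cfg2$state_sd), 0.15)
  expect_error(gen_latent_state(cfg2, -1), "positive")
})

test_that("reaction times couple positively to the latent state", {
  cfg <- synthetic_config(seed = 3, task = "PVT", sample_rate = 50)
  set.seed(3)
  sched <- task_schedule("PVT")
  sched$t_target_ms <- seq(5000, by = 6000, length.out = nrow(sched))
  s <- gen_latent_state(cfg, (max(sched$t_target_ms) + 5000) / 1000)
  ev <- gen_rts(sched, s, cfg)
  idx <- round(ev$t_target_ms * cfg$sample_rate / 1000) + 1
  ok <- !is.na(ev$rt_ms) & ev$rt_ms > 0
  expect_gt(stats::cor(s[idx[ok]], ev$rt_ms[ok]), 0.05)
  # beta = 0, sigma_rt = 0 -> constant RT at rt_base
  cfg0 <- synthetic_config(seed = 3, task = "PVT", sample_rate = 50,
                           beta = 0, sigma_rt = 0, fa_rate = 0)
  ev0 <- gen_rts(sched, s, cfg0)
  expect_true(all(ev0$rt_ms == cfg0$rt_base))
  # floor applies when parameters drive RT below the minimum
  cfgf <- synthetic_config(seed = 3, task = "PVT", sample_rate = 50,
                           rt_base = 0, beta = 0, sigma_rt = 1, fa_rate = 0)
  evf <- gen_rts(sched, s, cfgf)
  expect_true(all(evf$rt_ms >= cfgf$rt_min))
})

test_that("vigilance schedules use every latency step exactly four times", {
  set.seed(4)
  sched <- task_schedule("PVT")
  expect_equal(nrow(sched), 116)
  expect_equal(sort(unique(sched$latency_ms)), seq(1000, 8000, by = 250))
  expect_true(all(table(sched$latency_ms) == 4))
  sched2 <- task_schedule("2BT")
  expect_equal(nrow(sched2), 158)
  ant <- task_schedule("ANT")
  expect_equal(nrow(ant), 96)
  expect_true(all(table(ant$cue) == 24))
})

test_that("a noiseless uncoupled config produces a constant baseline trace", {
  cfg <- synthetic_config(seed = 5, task = "PVT", sample_rate = 50,
                          alpha = 0, phasic_amp = 0, sigma_m = 0,
                          blink_rate_per_min = 0, eye_asym_sd = 0)
  set.seed(5)
  sched <- task_schedule("PVT")
  sched$t_target_ms <- seq(5000, by = 6000, length.out = nrow(sched))
  s <- gen_latent_state(cfg, 700)
  rec <- gen_pupil_trace(sched, s, cfg)
  expect_true(all(rec$left == cfg$baseline_px))
  expect_true(all(rec$valid_left))
})

test_that("the phasic kernel leaves the conservative trend untouched", {
  # phasic-only trace: kernel support < 2 s, windows start at +/-2 s
  cfg <- synthetic_config(seed = 6, task = "PVT", sample_rate = 125,
                          alpha = 0, sigma_m = 0, blink_rate_per_min = 0,
                          eye_asym_sd = 0, phasic_amp = -40)
  set.seed(6)
  sched <- data.frame(trial_index = 1:10,
                      t_target_ms = seq(20000, by = 15000, length.out = 10))
  s <- numeric(200 * cfg$sample_rate)
  rec <- gen_pupil_trace(sched, s, cfg)
  cl <- preprocess_eye(rec, "left")
  for (t0 in sched$t_target_ms) {
    expect_identical(conservative_trend(cl, t0)$value_px, 0)
    # the smoothed trend does respond to the phasic transient
    expect_false(smoothed_trend(cl, t0, 10)$value_px == 0)
  }
})

test_that("a frozen positive state produces the analytic smoothed trend", {
  # s(t) = +1 over the whole window -> tonic ramp alpha px/s -> 10 s trend
  # equals alpha * 10 px
  cfg <- synthetic_config(seed = 7, task = "PVT", sample_rate = 125,
                          alpha = 2, phasic_amp = 0, sigma_m = 0,
                          blink_rate_per_min = 0, eye_asym_sd = 0)
  set.seed(7)
  sched <- data.frame(trial_index = 1, t_target_ms = 30000)
  s <- rep(1, 60 * cfg$sample_rate)
  rec <- gen_pupil_trace(sched, s, cfg)
  cl <- preprocess_eye(rec, "left")
  expect_equal(smoothed_trend(cl, 30000, 10)$value_px, cfg$alpha * 10,
               tolerance = 1e-6)
})

test_that("simulated sessions pass through the event-table contract", {
  cfg <- synthetic_config(seed = 8, n_participants = 1, task = "ANT",
                          sample_rate = 50)
  sess <- simulate_cohort(cfg)[[1]]
  ev <- sess$events
  expect_true(all(diff(ev$t_target_ms) > 0))
  expect_true(all(ev$t_target_ms < max(sess$recording$t)))
  expect_setequal(unique(ev$cue), c("none", "double", "center", "spatial"))
  expect_true(all(ev$rt_ms > 0 | is.na(ev$rt_ms) | ev$false_alarm))
  # excessive blink coverage is rejected outright
  cfg_bad <- synthetic_config(seed = 8, n_participants = 1, task = "PVT",
                              sample_rate = 50, blink_rate_per_min = 2000,
                              blink_dur_range_ms = c(4000, 8000))
  expect_error(simulate_cohort(cfg_bad), "90%")
})

test_that("coupled cohorts show the expected trend direction and timescale order", {
  # short-RT trials should carry the lower slow trend, and the slow-drift
  # generator should make the 16,384 ms effect exceed the 4,096 ms one
  cfg <- synthetic_config(seed = 9, n_participants = 8, task = "PVT",
                          sample_rate = 125)
  diffs <- replicate(4, NA_real_)
  d4 <- d16 <- numeric(4)
  for (r in 1:4) {
    cfg$seed <- 9 + r
    res <- suppressMessages(analyze_cohort(
      simulate_cohort(cfg), windows_s = 10,
      scales_ms = c(4096, 16384)))
    diffs[r] <- res$mean_diff_px[res$method == "smoothed"]
    d4[r] <- res$cohens_d[res$method == "decomposed" & res$scale_ms == 4096]
    d16[r] <- res$cohens_d[res$method == "decomposed" & res$scale_ms == 16384]
  }
  expect_true(mean(diffs) < 0)
  expect_lt(mean(abs(d4)), mean(abs(d16)))
})
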