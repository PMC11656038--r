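test_that("first-trial removal uses round-half-up of the session fraction", {
  # vigilance design: 116 trials -> 6 startup exclusions
  ev <- make_events(rt = rep(400, 116))
  ex <- exclude_trials(ev)
  expect_equal(sum(ex$reason == "startup", na.rm = TRUE), 6)
  # working-memory design: 158 trials -> 8
  ev2 <- make_events(rt = rep(900, 158), task = "2BT",
                     correct = rep(TRUE, 158))
  ex2 <- exclude_trials(ev2)
  expect_equal(sum(ex2$reason == "startup", na.rm = TRUE), 8)
  # 96 trials -> round_half_up(4.8) = 5
  ev3 <- make_events(rt = rep(700, 96), task = "ANT")
  expect_equal(sum(exclude_trials(ev3)$reason == "startup", na.rm = TRUE), 5)
})

test_that("exclusion rules flag misses, anticipations, and errors but delete nothing", {
  rt <- c(NA, 100, 150, 151, 400, 500)
  ev <- make_events(rt = rt, correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  ex <- exclude_trials(ev, first_fraction = 0)
  expect_equal(nrow(ex), length(rt))
  expect_identical(ex$reason,
                   c("miss", "anticipation", "anticipation", "incorrect",
                     NA, NA))
  # boundary: RT = 150 ms exactly is excluded ("150 ms or less")
  expect_true(ex$excluded[3])
  expect_false(ex$excluded[5])
  # identity case: nothing to exclude
  ev0 <- make_events(rt = rep(400, 20), correct = rep(TRUE, 20))
  expect_equal(sum(exclude_trials(ev0, first_fraction = 0)$excluded), 0)
  expect_error(exclude_trials(ev0[0, ]), "no trials")
})

test_that("exclusion is monotone in added rules", {
  set.seed(41)
  ev <- make_events(rt = sample(c(NA, 100, 300, 500), 60, replace = TRUE))
  n0 <- sum(!exclude_trials(ev, first_fraction = 0)$excluded)
  n1 <- sum(!exclude_trials(ev, first_fraction = 0.05)$excluded)
  n2 <- sum(!exclude_trials(ev, first_fraction = 0.10)$excluded)
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("attach_trends drops trials per method/scale only", {
  ev <- make_events(rt = rep(400, 4))
  trends <- rbind(
    data.frame(trial_id = ev$trial_id, method = "smoothed", scale_ms = 10000,
               value_px = 1:4, quality = "complete"),
    data.frame(trial_id = ev$trial_id, method = "smoothed", scale_ms = 15000,
               value_px = 1:4,
               quality = c("incomplete", "complete", "complete", "complete")))
  j <- attach_trends(ev, trends)
  expect_equal(sum(j$scale_ms == 10000), 4)
  expect_equal(sum(j$scale_ms == 15000), 3)
  expect_false(ev$trial_id[1] %in% j$trial_id[j$scale_ms == 15000])
  # duplicates rejected
  expect_error(attach_trends(rbind(ev, ev), trends), "duplicate")
  expect_warning(attach_trends(ev, trends[0, ]), "empty trend table")
})

test_that("mean split sends strictly-below-mean RTs to short, ties to long", {
  ev <- exclude_trials(make_events(rt = c(300, 400, 500, 600)),
                       first_fraction = 0)
  g <- split_by_rt(ev, "mean_split")
  expect_setequal(g$trial_id[g$group == "short"], c("P1:1", "P1:2"))
  expect_setequal(g$trial_id[g$group == "long"], c("P1:3", "P1:4"))
  # every valid trial assigned exactly once
  expect_setequal(g$trial_id, ev$trial_id)
  expect_false(any(duplicated(g$trial_id)))
  # identical RTs: all fall at the mean -> long
  ev2 <- exclude_trials(make_events(rt = rep(400, 6)), first_fraction = 0)
  g2 <- split_by_rt(ev2, "mean_split")
  expect_true(all(g2$group == "long"))
})

test_that("quartile split uses type-7 percentiles and leaves the middle out", {
  ev <- exclude_trials(make_events(rt = 200 + as.numeric(1:100)),
                       first_fraction = 0)
  g <- split_by_rt(ev, "quartile_split")
  short <- as.integer(sub("P1:", "", g$trial_id[g$group == "short"]))
  long <- as.integer(sub("P1:", "", g$trial_id[g$group == "long"]))
  # Q25 = 225.75, Q75 = 275.25 under type 7: short = trials 1..25,
  # long = trials 76..100
  expect_setequal(short, 1:25)
  expect_setequal(long, 76:100)
  expect_lte(nrow(g), 50)
  # all-identical RTs assign nothing
  ev2 <- exclude_trials(make_events(rt = rep(5e2, 8)), first_fraction = 0)
  expect_error(suppressMessages(split_by_rt(ev2, "quartile_split")),
               "no participant")
  # quartile symmetry: distinct RTs, n divisible by 4 -> n/4 per group
  set.seed(42)
  ev3 <- exclude_trials(make_events(rt = 200 + sample(1000, 40)),
                        first_fraction = 0)
  g3 <- split_by_rt(ev3, "quartile_split")
  expect_equal(sum(g3$group == "short"), 10)
  expect_equal(sum(g3$group == "long"), 10)
})

test_that("insufficient trials omit the participant, not the cohort", {
  ev <- rbind(make_events(rt = c(300, 500, 400, 600)),
              make_events(participant = "P2", rt = c(300, NA, NA, NA)))
  ev <- exclude_trials(ev, first_fraction = 0)
  expect_message(g <- split_by_rt(ev, "mean_split"), "P2")
  expect_setequal(unique(g$participant), "P1")
})

test_that("accuracy split re-admits incorrect trials and needs both outcomes", {
  ev <- make_events(rt = rep(900, 12), task = "2BT",
                    correct = c(rep(TRUE, 10), FALSE, FALSE))
  ev <- exclude_trials(ev, first_fraction = 0)
  expect_true(all(ev$excluded[11:12]))  # excluded as incorrect...
  g <- split_by_accuracy(ev)
  expect_equal(sum(g$group == "correct"), 10)
  expect_equal(sum(g$group == "incorrect"), 2)  # ...but re-admitted here
  # all-correct participant is omitted
  ev2 <- exclude_trials(make_events(rt = rep(900, 6), task = "2BT",
                                    correct = rep(TRUE, 6)),
                        first_fraction = 0)
  expect_error(suppressMessages(split_by_accuracy(ev2)), "no participant")
  expect_error(split_by_accuracy(make_events(rt = rep(1, 4))), "requires")
})

test_that("condition contrasts assign only the compared cue/target levels", {
  cue <- rep(c("none", "double", "center", "spatial"), each = 24)
  target <- rep(c("congruent", "neutral", "incongruent"), length.out = 96)
  ev <- make_events(rt = rep(700, 96), task = "ANT", cue = cue,
                    target_type = target)
  ev <- exclude_trials(ev, first_fraction = 0)
  al <- split_by_condition(ev, "alerting")
  expect_setequal(unique(al$group), c("center_cue", "no_cue"))
  expect_equal(sum(al$group == "center_cue"), 24)
  expect_equal(sum(al$group == "no_cue"), 24)
  expect_false(any(ev$trial_id[ev$cue == "double"] %in% al$trial_id))
  ex <- split_by_condition(ev, "executive")
  expect_setequal(unique(ex$group), c("congruent", "incongruent"))
  expect_false(any(ev$trial_id[ev$target_type == "neutral"] %in% ex$trial_id))
  expect_error(split_by_condition(make_events(rt = 1:4), "alerting"),
               "requires")
})

test_that("groups are disjoint within every scheme", {
  set.seed(43)
  ev <- exclude_trials(make_events(rt = rexp(80, 1 / 400) + 200))
  for (scheme in c("mean_split", "quartile_split")) {
    g <- split_by_rt(ev, scheme)
    expect_false(any(duplicated(g$trial_id)))
  }
})

test_that("event files round-trip with miss encoding", {
  ev <- make_events(rt = c(400, NA, 500), correct = c(TRUE, NA, FALSE))
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  ev2 <- read_events(path)
  expect_equal(ev2$rt_ms, ev$rt_ms)
  expect_equal(ev2$trial_id, ev$trial_id)
})
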