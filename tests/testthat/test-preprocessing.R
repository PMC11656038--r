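test_that("a fully valid constant trace yields no blink segments", {
  rec <- make_recording(n = 3000, value = 100)
  expect_identical(nrow(detect_blinks(rec, "left")), 0L)
  expect_identical(nrow(detect_blinks(rec, "right")), 0L)
})

test_that("blink margins extend 200 ms on both sides and merge across gaps", {
  # zeros on t in [1000, 1200] ms -> one segment [800, 1400]
  n <- 5000
  left <- rep(100, n)
  t <- 0:(n - 1)
  left[t >= 1000 & t <= 1200] <- 0
  rec <- make_recording(n = n, left = left)
  seg <- detect_blinks(rec, "left")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$t_start, 800)
  expect_equal(seg$t_end, 1400)

  # two zero-runs [1000,1200] and [1500,1600] merge into [800,1800]
  left2 <- rep(100, n)
  left2[(t >= 1000 & t <= 1200) | (t >= 1500 & t <= 1600)] <- 0
  rec2 <- make_recording(n = n, left = left2)
  seg2 <- detect_blinks(rec2, "left")
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$t_start, 800)
  expect_equal(seg2$t_end, 1800)
})

test_that("margin-and-merge agrees with a brute-force oracle on random blink sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 4000
    left <- 100 + random_trace(n, rho = 0.9, sd = 0.05)
    n_blinks <- sample(1:5, 1)
    core <- rep(FALSE, n)
    for (b in seq_len(n_blinks)) {
      a <- sample(1:(n - 100), 1)
      core[a:(a + sample(20:150, 1))] <- TRUE
    }
    core <- core[1:n]
    left[core] <- 0
    rec <- make_recording(n = n, left = left)
    # oracle: dilate the core mask by 200 samples (200 ms at 1 kHz), take runs;
    # flank extension cannot trigger because the valid trace is smooth
    dil <- rep(FALSE, n)
    for (i in which(core)) dil[max(1, i - 200):min(n, i + 200)] <- TRUE
    r <- rle(dil)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    exp_start <- (starts[r$values] - 1)
    exp_end <- (ends[r$values] - 1)
    seg <- detect_blinks(rec, "left")
    expect_equal(seg$t_start, exp_start)
    expect_equal(seg$t_end, exp_end)
  }
})

test_that("noisy flanks adjacent to a blink core are captured", {
  n <- 4000
  left <- 100 + random_trace(n, rho = 0.9, sd = 0.05)
  left[2000:2100] <- 0
  # steep artefactual flank right before the core
  left[1995:1999] <- c(95, 80, 60, 30, 10)
  rec <- make_recording(n = n, left = left)
  seg <- detect_blinks(rec, "left")
  expect_equal(nrow(seg), 1L)
  expect_lte(seg$t_start, 1994 - 200)
})

test_that("enlarging the margin never shrinks a segment", {
  n <- 6000
  left <- rep(100, n)
  left[c(1000:1100, 3000:3050)] <- 0
  rec <- make_recording(n = n, left = left)
  s1 <- detect_blinks(rec, "left", margin_ms = 100)
  s2 <- detect_blinks(rec, "left", margin_ms = 300)
  # every s1 segment is contained in some s2 segment
  for (i in seq_len(nrow(s1))) {
    covered <- any(s2$t_start <= s1$t_start[i] & s2$t_end >= s1$t_end[i])
    expect_true(covered)
  }
})

test_that("interpolation is linear between anchors and constant at edges", {
  # anchors 10 px at t=0 and 20 px at t=3 ms, gap at t=1,2
  rec <- pupil_recording(0:3, c(10, 0, 0, 20), c(10, 0, 0, 20),
                         sample_rate = 1000)
  seg <- data.frame(t_start = 1, t_end = 2, eye = "left")
  cl <- interpolate_blinks(rec, seg, "left")
  expect_equal(cl$value, c(10, 40 / 3, 50 / 3, 20))
  expect_identical(cl$interpolated, c(FALSE, TRUE, TRUE, FALSE))

  # constant anchors -> constant fill
  rec2 <- pupil_recording(0:4, c(10, 0, 0, 0, 10), c(10, 0, 0, 0, 10))
  cl2 <- interpolate_blinks(rec2, data.frame(t_start = 1, t_end = 3,
                                             eye = "left"), "left")
  expect_equal(cl2$value, rep(10, 5))

  # leading gap before first valid value 12 px -> constant extension
  rec3 <- pupil_recording(0:4, c(0, 0, 12, 13, 14), c(0, 0, 12, 13, 14))
  cl3 <- interpolate_blinks(rec3, data.frame(t_start = 0, t_end = 1,
                                             eye = "left"), "left")
  expect_equal(cl3$value, c(12, 12, 12, 13, 14))
})

test_that("interpolation conserves samples outside segments bitwise", {
  set.seed(12)
  n <- 3000
  left <- 100 + random_trace(n)
  left[1200:1300] <- 0
  rec <- make_recording(n = n, left = left)
  seg <- detect_blinks(rec, "left")
  cl <- interpolate_blinks(rec, seg, "left")
  outside <- !cl$interpolated
  expect_identical(cl$value[outside], left[outside])
  # second difference of filled values is 0 within each gap (linearity)
  gap <- which(cl$interpolated)
  runs <- split(gap, cumsum(c(1, diff(gap) != 1)))
  for (r in runs) {
    if (length(r) >= 3) {
      d2 <- diff(diff(cl$value[r]))
      expect_lt(max(abs(d2)), 1e-9)
    }
  }
})

test_that("a clean reconstituted recording has no residual blink evidence", {
  set.seed(13)
  n <- 3000
  left <- 100 + random_trace(n, rho = 0.9, sd = 0.05)
  left[1500:1600] <- 0
  rec <- make_recording(n = n, left = left)
  cl <- preprocess_eye(rec, "left")
  rec2 <- make_recording(n = n, left = cl$value)
  expect_identical(nrow(detect_blinks(rec2, "left")), 0L)
})

test_that("an eye with no valid samples is reported unusable", {
  rec <- make_recording(n = 2500, left = rep(0, 2500))
  seg <- detect_blinks(rec, "left")
  expect_error(interpolate_blinks(rec, seg, "left"), "eye unusable")
})

test_that("interpolated_fraction counts window share and flags truncation", {
  n <- 20000  # 20 s at 1 kHz
  left <- rep(100, n)
  left[10000:10999] <- 0  # 1 s blink (margins add 200 ms each side)
  rec <- make_recording(n = n, left = left)
  cl <- preprocess_eye(rec, "left")
  # window away from the blink
  expect_equal(interpolated_fraction(cl, 3000, 1000)$fraction, 0)
  # window fully inside the blink
  expect_equal(interpolated_fraction(cl, 10500, 200)$fraction, 1)
  # 10 s window holding the 1.4 s interpolated run (1 s + 2 x 200 ms margin)
  f <- interpolated_fraction(cl, 10500, 5000)
  expect_equal(f$fraction, 1400 / 10001, tolerance = 1e-6)
  expect_false(f$incomplete)
  expect_true(interpolated_fraction(cl, 500, 1000)$incomplete)
  expect_error(interpolated_fraction(cl, -5000, 1000), "no data")
})

test_that("samples files round-trip through write and read", {
  set.seed(14)
  rec <- make_recording(n = 500, left = 100 + rnorm(500))
  path <- tempfile(fileext = ".csv")
  write_samples(rec, path)
  rec2 <- read_samples(path, participant_id = "T01")
  expect_equal(rec2$left, rec$left, tolerance = 1e-12)
  expect_identical(rec2$valid_left, rec$valid_left)
  expect_equal(rec2$sample_rate, 1000)
})
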