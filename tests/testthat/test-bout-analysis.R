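test_that("preprocessing yields a z-scored 5 ms grid and linear interpolation", {
  # 4 ms input grid resampled to 5 ms
  set.seed(1)
  n <- 500
  raw <- tail_recording(dt = 0.004, tail_angle = cumsum(rnorm(n, 0, 0.1)),
                        grating_cmd = 10, trial_id = 1L)
  rec <- preprocess_tail(raw)
  expect_equal(rec$dt, 0.005)
  expect_equal(mean(rec$tail_angle), 0, tolerance = 1e-9)
  expect_equal(sd(rec$tail_angle), 1, tolerance = 1e-9)

  # piecewise-linear oracle at an off-grid point: 5 ms output sample k sits
  # at t = 5(k-1) ms between input samples
  t_out <- (seq_along(rec$tail_angle_raw) - 1) * 0.005
  t_in <- (seq_len(n) - 1) * 0.004
  k <- 7L # t = 30 ms, between input samples at 28 and 32 ms
  i <- findInterval(t_out[k], t_in)
  w <- (t_out[k] - t_in[i]) / 0.004
  oracle <- (1 - w) * raw$tail_angle[i] + w * raw$tail_angle[i + 1]
  expect_equal(rec$tail_angle_raw[k], oracle)

  expect_error(preprocess_tail(tail_recording(dt = 0.004,
                                              tail_angle = rep(2, 100),
                                              grating_cmd = 10)),
               "constant")
})

test_that("flick detection matches a brute-force extremum scan on a constructed trace", {
  # zigzag with 7 alternating extrema at known samples
  at <- c(21, 25, 29, 33, 45, 49, 53)
  vals <- c(0.3, -0.3, 0.25, -0.25, 0.1, -0.1, 0.3)
  x <- zigzag_trace(120, at, vals)
  ext <- boutloop:::local_extrema(x)
  # brute-force oracle over strict sign changes
  oracle <- integer()
  for (i in 2:(length(x) - 1)) {
    left <- x[seq_len(i - 1)]
    right <- x[(i + 1):length(x)]
    prev <- rev(left[left != x[i]])[1]
    nxt <- right[right != x[i]][1]
    if (!is.na(prev) && !is.na(nxt) &&
        ((x[i] > prev && x[i] > nxt) || (x[i] < prev && x[i] < nxt)) &&
        x[i - 1] != x[i]) # plateaus take their first sample
      oracle <- c(oracle, i)
  }
  expect_equal(ext, oracle)
  expect_true(all(at %in% ext))
})

test_that("bout boundaries snap to qualifying flicks and weak bouts are discarded", {
  # a bout whose extrema differ by only 0.10 rad has no qualifying flicks
  weak <- zigzag_trace(200, c(101, 105, 109, 113), c(0.05, -0.05, 0.05, -0.05))
  flag <- integer(200); flag[99:115] <- 1L
  rec_weak <- bare_recording(weak, bout_flag = flag)
  expect_equal(nrow(segment_bouts(rec_weak)), 0L)

  # a strong bout snaps onset/offset to the first/last flick extremum
  strong <- zigzag_trace(300, c(101, 105, 109, 113, 117), c(0.3, -0.3, 0.3, -0.3, 0.3))
  flag2 <- integer(300); flag2[95:125] <- 1L
  bt <- segment_bouts(bare_recording(strong, bout_flag = flag2),
                      min_dur_ms = 0)
  expect_equal(bt$onset, 101L)
  expect_equal(bt$offset, 117L)
})

test_that("segmentation is idempotent and its filters only remove", {
  p <- shrink_protocol(build_protocol("long_term_adaptation"), 1, 2, 2, 1)
  rec <- gen_tail_session(p, synth_config(seed = 8))
  bt <- segment_bouts(rec)
  expect_gt(nrow(bt), 10)
  expect_true(all(bt$duration_ms >= 100))
  expect_true(all(is.na(bt$next_interbout_ms) | bt$next_interbout_ms >= 100))
  expect_true(all(rec$grating_cmd[bt$onset] > 0))
  # interbout undefined exactly for each trial's last bout
  last_per_trial <- rev(!duplicated(rev(bt$trial)))
  expect_equal(is.na(bt$next_interbout_ms), last_per_trial)

  # idempotence: re-running on the corrected flags changes nothing
  flag2 <- integer(length(rec$tail_angle))
  for (k in seq_len(nrow(bt))) flag2[bt$onset[k]:bt$offset[k]] <- 1L
  rec2 <- rec
  rec2$bout_flag <- flag2
  bt2 <- segment_bouts(rec2)
  expect_equal(bt2$onset, bt$onset)
  expect_equal(bt2$offset, bt$offset)
})

test_that("animals with a ten-trial bout drought are excluded", {
  expect_true(exclude_fish(c(rep(1L, 5), rep(0L, 9), rep(2L, 5))))
  expect_false(exclude_fish(c(rep(1L, 5), rep(0L, 10), rep(2L, 5))))
  # brute-force run-length oracle on random 240-trial count vectors
  set.seed(4)
  for (i in 1:300) {
    counts <- rbinom(240, 3, 0.25)
    oracle <- FALSE
    run <- 0L
    for (v in counts) {
      run <- if (v == 0L) run + 1L else 0L
      if (run >= 10L) oracle <- TRUE
    }
    expect_equal(exclude_fish(counts), !oracle)
  }
})

test_that("bout power follows the windowed, baseline-subtracted, zeroed recipe", {
  rec <- bare_recording(numeric(2000))
  bouts <- data.frame(onset = 501L, offset = 580L)
  prof <- bout_power(rec, bouts)
  expect_equal(ncol(prof), 220L)
  expect_equal(prof[1, ], rep(0, 220))

  # sinusoidal bout with a constant resting offset: the pre-onset median is
  # subtracted and everything after the bout offset is exactly zero
  x <- rep(0.2, 2000)
  idx <- 501:580
  x[idx] <- 0.2 + 0.5 * sin(2 * pi * 25 * (idx - 501) * 0.005)
  prof2 <- bout_power(bare_recording(x), bouts)[1, ]
  # window covers samples 481:700; positions 101:220 lie past the offset
  expect_equal(prof2[101:220], rep(0, 120))
  expect_equal(prof2[1:100], (x[481:580] - 0.2)^2)

  # a bout too close to the recording start yields an undefined profile
  expect_true(all(is.na(bout_power(rec, data.frame(onset = 10L,
                                                   offset = 100L)))))
})

test_that("ballistic/reactive areas integrate the power curve around 220 ms", {
  prof <- rep(2, 220)
  ar <- split_power(prof)
  expect_equal(ar[["ballistic_area"]], 0.22 * 2)
  expect_equal(ar[["reactive_area"]], 0.775 * 2) # window ends at 995 ms
  expect_equal(ar[["reactive_area"]] / 0.78 / 2, 1, tolerance = 0.01)

  set.seed(5)
  for (i in 1:5) {
    prof <- runif(220)
    ar <- split_power(prof)
    tt <- (0:219) * 0.005 - 0.1
    expect_equal(ar[["ballistic_area"]],
                 pracma::trapz(tt[tt >= 0 & tt <= 0.22],
                               prof[tt >= 0 & tt <= 0.22]))
    expect_equal(ar[["reactive_area"]],
                 pracma::trapz(tt[tt >= 0.22], prof[tt >= 0.22]))
  }
})

test_that("block-of-ten metrics and the 40 ms adapting rule", {
  phase <- rep(c("calibration", "pre_adaptation", "adaptation",
                 "post_adaptation"), c(10, 10, 20, 10))
  flat <- adaptation_metrics(rep(500, 50), phase)
  expect_equal(flat$acute_reaction, 0)
  expect_equal(flat$reduction_of_acute_reaction, 0)
  expect_equal(flat$after_effect, 0)
  expect_false(flat$adapting)

  vals <- rep(c(0, 300, 420, 330, 260), c(10, 10, 10, 10, 10))
  m <- adaptation_metrics(vals, phase)
  expect_equal(m$acute_reaction, 120)
  expect_equal(m$reduction_of_acute_reaction, -90)
  expect_equal(m$after_effect, -40)
  expect_true(m$adapting)

  # trials without a first bout are skipped, not zero-filled
  vals_na <- vals
  vals_na[11:15] <- NA
  expect_equal(adaptation_metrics(vals_na, phase)$acute_reaction, 120)
  vals_all_na <- vals
  vals_all_na[31:40] <- NA
  expect_true(is.na(adaptation_metrics(vals_all_na,
                                       phase)$reduction_of_acute_reaction))
})

test_that("timepoint tests flag condition effects only where they exist", {
  set.seed(6)
  m <- 10L
  # two groups differing by a large shift only after timepoint 5
  g <- rep(c("a", "b"), each = 30)
  prof <- matrix(rnorm(60 * m, 0, 0.1), 60, m)
  prof[g == "b", 6:10] <- prof[g == "b", 6:10] + 5
  mask <- timepoint_condition_test(prof, g)
  expect_equal(mask, rep(c(FALSE, TRUE), each = 5), ignore_attr = TRUE)

  # family-wise type-I control under identical distributions
  any_sig <- vapply(1:200, function(i) {
    prof0 <- matrix(rnorm(40 * m), 40, m)
    any(timepoint_condition_test(prof0, rep(c("a", "b"), each = 20)),
        na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(any_sig), 0.1)

  expect_error(timepoint_condition_test(prof, rep("a", 60)), "two condition")
})

test_that("rank-sum group comparison matches exact enumeration on small samples", {
  # all of one group above the other, n = 3 vs 3: two-sided exact p = 0.1
  expect_equal(group_compare(c(1, 2, 3), c(10, 11, 12)), 2 / choose(6, 3))
  set.seed(7)
  expect_gt(group_compare(rnorm(200), rnorm(200)), 0.001)
  expect_warning(p1 <- group_compare(rep(1, 5), rep(1, 6)), "tied")
  expect_equal(p1, 1)
  # one-tailed option
  expect_equal(group_compare(c(1, 2, 3), c(10, 11, 12),
                             alternative = "less"), 1 / choose(6, 3))
  expect_error(group_compare(numeric(), 1), "at least one")
})
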