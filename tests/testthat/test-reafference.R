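test_that("vigor is a causal sliding SD: quiet traces give zero, fast oscillations give A/sqrt(2)", {
  expect_equal(compute_vigor(rep(1.3, 200), dt = 0.005), rep(0, 200))

  # fast sinusoid, period 5 ms << 50 ms window: plateau at A / sqrt(2)
  dt <- 0.001
  A <- 0.4
  t <- seq(0, 0.5, by = dt)
  x <- A * sin(2 * pi * t / 0.005)
  v <- compute_vigor(x, dt = dt)
  plateau <- v[t > 0.1]
  expect_true(all(abs(plateau - A / sqrt(2)) / (A / sqrt(2)) < 0.02))

  # brute-force windowed population SD oracle on an irregular trace
  set.seed(1)
  x <- cumsum(rnorm(400, 0, 0.05))
  v <- compute_vigor(x, dt = 0.005, window = 0.05)
  w <- 10L
  oracle <- vapply(seq_along(x), function(i) {
    seg <- x[max(1L, i - w + 1L):i]
    sqrt(mean((seg - mean(seg))^2))
  }, numeric(1))
  expect_equal(v, oracle, tolerance = 1e-10)
})

test_that("vigor rejects a non-uniform time base", {
  expect_error(compute_vigor(1:5, time = c(0, 1, 2, 4, 5)), "uniform")
})

test_that("multiplier calibration hits the 20 mm/s median in-bout velocity", {
  flag <- rep(c(0L, 1L), each = 50)
  expect_equal(calibrate_multiplier(rep(0.5, 100), flag), 40)

  # bimodal in-bout vigor: multiplier = 20 / sample median
  set.seed(2)
  vig <- c(rnorm(60, 0.2, 0.01), rnorm(40, 0.8, 0.01))
  flag2 <- rep(1L, 100)
  mult <- calibrate_multiplier(vig, flag2)
  expect_equal(mult, 20 / median(vig))
  expect_equal(median(vig * mult), 20)

  expect_error(calibrate_multiplier(rep(0.5, 10), rep(0L, 10)), "no bouts")
})

test_that("online bout detection thresholds strictly at 2 mm/s", {
  expect_equal(detect_bouts_online(rep(0, 50)), rep(0L, 50))
  v <- c(rep(0, 10), rep(5, 60), rep(0, 10)) # 300 ms step at 5 ms sampling
  expect_equal(boutloop:::flag_runs(detect_bouts_online(v)),
               data.frame(onset = 11L, offset = 70L))
  expect_equal(detect_bouts_online(c(1.9, 2, 2.1)), c(0L, 0L, 1L))
})

test_that("reafference transformations follow the gain/lag/gain-drop semantics", {
  n <- 500
  b <- integer(n); b[101:180] <- 1L # 400 ms bout
  v <- 20 * b

  expect_equal(apply_reafference(v, b, reaff_open_loop()), rep(10, n))
  shown <- apply_reafference(v, b, reaff_normal())
  expect_equal(shown[101:180], rep(-10, 80))
  expect_equal(shown[-(101:180)], rep(10, n - 80))

  # gain scales the reafference linearly
  s066 <- apply_reafference(v, b, reaff_condition("gain", gain = 0.66))
  expect_equal(10 - s066, 0.66 * (10 - shown) / 1)

  # profile 1100: reafference on for the first 150 ms, off for the next
  # 150 ms, on again beyond 300 ms of the bout
  s1100 <- apply_reafference(v, b, reaff_condition("gain_drop", profile = "1100"))
  oracle <- rep(10, n)
  oracle[101:130] <- -10   # segments 1-2: 0-150 ms
  oracle[131:160] <- 10    # segments 3-4: 150-300 ms, gain 0
  oracle[161:180] <- -10   # beyond 300 ms: gain 1
  expect_equal(s1100, oracle)

  expect_error(apply_reafference(v, b, structure(list(), class = "lm")))
})

test_that("normal, lag-0 and profile-1111 are one equivalence class on any input", {
  set.seed(3)
  for (rep_i in 1:5) {
    b <- as.integer(runif(400) > 0.7)
    v <- runif(400, 0, 30) * b
    out <- lapply(list(reaff_normal(),
                       reaff_condition("lag", lag = 0),
                       reaff_condition("lag", lag = 0, shunted = TRUE),
                       reaff_condition("gain_drop", profile = "1111")),
                  function(cc) apply_reafference(v, b, cc))
    for (k in 2:4) expect_equal(out[[k]], out[[1]])
  }
})

test_that("shunted and non-shunted lag agree during the bout and differ only after offset", {
  n <- 600
  b <- integer(n); b[101:200] <- 1L
  v <- 20 * b
  lagged <- apply_reafference(v, b, reaff_condition("lag", lag = 150))
  shunted <- apply_reafference(v, b, reaff_condition("lag", lag = 150,
                                                     shunted = TRUE))
  expect_equal(lagged[1:200], shunted[1:200])
  # non-shunted stream persists exactly lag ms past offset
  expect_equal(lagged[201:230], rep(-10, 30))
  expect_equal(shunted[201:230], rep(10, 30))
  expect_equal(lagged[231:n], shunted[231:n])
})

test_that("the redundant condition battery deduplicates to 18 functionally distinct conditions", {
  uc <- enumerate_conditions()
  expect_length(uc, 18L)
  labs <- boutloop:::condition_labels(uc)
  expect_setequal(labs, c("normal", "open_loop",
                          paste0("gain_", c(0.33, 0.66, 1.33, 1.66, 2)),
                          paste0("lag_", c(75, 150, 225, 300)),
                          paste0("shunted_lag_", c(75, 150, 225, 300)),
                          paste0("gain_drop_", c(1110, 1100, 1000))))
  eq <- lapply(uc, attr, "equivalents")
  names(eq) <- labs
  expect_setequal(eq$open_loop, c("gain_0", "lag_Inf", "shunted_lag_Inf"))
  expect_setequal(eq$normal,
                  c("gain_1", "lag_0", "shunted_lag_0", "gain_drop_1111"))
  expect_setequal(eq$shunted_lag_150, c("shunted_lag_150", "gain_drop_0011"))
  expect_setequal(eq$shunted_lag_300, c("shunted_lag_300", "gain_drop_0000"))

  # brute-force check: the 18 representatives are pairwise distinct on a
  # probe trace with a single constant-velocity bout
  n <- 700
  b <- integer(n); b[101:180] <- 1L
  v <- 20 * b
  sigs <- vapply(uc, function(cc)
    paste(round(apply_reafference(v, b, cc), 9), collapse = ","),
    character(1))
  expect_length(unique(sigs), 18L)
})

test_that("protocols assemble with the documented phase structure", {
  p <- build_protocol("long_term_adaptation", "lag_trained")
  expect_equal(nrow(p$trials), 240L)
  expect_equal(as.vector(table(factor(p$trials$phase,
                                      c("calibration", "pre_adaptation",
                                        "adaptation", "post_adaptation")))),
               c(10L, 10L, 210L, 10L))
  expect_true(all(p$trials$policy[p$trials$phase == "adaptation"] == "lag_225"))
  expect_true(all(p$trials$policy[p$trials$phase != "adaptation"] == "normal"))

  expect_equal(as.vector(table(factor(
    build_protocol("pc_imaging")$trials$phase,
    c("calibration", "pre_adaptation", "adaptation", "post_adaptation")))),
    c(10L, 10L, 50L, 50L))

  wb <- build_protocol("whole_brain_imaging")
  expect_equal(nrow(wb$trials), 60L)
  expect_equal(wb$blank_lead_s, 120)
  expect_error(build_protocol("open_field"))

  # command trace: 7.5 s static / 15 s at 10 mm/s / 7.5 s static per trial
  pc <- protocol_command(build_protocol("acute_reaction"), dt = 0.005)
  one <- pc$cmd[pc$trial_id == 1]
  expect_length(one, 6000L)
  expect_equal(one[1:1500], rep(0, 1500))
  expect_equal(one[1501:4500], rep(10, 3000))
  expect_equal(one[4501:6000], rep(0, 1500))

  # whole-brain reverse pulses: 350 ms at -10 mm/s, 5 s and 10 s after stop
  pcw <- protocol_command(wb, dt = 0.005)
  stop_t <- wb$blank_lead_s + 7.5 + 15
  i5 <- round((stop_t + 5) / 0.005) + 1
  expect_equal(pcw$cmd[i5 + 0:69], rep(-10, 70))
  i10 <- round((stop_t + 10) / 0.005) + 1
  expect_equal(pcw$cmd[i10 + 0:69], rep(-10, 70))
})

test_that("acute-reaction bouts draw conditions uniformly over the 18", {
  labs <- boutloop:::condition_labels(enumerate_conditions())
  set.seed(5)
  draws <- boutloop:::draw_bout_conditions("random_18", 10000L, labs)
  tab <- table(factor(draws, levels = seq_along(labs)))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("closed-loop sessions are deterministic and honor a motionless behaver", {
  p <- shrink_protocol(build_protocol("acute_reaction"), 1, 1, 2, 1)
  still <- function(u, t) 0
  rec <- run_closed_loop_session(p, still, seed = 4)
  expect_equal(rec$grating_shown, rec$grating_cmd)
  expect_equal(nrow(rec$bouts), 0L)

  r1 <- run_closed_loop_session(p, reference_params(), seed = 9)
  r2 <- run_closed_loop_session(p, reference_params(), seed = 9)
  expect_identical(r1, r2)

  # controller bouts have realistic durations under normal reafference
  pn <- shrink_protocol(build_protocol("long_term_adaptation"), 0, 2, 0, 0)
  rn <- run_closed_loop_session(pn, reference_params(), seed = 1)
  dur <- (rn$bouts$offset - rn$bouts$onset + 1) * rn$dt
  expect_true(all(dur >= 0.1 & dur <= 1))
  expect_gte(nrow(rn$bouts) / 2, 5) # >= 5 bouts per 15 s moving period

  expect_error(run_closed_loop_session(p, function(u, t) NaN), "non-finite")
})

test_that("scripted behavers get per-bout reafference through the offline transform", {
  p <- shrink_protocol(build_protocol("long_term_adaptation", "lag_trained"),
                       0, 1, 1, 0)
  sched <- data.frame(onset_s = c(10, 40), offset_s = c(10.4, 40.4))
  rec <- run_closed_loop_session(p, sched, seed = 1)
  expect_equal(nrow(rec$bouts), 2L)
  expect_equal(rec$bouts$condition, c("normal", "lag_225"))
  # normal bout: shown = 10 - 20 during the bout
  expect_equal(unique(rec$grating_shown[2001:2080]), -10)
  # lagged bout: shown stays at base for the first 225 ms of the bout
  expect_equal(unique(rec$grating_shown[8001:8045]), 10)
  expect_equal(unique(rec$grating_shown[8046:8080]), -10)
})
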