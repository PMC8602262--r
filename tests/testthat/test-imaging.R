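test_that("trace preprocessing detrends and z-scores", {
  set.seed(1)
  fs <- 1.5
  x <- rnorm(3000)
  y <- preprocess_trace(x, fs, "whole_brain")
  expect_equal(mean(y), 0, tolerance = 1e-9)
  expect_equal(sd(y), 1, tolerance = 1e-9)

  # a slow drift (period >> 300 s) is removed almost entirely: compare the
  # drift's contribution before and after baseline subtraction
  t <- seq(0, 2000 - 1 / fs, by = 1 / fs)
  drift <- sin(2 * pi * t / 1500)
  sig <- rnorm(length(t), 0, 0.05)
  filt <- function(tr) {
    z <- boutloop:::butter_pad(tr, 0.56, fs, "low")
    z - boutloop:::butter_pad(z, 0.0033, fs, "low")
  }
  resid_drift <- filt(sig + drift) - filt(sig)
  expect_lt(max(abs(resid_drift)) / max(abs(drift)), 0.1)

  # pc mode: the high-pass attenuates the drift amplitude by > 90%
  hp_drift <- boutloop:::butter_pad(drift, 0.0033, fs, "high")
  expect_lt(max(abs(hp_drift)) / max(abs(drift)), 0.1)

  expect_error(preprocess_trace(x, 0.005, "whole_brain"), "Nyquist")
  expect_error(preprocess_trace(rep(1, 100), 1.5, "whole_brain"), "constant")
})

test_that("preprocessing is nearly idempotent on indicator-band signals", {
  # a calcium-like trace: slow trial-locked responses well below the
  # 0.56 Hz de-noising cutoff, plus a little wideband noise
  set.seed(2)
  fs <- 1.5
  t <- seq_len(3000) / fs
  x <- sin(2 * pi * t / 30) + 0.5 * sin(2 * pi * t / 97) + rnorm(3000, 0, 0.02)
  once <- preprocess_trace(x, fs, "whole_brain")
  twice <- preprocess_trace(once, fs, "whole_brain")
  # judged away from the trace edges, where finite-length padding
  # transients (not the filter response) dominate
  core <- 1000:2000 # the 3.3 mHz stage's transients span ~700 samples
  expect_lt(sqrt(mean((twice - once)[core]^2)) / sd(once[core]), 0.01)
})

test_that("triggered averages subtract baselines and mask following triggers", {
  fs <- 2
  x <- rep(3, 100)
  av <- triggered_average(x, fs, c(10, 20, 30), len_s = 5, pre_s = 1)
  expect_equal(av$mean, rep(0, 10)) # constant trace: baseline removal
  expect_equal(av$n, 3L)

  # two triggers 2 s apart inside a 5 s window: mask after the second
  x2 <- seq_len(100) * 0.1
  m <- triggered_traces(x2, fs, c(10, 12, 30), len_s = 5, pre_s = 1)
  # trigger at 12 s is inadmissible (one in the preceding second? no - 2 s
  # gap, admissible); trigger at 10 s is masked from t = +2 s
  i10 <- which(attr(m, "triggers_s") == 10)
  tt <- attr(m, "time_s")
  expect_true(all(is.nan(m[i10, tt >= 2])))
  expect_false(anyNA(m[i10, tt < 2]))
  # hand-masked oracle for the unmasked part
  idx <- (10 * fs + 1 - 2):(10 * fs + 8) # samples of the first window
  oracle <- x2[idx] - mean(x2[idx[1:2]])
  expect_equal(unname(m[i10, tt < 2]), oracle[tt < 2])

  # a trigger with another one in its preceding second is dropped
  m2 <- triggered_traces(x2, fs, c(10, 10.5), len_s = 5, pre_s = 1)
  expect_equal(attr(m2, "triggers_s"), 10)
  expect_error(triggered_traces(x2, fs, numeric()), "admissible")
})

test_that("sensory and motor scores classify constructed traces sensibly", {
  p <- shrink_protocol(build_protocol("whole_brain_imaging"), 1, 2, 4, 0)
  p$blank_lead_s <- 30
  cfg <- synth_config(seed = 21)
  rec <- gen_tail_session(p, cfg)
  specs <- data.frame(type = c("sensor", "noise"), tau = c(0.5, NA),
                      profile = NA, snr = c(8, 1))
  fl <- gen_fluorescence(rec, specs, fs = 1.5, config = cfg)
  tr <- apply(fl$traces, 1, preprocess_trace, fs = fl$fs,
              mode = "whole_brain")
  sm <- sensory_motor_scores(tr[, 1], fl$fs, fl$grating_onsets_s,
                             fl$bout_onsets_s, n_shuffles = 500, seed = 3)
  expect_equal(sm$class, "sensory")
  expect_true(sm$sensory_significant)

  # pure-noise traces stay unclassified in the vast majority of seeds
  classes <- vapply(1:30, function(i) {
    boutloop:::with_seed(100 + i, {
      noise <- rnorm(length(tr[, 2]))
      sensory_motor_scores(noise, fl$fs, fl$grating_onsets_s,
                           fl$bout_onsets_s, n_shuffles = 300,
                           seed = i)$class
    })
  }, character(1))
  frac <- mean(classes == "unclassified")
  # consistent with a type-I rate near 5% per score (>= 90% joint)
  expect_gt(stats::binom.test(sum(classes == "unclassified"), 30, 0.9,
                              alternative = "less")$p.value, 0.05)

  expect_error(sensory_motor_scores(rnorm(10), 1.5, 1, 1), "too short")
})

test_that("leaky-integrator time constants are recovered from noiseless traces", {
  set.seed(3)
  fs <- 5
  stim <- rep(rep(c(0, 10, 0), c(40, 75, 40)), 8) # trial-like drive
  for (tau in c(0.5, 2, 4.5, 9.5)) {
    trace <- boutloop:::indicator_convolve(
      boutloop:::leaky_integrate(stim, tau, fs), fs)
    ft <- fit_time_constant(trace, stim, fs)
    expect_equal(ft$tau, tau)
    # invariance to affine rescaling of the trace
    expect_equal(fit_time_constant(3.7 * trace + 11, stim, fs)$tau, tau)
  }
  expect_equal(fit_time_constant(
    boutloop:::indicator_convolve(boutloop:::leaky_integrate(stim, 1.5, fs), fs),
    stim, fs)$class, "sensor")
  expect_equal(fit_time_constant(
    boutloop:::indicator_convolve(boutloop:::leaky_integrate(stim, 2, fs), fs),
    stim, fs)$class, "integrator")
  expect_error(fit_time_constant(rep(1, length(stim)), stim, fs),
               "constant")
})

test_that("time-constant changes are summarized and thresholded at 0.4 s", {
  same <- tau_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$delta, c(0, 0, 0))
  expect_equal(same$flagged_fraction, 0)

  # planted -1.0 s decreases in 30% of units
  set.seed(9)
  n <- 200
  t0 <- sample(seq(2, 8, by = 0.5), n, replace = TRUE)
  shift <- rep(c(-1, 0), c(60, 140))
  tc <- tau_change(t0, t0 + shift)
  expect_gt(tc$flagged_fraction, 0.3 - 2 * sqrt(0.3 * 0.7 / n))
  expect_lt(tc$flagged_fraction, 0.3 + 2 * sqrt(0.3 * 0.7 / n))
  expect_equal(tc$density$bw, 0.1)
  # units with a missing block are skipped
  expect_length(tau_change(c(1, NA, 3), c(2, 2, NA))$delta, 1L)
})

test_that("the motor regressor is the indicator-kernel convolution of the bout flag", {
  fs <- 5
  expect_equal(motor_regressor(rep(0, 50), fs), rep(0, 50))
  imp <- c(1, rep(0, 9))
  r <- motor_regressor(imp, fs)
  a <- exp(-log(2) / (fs * 1.8))
  expect_equal(r[1:5], a^(0:4))
  expect_error(motor_regressor(c(0, 2), fs), "binary")
})

test_that("protocol-transition criteria equal hand-computed block differences", {
  phase <- rep(c("calibration", "pre_adaptation", "adaptation",
                 "post_adaptation"), c(10, 10, 50, 50))
  expect_equal(unname(compute_criteria(rep(2.5, 120), phase)),
               rep(0, 4))
  # step schedule: pre 1.0, early-adapt 1.0, late-adapt 0.4, early-post
  # 0.4, late-post 1.0
  resp <- c(rep(1, 20), rep(1, 25), rep(0.4, 25), rep(0.4, 25), rep(1, 25))
  expect_equal(unname(compute_criteria(resp, phase)),
               c(0, -0.6, 0, 0.6))
  expect_error(compute_criteria(resp[1:30], phase[1:30]), "phase labels")
})

test_that("barcodes partition outcomes and reproduce under a seed", {
  phase <- rep(c("calibration", "pre_adaptation", "adaptation",
                 "post_adaptation"), c(10, 10, 50, 50))
  set.seed(10)
  resp <- rnorm(120)
  b1 <- barcode(resp, phase, n_shuffles = 2000, seed = 7)
  expect_match(b1$barcode, "^[+0-]{4}$")
  expect_identical(b1, barcode(resp, phase, n_shuffles = 2000, seed = 7))

  # a strong planted decline-and-recovery profile maps to 0-0+
  resp2 <- c(rep(1, 20), rep(1, 25), rep(0.4, 25), rep(0.4, 25), rep(1, 25)) +
    rnorm(120, 0, 0.05)
  expect_equal(barcode(resp2, phase, n_shuffles = 2000, seed = 7)$barcode,
               "0-0+")
  expect_error(barcode(resp[1:25], phase[c(1:10, 21:35)],
                       n_shuffles = 10, seed = 1), "too few")
})

test_that("ROI segmentation finds planted blobs and ignores white noise", {
  # independent white noise: no somata-sized ROI survives the area bounds
  zero_hits <- vapply(1:5, function(i) {
    mv <- boutloop:::with_seed(i, array(rnorm(32 * 32 * 60), c(32, 32, 60)))
    nrow(segment_rois(mv)$rois) == 0L
  }, logical(1))
  expect_true(all(zero_hits))

  # two well-separated blobs: exactly two ROIs covering >= 80% of each
  vol <- gen_volume(2, synth_config(seed = 12, volume_dims = c(40, 40)))
  seg <- segment_rois(vol$movie, voxel_size = vol$voxel_size)
  expect_equal(nrow(seg$rois), 2L)
  overlap <- vapply(vol$masks, function(gt) {
    gt_key <- paste(gt[, 1], gt[, 2])
    max(vapply(seg$masks, function(m)
      mean(gt_key %in% paste(m[, "x"], m[, "y"])), numeric(1)))
  }, numeric(1))
  expect_true(all(overlap >= 0.8))
  # ROI traces are voxel sums of somata-scale areas
  expect_true(all(seg$rois$area_um2 >= 9 & seg$rois$area_um2 <= 28))
  expect_equal(ncol(seg$traces), dim(vol$movie)[4])
})

test_that("cluster enrichment flags group-specific barcodes", {
  df <- rbind(
    data.frame(fish = rep(1:4, each = 20), group = "adapting",
               barcode = rep(c("0-0+", "0000"), c(8, 12))),
    data.frame(fish = rep(5:8, each = 20), group = "control",
               barcode = "0000"),
    data.frame(fish = rep(9:12, each = 20), group = "nonadapting",
               barcode = "0000"))
  ce <- cluster_enrichment(df)
  row <- ce[ce$cluster == "0-0+", ]
  expect_true(row$significant)
  expect_true(row$reported)

  # identical compositions: nothing significant
  df0 <- data.frame(fish = rep(1:6, each = 10),
                    group = rep(c("a", "b"), each = 30),
                    barcode = rep(c("0000", "+000"), 30))
  ce0 <- cluster_enrichment(df0)
  expect_false(any(ce0$significant))
  expect_error(cluster_enrichment(df0[df0$group == "a", ]), "2 groups")
})
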