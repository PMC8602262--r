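#' Swim vigor: causal sliding standard deviation of the tail trace
#'
#' Vigor is the sliding standard deviation of the cumulative tail angle over
#' a trailing 50 ms window, computed as it would be on the rig (causally:
#' each output sample uses only the current and preceding samples; the
#' window expands from one sample at the start of the recording). It is near
#' zero during quiescence and rises during swim bouts, which makes it a
#' proxy for the forward velocity a freely swimming larva would reach.
#'
#' The population form of the standard deviation is used, so a fast
#' oscillation of amplitude A yields a plateau of A/sqrt(2).
#'
#' @param tail_angle tail trace in radians.
#' @param dt sampling period in seconds (uniform grid). Alternatively pass
#'   `time`, a vector of sample times, which must be uniform.
#' @param time optional time vector; rejected if not uniformly sampled.
#' @param window window length in seconds (50 ms on the rig).
#' @return vigor series (radians), aligned to the input grid.
#' @examples
#' compute_vigor(rep(1, 100), dt = 0.005)  # constant trace: vigor is 0
#' @export
compute_vigor <- function(tail_angle, dt = NULL, time = NULL, window = 0.05) {
  if (is.null(dt)) {
    if (is.null(time)) stop("supply `dt` or `time`")
    steps <- diff(time)
    if (length(steps) < 1L || any(abs(steps - steps[1]) > 1e-9 * steps[1]) ||
        steps[1] <= 0)
      stop("time base must be uniform with positive sampling period")
    dt <- steps[1]
  }
  stopifnot_scalar(dt, "dt")
  w <- max(1L, as.integer(round(window / dt)))
  n <- length(tail_angle)
  # centring improves the conditioning of the running-moment computation
  x <- as.numeric(tail_angle) - mean(tail_angle)
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  cnt <- i - lo
  sum1 <- s1[i] - c(0, s1)[lo + 1L]
  sum2 <- s2[i] - c(0, s2)[lo + 1L]
  v <- sum2 / cnt - (sum1 / cnt)^2
  sqrt(pmax(v, 0))
}

#' Calibrate the vigor-to-velocity multiplier
#'
#' Finds the factor converting vigor (radians) into estimated forward
#' velocity (mm/s) such that the median estimated velocity over all in-bout
#' samples of the supplied session equals `target_median` (20 mm/s on the
#' rig, matching free swimming). On the rig this is optimized during the
#' calibration phase; pass only that phase to reproduce the protocol, or a
#' whole session to calibrate against all of its bouts.
#'
#' @param rec a [tail_recording()] with computed vigor and bout flags, or a
#'   numeric vigor vector (then supply `bout_flag`).
#' @param bout_flag 0/1 vector (ignored when `rec` is a recording).
#' @param target_median desired median in-bout estimated velocity (mm/s).
#' @return the multiplier (mm/s per radian).
#' @export
calibrate_multiplier <- function(rec, bout_flag = NULL, target_median = 20) {
  if (inherits(rec, "tail_recording")) {
    vigor <- rec$vigor
    bout_flag <- rec$bout_flag
  } else vigor <- rec
  if (is.null(bout_flag) || !any(bout_flag == 1))
    stop("calibration failed: the session contains no bouts")
  m <- median(vigor[bout_flag == 1], na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("calibration failed: in-bout vigor is not positive")
  target_median / m
}

#' Online bout detection by velocity threshold
#'
#' Marks a sample as in-bout exactly when the estimated velocity exceeds the
#' threshold (strictly greater than; 2 mm/s on the rig). This mirrors the
#' hysteresis-free real-time detector; refined, flick-corrected segmentation
#' is done offline by [segment_bouts()].
#'
#' @param est_velocity estimated velocity series (mm/s).
#' @param threshold detection threshold (mm/s).
#' @return integer 0/1 bout flag series.
#' @export
detect_bouts_online <- function(est_velocity, threshold = 2) {
  as.integer(est_velocity > threshold)
}
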