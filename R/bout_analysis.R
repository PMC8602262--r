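#' Preprocess a raw tail recording
#'
#' Interpolates the tail trace and the grating-velocity traces to a uniform
#' 5 ms grid (linear interpolation; flags and trial indices are carried by
#' nearest-neighbour lookup) and z-scores the tail trace over the session.
#' The raw-radian trace is kept alongside (`tail_angle_raw`) because bout
#' power is measured in squared radians.
#'
#' @param rec a [tail_recording()] (any uniform sampling period).
#' @param dt_out output sampling period (s).
#' @return a preprocessed [tail_recording()] with `tail_angle` z-scored and
#'   `tail_angle_raw` in radians.
#' @export
preprocess_tail <- function(rec, dt_out = 0.005) {
  if (!inherits(rec, "tail_recording")) stop("`rec` must be a tail_recording")
  if (!all(is.finite(rec$tail_angle))) stop("tail trace must be finite")
  n <- length(rec$tail_angle)
  t_in <- (seq_len(n) - 1) * rec$dt
  t_out <- seq(0, t_in[n], by = dt_out)
  lin <- function(y) approx(t_in, y, t_out, rule = 2)$y
  near <- function(y) y[pmin(pmax(round(t_out / rec$dt) + 1, 1), n)]
  tail_raw <- lin(rec$tail_angle)
  s <- sd(tail_raw)
  if (!is.finite(s) || s == 0)
    stop("tail trace is constant: z-score undefined")
  out <- tail_recording(dt = dt_out, tail_angle = (tail_raw - mean(tail_raw)) / s,
                        grating_cmd = lin(rec$grating_cmd),
                        grating_shown = lin(rec$grating_shown),
                        vigor = if (all(is.na(rec$vigor))) NA_real_ else lin(rec$vigor),
                        est_velocity = if (all(is.na(rec$est_velocity)))
                          NA_real_ else lin(rec$est_velocity),
                        bout_flag = near(rec$bout_flag),
                        trial_id = near(rec$trial_id), phase = rec$phase,
                        bouts = rec$bouts, multiplier = rec$multiplier)
  out$tail_angle_raw <- tail_raw
  out
}

# Indices of local extrema of x, strict comparisons; across plateaus the
# first sample of the plateau is taken.
local_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer())
  s <- sign(d[nz])
  chg <- which(s[-1] != s[-length(s)])
  nz[chg] + 1L
}

#' Segment bouts from a recording by flick correction
#'
#' Offline bout segmentation: starting from the online bout-flag intervals,
#' individual tail flicks are detected (a flick is the section of the tail
#' trace between two adjacent local extrema with magnitude > 0.14 rad and
#' duration <= 100 ms) and each bout's onset/offset is snapped to the start
#' of its first and the end of its last qualifying flick. Bouts without any
#' qualifying flick, bouts outside forward grating motion, bouts shorter
#' than 100 ms and bouts adjacent to an interbout shorter than 100 ms are
#' excluded. The interbout following the last bout of a trial is undefined.
#'
#' @param rec a preprocessed [tail_recording()] (see [preprocess_tail()]);
#'   flick detection runs on the recording's `tail_angle` channel.
#' @param flick_mag minimal flick magnitude (in the units of `tail_angle`).
#' @param flick_dur_max maximal flick duration (s).
#' @param min_dur_ms minimal bout and interbout duration (ms).
#' @return a `bout_table` data frame: `onset`, `offset` (sample indices of
#'   the flick-corrected bout), `onset_s`, `duration_ms`,
#'   `next_interbout_ms` (`NA` for the last bout of a trial), `trial`,
#'   `first_in_trial`, `condition`.
#' @export
segment_bouts <- function(rec, flick_mag = 0.14, flick_dur_max = 0.1,
                          min_dur_ms = 100) {
  x <- rec$tail_angle
  dt <- rec$dt
  ext <- local_extrema(x)
  flick <- NULL
  if (length(ext) >= 2L) {
    a <- ext[-length(ext)]
    b <- ext[-1]
    ok <- abs(x[b] - x[a]) > flick_mag & (b - a) * dt <= flick_dur_max
    flick <- cbind(start = a[ok], end = b[ok])
  }
  runs <- flag_runs(rec$bout_flag)
  out <- list()
  if (nrow(runs) && !is.null(flick) && nrow(flick)) {
    for (k in seq_len(nrow(runs))) {
      on <- runs$onset[k]; off <- runs$offset[k]
      hit <- which(flick[, "start"] <= off & flick[, "end"] >= on)
      if (!length(hit)) next
      o1 <- flick[hit[1], "start"]
      o2 <- flick[hit[length(hit)], "end"]
      if (rec$grating_cmd[o1] <= 0) next # only during forward grating motion
      cond <- NA_character_
      if (!is.null(rec$bouts) && nrow(rec$bouts)) {
        m <- which(rec$bouts$onset <= off & rec$bouts$offset >= on)
        if (length(m)) cond <- rec$bouts$condition[m[1]]
      }
      out[[length(out) + 1L]] <- data.frame(
        onset = o1, offset = o2, trial = rec$trial_id[o1],
        condition = cond)
    }
  }
  if (!length(out)) {
    empty <- data.frame(onset = integer(), offset = integer(),
                        onset_s = numeric(), duration_ms = numeric(),
                        next_interbout_ms = numeric(), trial = integer(),
                        first_in_trial = logical(), condition = character())
    class(empty) <- c("bout_table", "data.frame")
    return(empty)
  }
  bt <- do.call(rbind, out)
  bt <- bt[order(bt$onset), , drop = FALSE]
  bt$duration_ms <- (bt$offset - bt$onset + 1L) * dt * 1000
  # interbouts between neighbouring bouts of the same trial
  nb <- nrow(bt)
  gap_next <- rep(NA_real_, nb)
  if (nb > 1L) {
    same <- bt$trial[-1] == bt$trial[-nb]
    gap <- (bt$onset[-1] - bt$offset[-nb] - 1L) * dt * 1000
    gap_next[which(same)] <- gap[same]
  }
  gap_prev <- c(NA_real_, gap_next[-nb])
  keep <- bt$duration_ms >= min_dur_ms &
    (is.na(gap_next) | gap_next >= min_dur_ms) &
    (is.na(gap_prev) | gap_prev >= min_dur_ms)
  bt$next_interbout_ms <- gap_next
  bt <- bt[keep, , drop = FALSE]
  bt$onset_s <- (bt$onset - 1L) * dt
  bt$first_in_trial <- !duplicated(bt$trial)
  rownames(bt) <- NULL
  bt <- bt[, c("onset", "offset", "onset_s", "duration_ms",
               "next_interbout_ms", "trial", "first_in_trial", "condition")]
  class(bt) <- c("bout_table", "data.frame")
  bt
}

#' Animal inclusion check
#'
#' An animal is excluded when its session contains a block of ten or more
#' consecutive trials without any bouts (a sign of damage or severe
#' deficits rather than of the manipulation under study).
#'
#' @param trial_bout_counts integer vector of bout counts, ordered by trial.
#' @param block_len length of the disqualifying zero-bout run.
#' @return `TRUE` (keep) or `FALSE` (exclude).
#' @export
exclude_fish <- function(trial_bout_counts, block_len = 10L) {
  r <- rle(trial_bout_counts == 0L)
  !any(r$values & r$lengths >= block_len)
}

#' Bout power profiles
#'
#' For each bout, a 1.1 s section of the tail trace starting 100 ms before
#' bout onset is selected; the median of the 100 ms pre-onset window is
#' subtracted, samples after the bout offset are replaced with zeros (so
#' subsequent bouts do not contaminate the window), and the result is
#' squared. At 5 ms sampling the half-open window \[-100 ms, 1000 ms)
#' contains exactly 220 samples.
#'
#' @param rec a preprocessed [tail_recording()].
#' @param bouts a `bout_table` from [segment_bouts()].
#' @param use `"raw"` (squared radians, default) or `"zscored"`.
#' @param pre_s,len_s window geometry (s).
#' @return a bouts x samples matrix (rows of `NA` for bouts too close to
#'   the recording start); attribute `time_s` holds the within-window time
#'   relative to bout onset.
#' @export
bout_power <- function(rec, bouts, use = c("raw", "zscored"),
                       pre_s = 0.1, len_s = 1.1) {
  use <- match.arg(use)
  x <- if (use == "raw" && !is.null(rec$tail_angle_raw)) rec$tail_angle_raw
       else rec$tail_angle
  dt <- rec$dt
  npre <- round(pre_s / dt)
  nwin <- round(len_s / dt)
  prof <- matrix(NA_real_, nrow(bouts), nwin)
  for (k in seq_len(nrow(bouts))) {
    i0 <- bouts$onset[k] - npre
    if (i0 < 1L || i0 + nwin - 1L > length(x)) next
    seg <- x[i0:(i0 + nwin - 1L)]
    base <- median(seg[seq_len(npre)])
    seg <- seg - base
    post_off <- which(seq(i0, by = 1L, length.out = nwin) > bouts$offset[k])
    seg[post_off] <- 0
    prof[k, ] <- seg^2
  }
  attr(prof, "time_s") <- (seq_len(nwin) - 1L - npre) * dt
  prof
}

#' Split a bout power profile into ballistic and reactive areas
#'
#' The ballistic period covers 0-220 ms after bout onset (the span over
#' which ongoing reafference cannot yet influence the tail beat, given the
#' 220 ms sensory delay); the reactive period covers the remainder of the
#' window. Areas under the power curve are computed by the trapezoidal
#' rule, in units of `profile` x seconds.
#'
#' @param profile one power profile (a row of [bout_power()] output).
#' @param dt sampling period (s).
#' @param pre_s pre-onset span of the window (s).
#' @param boundary_s ballistic/reactive boundary after onset (s).
#' @return `c(ballistic_area, reactive_area)`.
#' @export
split_power <- function(profile, dt = 0.005, pre_s = 0.1, boundary_s = 0.22) {
  tt <- (seq_along(profile) - 1) * dt - pre_s
  bal <- tt >= 0 & tt <= boundary_s
  rea <- tt >= boundary_s
  c(ballistic_area = trapz_area(tt[bal], profile[bal]),
    reactive_area = trapz_area(tt[rea], profile[rea]))
}

#' Block-of-ten adaptation metrics
#'
#' Summarizes a long-term adaptation session by block differences of a
#' per-trial metric (canonically the first-bout duration): *acute reaction*
#' (first ten adaptation trials minus the pre-adaptation block),
#' *reduction of acute reaction* (last ten adaptation trials minus the
#' first ten), and *after-effect* (first ten post-adaptation trials minus
#' the pre-adaptation block). Trials without a value (no first bout) are
#' skipped, not zero-filled. A lag-trained animal counts as *adapting* when
#' the first-bout duration drops by at least 40 ms from the first to the
#' last ten adaptation trials.
#'
#' @param values per-trial metric (e.g. first-bout duration in ms), `NA`
#'   where undefined; ordered by trial.
#' @param phase character phase label per trial.
#' @param block block length in trials.
#' @param adapt_threshold adapting-classification threshold, in the units
#'   of `values`.
#' @return a list with `acute_reaction`, `reduction_of_acute_reaction`,
#'   `after_effect` and `adapting`.
#' @export
adaptation_metrics <- function(values, phase, block = 10L,
                               adapt_threshold = 40) {
  if (length(values) != length(phase)) stop("values/phase length mismatch")
  blk <- function(idx) {
    v <- values[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  pre <- which(phase == "pre_adaptation")
  ad <- which(phase == "adaptation")
  post <- which(phase == "post_adaptation")
  if (!length(pre) || !length(ad)) stop("phase labels lack required phases")
  pre_m <- blk(utils::tail(pre, block))
  ad_first <- blk(utils::head(ad, block))
  ad_last <- blk(utils::tail(ad, block))
  post_m <- if (length(post)) blk(utils::head(post, block)) else NA_real_
  red <- ad_last - ad_first
  list(acute_reaction = ad_first - pre_m,
       reduction_of_acute_reaction = red,
       after_effect = post_m - pre_m,
       adapting = !is.na(red) && red <= -adapt_threshold)
}

#' Timepoint-wise condition dependence of bout power
#'
#' Runs a Kruskal-Wallis test across reafference conditions at every
#' timepoint of the bout-power window and flags timepoints significant
#' under Bonferroni correction for the number of tested timepoints
#' (0.05/220 for the standard window).
#'
#' @param profiles bouts x timepoints matrix from [bout_power()].
#' @param condition condition label per bout (row).
#' @param alpha nominal significance level before correction.
#' @return logical vector per timepoint (`NA` where the test is undefined);
#'   attribute `p` holds the raw p-values.
#' @export
timepoint_condition_test <- function(profiles, condition, alpha = 0.05) {
  condition <- as.factor(condition)
  if (nlevels(droplevels(condition)) < 2L)
    stop("need at least two condition groups")
  m <- ncol(profiles)
  p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    v <- profiles[, j]
    ok <- !is.na(v)
    g <- droplevels(condition[ok])
    if (nlevels(g) < 2L || length(unique(v[ok])) < 2L) next
    p[j] <- kruskal.test(v[ok], g)$p.value
  }
  mask <- p < alpha / m
  attr(mask, "p") <- p
  mask
}

#' Rank-sum comparison of a per-fish metric between two groups
#'
#' Mann-Whitney U test (exact for small untied samples, normal
#' approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]). Degenerate all-tied input yields p = 1 with a
#' warning.
#'
#' @param x,y metric values of the two groups; alternatively pass `x` and a
#'   group factor `g`.
#' @param g optional two-level grouping factor for `x`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return the p-value.
#' @export
group_compare <- function(x, y = NULL, g = NULL,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.null(g)) {
    g <- as.factor(g)
    if (nlevels(droplevels(g)) != 2L) stop("`g` must have two levels")
    y <- x[g == levels(g)[2]]
    x <- x[g == levels(g)[1]]
  }
  if (!length(x) || !length(y)) stop("both groups need at least one value")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p = 1")
    return(1)
  }
  suppressWarnings(wilcox.test(x, y, alternative = alternative)$p.value)
}
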