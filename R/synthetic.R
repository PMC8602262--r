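#' Configuration of the synthetic-data generators
#'
#' Collects the knobs of the generators in one list. Tail kinematics:
#' bouts are rendered as a 25 Hz carrier oscillation (the larval tail-beat
#' scale) of amplitude `flick_amp` radians under a rectangular envelope
#' (optionally tapered over `env_ramp_s`), so that flick magnitudes
#' comfortably exceed the 0.14 rad detection threshold and flick-corrected
#' bout boundaries coincide with the ground truth. Fluorescence: latent
#' signals are convolved with an exponential indicator kernel
#' (`half_decay`), with additive Gaussian noise and one slow sinusoidal
#' drift so that detrending efficacy is measurable. Volumes: somata-sized
#' flat discs of radius `blob_radius_um` sharing a within-blob time course
#' on a noisy background.
#'
#' @param seed integer seed; all generators are deterministic given it.
#' @param flick_amp tail oscillation amplitude (rad).
#' @param tail_freq tail-beat frequency (Hz).
#' @param tail_noise_sd white sensor noise on the tail trace (rad).
#' @param env_ramp_s amplitude taper at bout edges (s; 0 = rectangular).
#' @param behaver behaver passed to [run_closed_loop_session()].
#' @param noise_sd fluorescence noise SD (a.u., relative to unit signal).
#' @param drift_amp,drift_period_s slow drift amplitude and period.
#' @param half_decay indicator kernel half-decay (s).
#' @param blob_radius_um blob radius (um).
#' @param voxel_size voxel dimensions (um).
#' @param volume_dims `c(nx, ny)` of generated planes.
#' @param volume_frames number of volumes.
#' @param volume_fs volumetric sampling rate (Hz).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = NULL, flick_amp = 0.5, tail_freq = 25,
                         tail_noise_sd = 0, env_ramp_s = 0,
                         behaver = reference_params(), noise_sd = 0.2,
                         drift_amp = 0.5, drift_period_s = 600,
                         half_decay = 1.8, blob_radius_um = 1.8,
                         voxel_size = c(0.6, 0.6, 7),
                         volume_dims = c(48, 48), volume_frames = 120,
                         volume_fs = 1.5) {
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic behavioral session with rendered tail kinematics
#'
#' Runs the closed loop for the given protocol and behaver
#' ([run_closed_loop_session()]), then renders each ground-truth bout as an
#' amplitude-modulated tail oscillation, computes vigor, calibrates the
#' vigor-to-velocity multiplier against the calibration-phase bouts (all
#' bouts, if the protocol has no calibration phase) and derives the online
#' bout flag from the estimated velocity. The ground-truth bout table is
#' kept in the returned recording's `bouts` field.
#'
#' @param protocol an [build_protocol()] object.
#' @param config a [synth_config()].
#' @param dt sampling period (s).
#' @param param_schedule optional per-trial controller-parameter schedule,
#'   passed to [run_closed_loop_session()].
#' @return a [tail_recording()].
#' @export
gen_tail_session <- function(protocol, config = synth_config(), dt = 0.005,
                             param_schedule = NULL) {
  rec <- run_closed_loop_session(protocol, config$behaver,
                                 seed = config$seed, dt = dt,
                                 param_schedule = param_schedule)
  n <- length(rec$est_velocity)
  tail <- render_tail(rec$bouts, n, dt, config)
  if (config$tail_noise_sd > 0)
    tail <- tail + with_seed(
      if (is.null(config$seed)) NULL else config$seed + 1L,
      rnorm(n, 0, config$tail_noise_sd))
  vigor <- compute_vigor(tail, dt = dt)
  gt_flag <- integer(n)
  for (k in seq_len(nrow(rec$bouts)))
    gt_flag[rec$bouts$onset[k]:rec$bouts$offset[k]] <- 1L
  cal <- rec$trial_id %in%
    which(protocol$trials$phase == "calibration")
  mult <- tryCatch(
    if (any(gt_flag == 1L & cal)) calibrate_multiplier(vigor[cal], gt_flag[cal])
    else calibrate_multiplier(vigor, gt_flag),
    error = function(e) {
      warning("velocity calibration failed (", conditionMessage(e),
              "); estimated velocity set to zero", call. = FALSE)
      NA_real_
    })
  est <- if (is.na(mult)) numeric(n) else vigor * mult
  tail_recording(dt = dt, tail_angle = tail, grating_cmd = rec$grating_cmd,
                 grating_shown = rec$grating_shown, vigor = vigor,
                 est_velocity = est,
                 bout_flag = detect_bouts_online(est),
                 trial_id = rec$trial_id, phase = rec$phase,
                 bouts = rec$bouts, multiplier = mult)
}

# Render ground-truth bouts as cosine-carrier oscillations. The carrier
# starts at an extremum at bout onset so the first detectable flick begins
# exactly at the ground-truth onset.
render_tail <- function(bouts, n, dt, config) {
  tail <- numeric(n)
  if (is.null(bouts) || !nrow(bouts)) return(tail)
  for (k in seq_len(nrow(bouts))) {
    idx <- bouts$onset[k]:bouts$offset[k]
    t_rel <- (idx - bouts$onset[k]) * dt
    env <- rep(1, length(idx))
    if (config$env_ramp_s > 0) {
      r <- config$env_ramp_s
      env <- pmin(1, pmin(t_rel, rev(t_rel)) / r)
    }
    tail[idx] <- tail[idx] +
      config$flick_amp * env * cos(2 * pi * config$tail_freq * t_rel)
  }
  tail
}

#' Generate a synthetic cohort for the long-term adaptation analysis
#'
#' Three groups of synthetic fish: normal-reafference controls (constant
#' controller), lag-trained adapting fish (the controller's parameters
#' drift linearly toward an "adapted" set over the 225 ms-lag adaptation
#' phase and stay adapted during post-adaptation, emulating an internal
#' model recalibrating the controller), and lag-trained non-adapting fish
#' (parameters fixed, with blunted velocity-sensor weights). Per-fish
#' parameter jitter provides between-animal variability. By construction
#' the adapting group shows a positive acute reaction, a reduction of at
#' least the 40 ms classification threshold, and a negative after-effect
#' in first-bout duration.
#'
#' @param n_per_group number of fish per group.
#' @param config a [synth_config()]; `config$seed` seeds everything.
#' @param variant protocol variant for the lag-trained groups.
#' @param param_cv lognormal coefficient of variation of the per-fish
#'   parameter jitter.
#' @param adapted_scale named multipliers defining the adapted parameter
#'   set relative to baseline.
#' @param blunt_scale sensor-weight multiplier of the non-adapting group.
#' @param dt sampling period (s).
#' @return a data frame with one row per fish: `fish`, `group`,
#'   `acute_reaction`, `reduction_of_acute_reaction`, `after_effect` (ms)
#'   and `adapting`; the per-trial first-bout durations are attached as
#'   attribute `first_bout_ms` (a fish x trial matrix).
#' @export
gen_adapting_cohort <- function(n_per_group = 20,
                                config = synth_config(seed = 1),
                                variant = "long_term_adaptation",
                                param_cv = 0.02,
                                adapted_scale = c(omega_m = 1.25,
                                                  omega_i = 1.1),
                                blunt_scale = 0.85, dt = 0.005) {
  groups <- c("control", "lag_adapting", "lag_nonadapting")
  base <- config$behaver
  if (!inherits(base, "controller_params"))
    stop("the cohort generator needs a controller behaver")
  out <- list()
  fb_all <- list()
  fish_id <- 0L
  for (g in groups) {
    proto <- build_protocol(variant,
                            if (g == "control") "normal_reafference_control"
                            else "lag_trained")
    ad_trials <- which(proto$trials$phase == "adaptation")
    post_trials <- which(proto$trials$phase == "post_adaptation")
    for (i in seq_len(n_per_group)) {
      fish_id <- fish_id + 1L
      fseed <- (config$seed %||% 0L) * 1000L + fish_id
      p <- with_seed(fseed, jitter_params(base, param_cv))
      if (g == "lag_nonadapting")
        p <- scale_params(p, c(omega_f = blunt_scale, omega_r = blunt_scale))
      schedule <- NULL
      if (g == "lag_adapting") {
        p_adapted <- scale_params(p, adapted_scale)
        schedule <- make_adaptation_schedule(p, p_adapted, ad_trials,
                                             post_trials)
      }
      rec <- run_closed_loop_session(proto, p, seed = fseed, dt = dt,
                                     param_schedule = schedule)
      fb <- first_bout_durations(rec, nrow(proto$trials))
      met <- adaptation_metrics(fb, proto$trials$phase)
      out[[fish_id]] <- data.frame(
        fish = fish_id, group = g,
        acute_reaction = met$acute_reaction,
        reduction_of_acute_reaction = met$reduction_of_acute_reaction,
        after_effect = met$after_effect, adapting = met$adapting)
      fb_all[[fish_id]] <- fb
    }
  }
  res <- do.call(rbind, out)
  attr(res, "first_bout_ms") <- do.call(rbind, fb_all)
  res
}

jitter_params <- function(p, cv) {
  v <- unclass(p)
  v[1:8] <- v[1:8] * exp(rnorm(8, 0, cv))
  do.call(controller_params, as.list(v[1:8]))
}

scale_params <- function(p, scales) {
  v <- unclass(p)
  v[names(scales)] <- v[names(scales)] * scales
  do.call(controller_params, as.list(v[1:8]))
}

# Linear drift from baseline to adapted over the adaptation trials;
# adapted parameters persist through post-adaptation.
make_adaptation_schedule <- function(p0, p1, ad_trials, post_trials) {
  v0 <- unclass(p0)[1:8]
  v1 <- unclass(p1)[1:8]
  function(trial) {
    w <- if (trial %in% ad_trials)
      (match(trial, ad_trials) - 1) / max(1, length(ad_trials) - 1)
    else if (trial %in% post_trials) 1
    else 0
    do.call(controller_params, as.list(v0 * (1 - w) + v1 * w))
  }
}

#' First-bout duration per trial of a session
#'
#' @param rec a [tail_recording()] whose `bouts` table carries ground-truth
#'   or segmented bouts with `onset`, `offset`, `trial`.
#' @param n_trials total trial count.
#' @return numeric vector of first-bout durations (ms), `NA` for trials
#'   without bouts.
#' @export
first_bout_durations <- function(rec, n_trials) {
  fb <- rep(NA_real_, n_trials)
  b <- rec$bouts
  if (is.null(b) || !nrow(b)) return(fb)
  dur <- if (!is.null(b$duration_ms)) b$duration_ms else
    (b$offset - b$onset + 1L) * rec$dt * 1000
  first <- !duplicated(b$trial)
  fb[b$trial[first]] <- dur[first]
  fb
}

#' Generate synthetic fluorescence traces for a behavioral session
#'
#' Produces per-ROI fluorescence from latent signals tied to the session:
#' *sensor*/*integrator* ROIs leaky-integrate the forward component of the
#' shown grating velocity with their time constant; *motor* ROIs follow the
#' bout flag; *barcode* ROIs respond to the first bout of each trial with
#' an amplitude that follows a block schedule encoding a target barcode
#' profile; *noise* ROIs carry no signal. Every latent is convolved with
#' the indicator kernel, scaled to unit SD, and corrupted with Gaussian
#' noise of SD `1/snr` plus a slow sinusoidal drift.
#'
#' @param session a [tail_recording()] (e.g. from [gen_tail_session()] or
#'   [run_closed_loop_session()]).
#' @param specs a data frame with columns `type` (one of `"sensor"`,
#'   `"integrator"`, `"motor"`, `"barcode"`, `"noise"`), `tau` (s, for
#'   sensor/integrator), `profile` (4-char over `+0-`, for barcode) and
#'   optionally `snr` (signal SD / noise SD; default from `config`).
#' @param fs imaging frame rate (Hz).
#' @param config a [synth_config()].
#' @param barcode_delta amplitude step per barcode symbol, as a fraction of
#'   the baseline response.
#' @return a list: `traces` (ROI x frame matrix), `fs`, `time_s`,
#'   `grating_onsets_s`, `bout_onsets_s`, `first_bout_onsets_s`,
#'   `trial_of_frame`, `phase` (per trial), `responses` are left to the
#'   analysis; `truth` echoes the specs.
#' @export
gen_fluorescence <- function(session, specs, fs = 5,
                             config = synth_config(), barcode_delta = 0.6) {
  dt <- session$dt
  n <- length(session$grating_shown)
  frame_idx <- seq(1L, n, by = max(1L, round(1 / (fs * dt))))
  fs_eff <- 1 / (dt * max(1L, round(1 / (fs * dt))))
  time_s <- (frame_idx - 1L) * dt
  stim <- pmax(session$grating_shown[frame_idx], 0)
  bflag <- session$bout_flag[frame_idx]
  b <- session$bouts
  first <- b[!duplicated(b$trial), , drop = FALSE]
  first_onsets_s <- (first$onset - 1L) * dt
  trial_starts <- vapply(seq_len(max(session$trial_id)), function(k)
    which(session$trial_id == k)[1], integer(1))
  # grating onset = start of forward motion within each trial
  grating_onsets_s <- vapply(seq_along(trial_starts), function(k) {
    i <- which(session$trial_id == k & session$grating_cmd > 0)[1]
    (i - 1L) * dt
  }, numeric(1))
  bout_onsets_s <- (b$onset - 1L) * dt
  phase <- session$phase
  n_roi <- nrow(specs)
  traces <- matrix(NA_real_, n_roi, length(frame_idx))
  # Step schedule: early/late halves of the adaptation and post phases sit
  # at the block levels implied by the barcode symbols, so the
  # block-difference criteria are clean regardless of phase length.
  amp_schedule <- function(profile) {
    sym <- strsplit(profile, "")[[1]]
    step <- c("+" = barcode_delta, "0" = 0, "-" = -barcode_delta)[sym]
    lv <- cumsum(c(1, step)) # pre, ad1, ad2, post1, post2 block levels
    amp <- numeric(length(phase))
    half <- function(idx, a, b) {
      k <- match(seq_along(phase), idx)
      ifelse(!is.na(k) & k <= length(idx) / 2, a,
             ifelse(!is.na(k), b, NA))
    }
    ad <- half(which(phase == "adaptation"), lv[2], lv[3])
    po <- half(which(phase == "post_adaptation"), lv[4], lv[5])
    amp <- ifelse(phase %in% c("calibration", "pre_adaptation"), lv[1],
                  ifelse(phase == "adaptation", ad, po))
    amp
  }
  with_seed(config$seed, {
    for (r in seq_len(n_roi)) {
      type <- specs$type[r]
      snr <- if (!is.null(specs$snr)) specs$snr[r] else 1 / config$noise_sd
      latent <- switch(type,
        sensor = ,
        integrator = leaky_integrate(stim, specs$tau[r], fs_eff),
        motor = as.numeric(bflag),
        barcode = {
          amp <- amp_schedule(specs$profile[r])
          x <- numeric(length(frame_idx))
          fr <- pmin(length(frame_idx),
                     floor(first_onsets_s * fs_eff) + 1L)
          x[fr] <- amp[first$trial]
          x
        },
        noise = numeric(length(frame_idx)),
        stop("unknown ROI type: ", type))
      sig <- indicator_convolve(latent, fs_eff, config$half_decay)
      s <- sd(sig)
      if (s > 0) sig <- sig / s
      noise_sd <- if (type == "noise") 1 else 1 / snr
      drift <- config$drift_amp *
        sin(2 * pi * time_s / config$drift_period_s + runif(1, 0, 2 * pi))
      traces[r, ] <- sig + rnorm(length(frame_idx), 0, noise_sd) + drift
    }
  })
  list(traces = traces, fs = fs_eff, time_s = time_s,
       grating_onsets_s = grating_onsets_s, bout_onsets_s = bout_onsets_s,
       first_bout_onsets_s = first_onsets_s,
       first_bout_trial = first$trial, phase = phase, truth = specs)
}

#' Generate a synthetic volumetric movie with planted blobs
#'
#' Plants `n_blobs` somata-sized flat discs (radius `config$blob_radius_um`)
#' at random non-overlapping positions in each plane. All voxels of a blob
#' share one latent time course (smoothed noise convolved with the
#' indicator kernel, unit SD) scaled by `snr`; the background and the
#' additive voxel noise are unit-SD white noise. Ground-truth masks are
#' returned alongside.
#'
#' @param n_blobs number of blobs.
#' @param config a [synth_config()].
#' @param snr blob signal SD over voxel noise SD.
#' @param min_sep_um minimal centre-to-centre separation (um).
#' @return list with `movie` (`[x, y, z, t]`), `masks` (list of `[x, y]`
#'   matrices), `centers`, `voxel_size`, `truth` data frame.
#' @export
gen_volume <- function(n_blobs, config = synth_config(seed = 1), snr = 5,
                       min_sep_um = 6) {
  nx <- config$volume_dims[1]; ny <- config$volume_dims[2]
  nt <- config$volume_frames
  vx <- config$voxel_size[1]; vy <- config$voxel_size[2]
  r_vox <- config$blob_radius_um / vx
  with_seed(config$seed, {
    centers <- matrix(numeric(), 0, 2)
    guard <- 0L
    while (nrow(centers) < n_blobs) {
      guard <- guard + 1L
      if (guard > 5000L)
        stop("could not place blobs without overlap; field too crowded")
      cand <- c(runif(1, r_vox + 2, nx - r_vox - 1),
                runif(1, r_vox + 2, ny - r_vox - 1))
      if (nrow(centers) == 0 ||
          all(sqrt(colSums((t(centers) - cand)^2)) * vx >= min_sep_um))
        centers <- rbind(centers, cand)
    }
    movie <- array(rnorm(nx * ny * nt), c(nx, ny, 1, nt))
    masks <- list()
    for (k in seq_len(nrow(centers))) {
      latent <- indicator_convolve(rnorm(nt), config$volume_fs,
                                   config$half_decay)
      latent <- latent / sd(latent)
      gx <- outer(seq_len(nx) - centers[k, 1], rep(1, ny))
      gy <- outer(rep(1, nx), seq_len(ny) - centers[k, 2])
      inside <- which(gx^2 + gy^2 <= r_vox^2, arr.ind = TRUE)
      for (j in seq_len(nrow(inside)))
        movie[inside[j, 1], inside[j, 2], 1, ] <-
          movie[inside[j, 1], inside[j, 2], 1, ] + snr * latent
      masks[[k]] <- inside
    }
    areas <- vapply(masks, nrow, 1L) * vx * vy
    list(movie = movie, masks = masks, centers = centers,
         voxel_size = config$voxel_size,
         truth = data.frame(blob = seq_len(n_blobs), area_um2 = areas))
  })
}
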