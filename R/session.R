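#' Run a full closed-loop session
#'
#' Plays an experimental protocol against a behaver: per trial, the behaver
#' produces swim velocity in response to the shown grating, bouts are
#' detected, each bout is assigned a reafference condition according to the
#' protocol's per-phase policy (drawn from a seeded RNG for the random
#' policies), and the reafference transforms the behaver's velocity into
#' the shown grating for subsequent samples.
#'
#' Behavers:
#' \describe{
#'   \item{[controller_params()]}{the feedback-controller model, stepped by
#'     the compiled closed-loop core (fast path). State is reset at each
#'     trial start, with the sensory delay buffer primed with the static
#'     grating command.}
#'   \item{a function `f(u, t)`}{called once per sample with the shown
#'     grating velocity of the previous sample and the sample index,
#'     returning the current swim velocity (mm/s, >= 0). Samples with
#'     velocity above 2 mm/s count as in-bout. Slow but fully general.}
#'   \item{a data frame}{a scripted bout schedule with columns `onset_s`,
#'     `offset_s` (session time) and optionally `velocity` (default
#'     20 mm/s); the behaver ignores its visual input.}
#' }
#'
#' @param protocol an [build_protocol()] object.
#' @param behaver see Details.
#' @param seed integer; seeds the per-bout condition draws (and is the only
#'   source of randomness — the session is bit-reproducible given `seed`
#'   and the behaver).
#' @param dt sampling period (s).
#' @param param_schedule optional per-trial controller parameters for the
#'   controller behaver: a function `f(trial)` returning a
#'   [controller_params()] object (used by the synthetic adapting-fish
#'   generator to emulate a slowly recalibrating controller).
#' @return a [tail_recording()] with binary-velocity channels
#'   (`est_velocity` is the behaver's velocity; `tail_angle` is zero — use
#'   [gen_tail_session()] for rendered kinematics) and a `bouts` table with
#'   per-bout condition labels.
#' @export
run_closed_loop_session <- function(protocol, behaver = reference_params(),
                                    seed = NULL, dt = 0.005,
                                    param_schedule = NULL) {
  pc <- protocol_command(protocol, dt)
  uconds <- enumerate_conditions(dt)
  with_seed(seed, {
    if (inherits(behaver, "controller_params"))
      session_controller(protocol, behaver, pc, uconds, dt, param_schedule)
    else if (is.data.frame(behaver))
      session_scripted(protocol, behaver, pc, uconds, dt)
    else if (is.function(behaver))
      session_callback(protocol, behaver, pc, uconds, dt)
    else stop("unsupported behaver")
  })
}

session_controller <- function(protocol, params, pc, uconds, dt,
                               param_schedule = NULL) {
  p <- as_param_vector(params)
  n <- length(pc$cmd)
  vel <- numeric(n); shown <- pc$cmd; bflag <- integer(n)
  bouts <- list()
  seg <- round(0.075 / dt)
  labs <- condition_labels(uconds)
  enc <- encode_conditions(uconds, dt)
  for (k in seq_len(nrow(protocol$trials))) {
    idx <- which(pc$trial_id == k)
    ci <- draw_bout_conditions(protocol$trials$policy[k], 200L, labs)
    pk <- if (is.null(param_schedule)) p else
      as_param_vector(param_schedule(k))
    res <- sim_trial_cpp(pk, pc$cmd[idx], dt, enc[ci, , drop = FALSE], seg)
    vel[idx] <- res$vel
    shown[idx] <- res$shown
    bflag[idx] <- res$b
    if (length(res$onset))
      bouts[[k]] <- data.frame(onset = idx[1] + res$onset,
                               offset = idx[1] + res$offset,
                               trial = k,
                               condition = labs[ci][
                                 pmin(res$cond_index + 1L, length(ci))])
  }
  finish_session(protocol, pc, dt, vel, shown, bflag, bouts)
}

session_scripted <- function(protocol, schedule, pc, uconds, dt) {
  n <- length(pc$cmd)
  vel <- numeric(n)
  v0 <- if (is.null(schedule$velocity)) rep(20, nrow(schedule)) else schedule$velocity
  for (k in seq_len(nrow(schedule))) {
    i0 <- round(schedule$onset_s[k] / dt) + 1L
    i1 <- round(schedule$offset_s[k] / dt)
    if (i0 <= n && i1 >= i0) vel[i0:min(i1, n)] <- v0[k]
  }
  if (any(!is.finite(vel))) stop("behaver emitted non-finite velocity")
  bflag <- as.integer(vel > 0)
  runs <- flag_runs(bflag)
  labs <- condition_labels(uconds)
  # assign a condition per bout, respecting the trial the bout starts in
  labels <- character(nrow(runs))
  shown <- pc$cmd
  if (nrow(runs)) for (k in seq_len(nrow(runs))) {
    tr <- pc$trial_id[runs$onset[k]]
    pol <- if (tr >= 1) protocol$trials$policy[tr] else "normal"
    ci <- draw_bout_conditions(pol, 1L, labs)[1]
    labels[k] <- labs[ci]
    mask <- integer(length(bflag))
    mask[runs$onset[k]:runs$offset[k]] <- 1L
    shown <- shown - (pc$cmd - apply_reafference(vel * mask, mask,
                                                 uconds[[ci]],
                                                 pc$cmd, dt))
  }
  bouts <- if (nrow(runs))
    list(data.frame(onset = runs$onset, offset = runs$offset,
                    trial = pc$trial_id[runs$onset], condition = labels))
  finish_session(protocol, pc, dt, vel, shown, bflag, bouts)
}

session_callback <- function(protocol, behaver, pc, uconds, dt) {
  n <- length(pc$cmd)
  vel <- numeric(n); shown <- pc$cmd; bflag <- integer(n)
  reaff <- numeric(n); src <- integer(n)
  seg <- round(0.075 / dt)
  labs <- condition_labels(uconds)
  cur <- NULL; nb <- 0L; onset <- 0L
  bouts <- list()
  prev_shown <- pc$cmd[1]
  b_prev <- 0L
  for (t in seq_len(n)) {
    v <- behaver(prev_shown, t)
    if (!is.finite(v)) stop("behaver emitted non-finite velocity")
    vel[t] <- v
    b <- as.integer(v > 2)
    if (b == 1L && b_prev == 0L) {
      nb <- nb + 1L; onset <- t
      tr <- pc$trial_id[t]
      pol <- if (tr >= 1) protocol$trials$policy[tr] else "normal"
      ci <- draw_bout_conditions(pol, 1L, labs)[1]
      cur <- uconds[[ci]]
      bouts[[nb]] <- data.frame(onset = t, offset = NA_integer_, trial = tr,
                                condition = labs[ci])
    }
    if (b == 0L && b_prev == 1L) {
      bouts[[nb]]$offset <- t - 1L
      if (cur$kind == "lag" && isTRUE(cur$shunted) && !is.infinite(cur$lag)) {
        l <- round(cur$lag / 1000 / dt)
        jj <- t:min(n, t - 1L + l)
        jj <- jj[src[jj] == nb]
        reaff[jj] <- 0
      }
    }
    if (b == 1L) {
      if (cur$kind == "gain") reaff[t] <- reaff[t] + cur$gain * v
      else if (cur$kind == "lag") {
        if (!is.infinite(cur$lag)) {
          l <- round(cur$lag / 1000 / dt)
          if (t + l <= n) { reaff[t + l] <- reaff[t + l] + v; src[t + l] <- nb }
        }
      } else {
        kseg <- (t - onset) %/% seg
        dig <- as.numeric(strsplit(cur$profile, "")[[1]])
        g <- if (kseg < 4) dig[kseg + 1] else 1
        reaff[t] <- reaff[t] + g * v
      }
    }
    shown[t] <- pc$cmd[t] - reaff[t]
    bflag[t] <- b
    prev_shown <- shown[t]
    b_prev <- b
  }
  if (b_prev == 1L) bouts[[nb]]$offset <- n
  finish_session(protocol, pc, dt, vel, shown, bflag, bouts)
}

finish_session <- function(protocol, pc, dt, vel, shown, bflag, bouts) {
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(onset = integer(), offset = integer(), trial = integer(),
               condition = character())
  tail_recording(dt = dt, tail_angle = numeric(length(vel)),
                 grating_cmd = pc$cmd, grating_shown = shown,
                 est_velocity = vel, bout_flag = bflag,
                 trial_id = pc$trial_id,
                 phase = protocol$trials$phase, bouts = bouts)
}
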