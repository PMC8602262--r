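#' Build an experimental protocol
#'
#' All protocols share one trial structure: 7.5 s of static grating, 15 s of
#' forward grating motion at 10 mm/s, then 7.5 s static (30 s per trial).
#' Trials are grouped into four phases: calibration (10 trials, normal
#' reafference, velocity-multiplier calibration), pre-adaptation (10 trials,
#' normal reafference), adaptation (variant-specific), and post-adaptation
#' (normal reafference).
#'
#' Variants:
#' \describe{
#'   \item{acute_reaction}{10/10/210/10 trials; during adaptation the
#'     reafference condition of every bout is drawn uniformly at random from
#'     the 18 unique conditions.}
#'   \item{long_term_adaptation}{10/10/210/10 trials; all adaptation bouts
#'     receive a 225 ms non-shunted lag (`lag_trained` group) or normal
#'     reafference (`normal_reafference_control`).}
#'   \item{pc_imaging}{10/10/50/50 trials; otherwise as long-term
#'     adaptation.}
#'   \item{whole_brain_imaging}{120 s of blank screen, then 10/10/40 trials
#'     with no post-adaptation phase; adaptation bouts are randomly normal
#'     or open-loop, and each static period carries two 350 ms reverse
#'     grating pulses 5 and 10 s after the grating stops.}
#' }
#'
#' @param variant protocol variant, see Details.
#' @param group `"normal_reafference_control"` or `"lag_trained"` (the group
#'   only matters for the long-term adaptation and PC imaging variants).
#' @param seed integer seed for the per-bout condition draws made when the
#'   protocol is run.
#' @return an object of class `omr_protocol` with a `trials` data frame
#'   (columns `trial`, `phase`, `policy`).
#' @examples
#' p <- build_protocol("long_term_adaptation", "lag_trained", seed = 1)
#' nrow(p$trials)  # 240
#' @export
build_protocol <- function(variant = c("acute_reaction",
                                       "long_term_adaptation",
                                       "whole_brain_imaging", "pc_imaging"),
                           group = c("normal_reafference_control",
                                     "lag_trained"),
                           seed = NULL) {
  variant <- match.arg(variant)
  group <- match.arg(group)
  counts <- switch(variant,
    acute_reaction = c(10, 10, 210, 10),
    long_term_adaptation = c(10, 10, 210, 10),
    pc_imaging = c(10, 10, 50, 50),
    whole_brain_imaging = c(10, 10, 40, 0))
  adapt_policy <- switch(variant,
    acute_reaction = "random_18",
    long_term_adaptation = ,
    pc_imaging = if (group == "lag_trained") "lag_225" else "normal",
    whole_brain_imaging = "random_normal_openloop")
  phase <- rep(c("calibration", "pre_adaptation", "adaptation",
                 "post_adaptation"), counts)
  policy <- rep(c("normal", "normal", adapt_policy, "normal"), counts)
  structure(list(
    variant = variant, group = group, seed = seed,
    trials = data.frame(trial = seq_along(phase), phase = phase,
                        policy = policy, stringsAsFactors = FALSE),
    static_s = 7.5, moving_s = 15, base_velocity = 10,
    blank_lead_s = if (variant == "whole_brain_imaging") 120 else 0,
    reverse_pulses = variant == "whole_brain_imaging"),
    class = "omr_protocol")
}

#' @export
print.omr_protocol <- function(x, ...) {
  tab <- table(factor(x$trials$phase, levels = unique(x$trials$phase)))
  cat(sprintf("<protocol: %s / %s, %d trials>\n", x$variant, x$group,
              nrow(x$trials)))
  cat("  phases:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Grating command trace of a protocol
#'
#' Lays the protocol out on a uniform time grid: the optional blank lead-in,
#' then per trial 7.5 s static / 15 s forward at 10 mm/s / 7.5 s static.
#' For the whole-brain variant, two 350 ms reverse pulses (-10 mm/s) are
#' inserted 5 and 10 s after each motion offset (the second pulse falls in
#' the next trial's leading static period).
#'
#' @param protocol an [build_protocol()] object.
#' @param dt sampling period (s).
#' @return a list with `cmd` (mm/s), `trial_id` (0 during the lead-in) and
#'   `phase` per sample.
#' @export
protocol_command <- function(protocol, dt = 0.005) {
  n_static <- round(protocol$static_s / dt)
  n_mov <- round(protocol$moving_s / dt)
  n_trial <- 2L * n_static + n_mov
  n_lead <- round(protocol$blank_lead_s / dt)
  ntr <- nrow(protocol$trials)
  n <- n_lead + ntr * n_trial
  cmd <- numeric(n)
  trial_id <- integer(n)
  phase <- character(n)
  if (n_lead > 0) phase[1:n_lead] <- "blank"
  trial_cmd <- c(rep(0, n_static), rep(protocol$base_velocity, n_mov),
                 rep(0, n_static))
  for (k in seq_len(ntr)) {
    idx <- n_lead + (k - 1L) * n_trial + seq_len(n_trial)
    cmd[idx] <- trial_cmd
    trial_id[idx] <- k
    phase[idx] <- protocol$trials$phase[k]
  }
  if (isTRUE(protocol$reverse_pulses)) {
    n_pulse <- round(0.35 / dt)
    for (k in seq_len(ntr)) {
      stop_i <- n_lead + (k - 1L) * n_trial + n_static + n_mov  # motion offset
      for (delay_s in c(5, 10)) {
        i0 <- stop_i + round(delay_s / dt)
        ii <- i0 + seq_len(n_pulse)
        ii <- ii[ii <= n]
        cmd[ii[cmd[ii] == 0]] <- -protocol$base_velocity
      }
    }
  }
  list(cmd = cmd, trial_id = trial_id, phase = phase, dt = dt)
}

# Draw per-bout reafference condition indices (into the unique set) for one
# trial under a policy. Non-random policies need a single index (the
# closed-loop core reuses the last drawn condition for further bouts).
draw_bout_conditions <- function(policy, n, labs) {
  switch(policy,
    normal = which(labs == "normal"),
    lag_225 = which(labs == "lag_225"),
    random_18 = sample.int(length(labs), n, replace = TRUE),
    random_normal_openloop =
      sample(which(labs %in% c("normal", "open_loop")), n, replace = TRUE),
    stop("unknown condition policy: ", policy))
}
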