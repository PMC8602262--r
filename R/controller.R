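#' Parameters of the delayed feedback controller
#'
#' The controller senses the shown grating velocity after a fixed 220 ms
#' sensory processing delay, splits it into forward and reverse components
#' by rectification with weights `omega_f` and `omega_r` (per mm/s), and
#' accumulates the recombined drive in a leaky velocity integrator with
#' time constant `tau_s` whose output — the sensory drive V, clipped to
#' \[0, 1\] — feeds the motor output generator. The motor drive
#' `D = max(0, V + omega_s * b - omega_i * M)` triggers a bout (`b = 1`,
#' output velocity 20 mm/s) whenever it reaches the threshold `thr`;
#' `omega_s` is a self-excitation loop keeping bouts alive once started.
#' A leaky motor integrator (time constant `tau_m`, input weight `omega_m`,
#' output M, "tiredness", clipped at 1) integrates the motor command and
#' inhibits the motor output with weight `omega_i`, guaranteeing finite
#' bouts even under sustained sensory drive.
#'
#' Eight parameters are free; the sensory delay (220 ms) and the output
#' magnitude (20 mm/s) are fixed.
#'
#' @param omega_f,omega_r forward/reverse velocity-sensor weights (per mm/s).
#' @param tau_s sensory (velocity) integrator time constant (s).
#' @param thr motor-command threshold (dimensionless).
#' @param omega_s self-excitation weight of the command generator.
#' @param omega_m input weight of the motor integrator.
#' @param tau_m motor integrator time constant (s).
#' @param omega_i inhibition weight of tiredness onto the motor output.
#' @param delta_t sensory processing delay (s, fixed).
#' @param swim_speed output velocity while swimming (mm/s, fixed).
#' @return a named numeric vector of class `controller_params`.
#' @seealso [reference_params()] for the package's reference set,
#'   [simulate_controller()], [run_model_trial()], [fit_controller()].
#' @export
controller_params <- function(omega_f, omega_r, tau_s, thr, omega_s,
                              omega_m, tau_m, omega_i,
                              delta_t = 0.22, swim_speed = 20) {
  p <- c(omega_f = omega_f, omega_r = omega_r, tau_s = tau_s, thr = thr,
         omega_s = omega_s, omega_m = omega_m, tau_m = tau_m,
         omega_i = omega_i, delta_t = delta_t, swim_speed = swim_speed)
  if (any(!is.finite(p))) stop("controller parameters must be finite")
  if (any(p[c("omega_f", "omega_r", "tau_s", "thr", "omega_s", "omega_m",
              "tau_m", "omega_i")] <= 0))
    stop("all weights, time constants and the threshold must be > 0")
  structure(p, class = "controller_params")
}

#' @export
print.controller_params <- function(x, ...) {
  cat("<controller parameters>\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Reference controller parameter set
#'
#' A parameter set producing bouts and interbouts of realistic duration
#' under normal reafference and reproducing the qualitative acute-reaction
#' pattern across the full condition battery (see the methods vignette for
#' how it was obtained and validated). Used as the default behaver of the
#' synthetic session generators and as the ground truth of the
#' behavior-recovery tests.
#'
#' @return a [controller_params()] object.
#' @export
reference_params <- function() {
  controller_params(omega_f = 0.19, omega_r = 0.058, tau_s = 1.65,
                    thr = 0.40, omega_s = 0.66, omega_m = 0.90,
                    tau_m = 0.95, omega_i = 2.5)
}

as_param_vector <- function(params) {
  if (!inherits(params, "controller_params"))
    stop("`params` must be a controller_params object")
  as.numeric(params)
}

#' Simulate the controller on a grating command trace
#'
#' Runs the closed loop: the controller sees the shown grating velocity
#' (command minus reafference) after the sensory delay and emits a binary
#' swim velocity; the reafference applied to its output follows `cond`.
#' The model is deterministic; `seed` is accepted only for interface
#' symmetry with stochastic behavers.
#'
#' @param params a [controller_params()] object.
#' @param grating_cmd commanded grating velocity per sample (mm/s), or
#'   `NULL` to use one standard trial (7.5 s static, 15 s at 10 mm/s,
#'   7.5 s static).
#' @param cond the reafference condition applied to every bout (a
#'   [reaff_condition()]), or a list of conditions consumed per bout in
#'   order (the last is reused once exhausted).
#' @param dt simulation step (s).
#' @param state0 optional starting state `c(V, M)`.
#' @param seed ignored (the model is noise-free).
#' @return an object of class `omr_sim`: per-sample `V` (sensory drive),
#'   `M` (tiredness), `D` (motor drive), `b` (bout flag), `vel` (output
#'   velocity), `shown` (shown grating), plus a `bouts` data frame.
#' @examples
#' sim <- simulate_controller(reference_params(), cond = reaff_normal())
#' nrow(sim$bouts)
#' @export
simulate_controller <- function(params, grating_cmd = NULL,
                                cond = reaff_normal(), dt = 0.005,
                                state0 = c(0, 0), seed = NULL) {
  p <- as_param_vector(params)
  if (is.null(grating_cmd))
    grating_cmd <- c(rep(0, round(7.5 / dt)), rep(10, round(15 / dt)),
                     rep(0, round(7.5 / dt)))
  if (any(!is.finite(grating_cmd))) stop("grating command must be finite")
  conds <- if (inherits(cond, "reaff_condition")) list(cond) else cond
  mat <- encode_conditions(conds, dt)
  res <- sim_trial_cpp(p, as.numeric(grating_cmd), dt, mat,
                       round(0.075 / dt), state0[1], state0[2])
  labs <- vapply(conds, condition_label, character(1))
  ci <- res$cond_index + 1L
  bouts <- data.frame(onset = res$onset + 1L, offset = res$offset + 1L,
                      condition = labs[pmin(ci, length(labs))])
  bouts$duration_ms <- (bouts$offset - bouts$onset + 1L) * dt * 1000
  structure(list(dt = dt, V = res$V, M = res$M, D = res$D, b = res$b,
                 vel = res$vel, shown = res$shown, cmd = grating_cmd,
                 bout_id = res$bout_id, bouts = bouts, params = params),
            class = "omr_sim")
}

#' @export
print.omr_sim <- function(x, ...) {
  cat(sprintf("<controller simulation: %.1f s, %d bouts>\n",
              length(x$b) * x$dt, nrow(x$bouts)))
  invisible(x)
}

#' Single model test trial
#'
#' The short protocol used to characterize the model's acute reaction:
#' 300 ms of static grating followed by 9.7 s of forward motion at 10 mm/s.
#' The first bout receives normal reafference and the second the probed
#' condition. If a third bout starts within the trial, the duration of the
#' second bout and of the subsequent interbout are returned; otherwise the
#' trial produces no output (`NULL`).
#'
#' @param params a [controller_params()] object.
#' @param cond2 reafference condition of the second bout.
#' @param dt simulation step (s).
#' @param seed ignored (deterministic).
#' @return `list(bout_ms, interbout_ms)` or `NULL`.
#' @export
run_model_trial <- function(params, cond2 = reaff_normal(), dt = 0.005,
                            seed = NULL) {
  tbl <- model_trial_table_cpp(as_param_vector(params),
                               encode_conditions(list(cond2), dt), dt,
                               0.3, 9.7, 10, round(0.075 / dt))
  if (is.na(tbl[1, 1])) return(NULL)
  list(bout_ms = tbl[1, 1], interbout_ms = tbl[1, 2])
}

#' Model duration table over the condition battery
#'
#' Runs [run_model_trial()] for each condition and collects second-bout and
#' second-interbout durations — the model analogue of the per-condition
#' behavioral summary used for fitting.
#'
#' @param params a [controller_params()] object.
#' @param conditions list of conditions (default: the unique 18).
#' @param dt simulation step (s).
#' @return a data frame with columns `condition`, `bout_ms`, `interbout_ms`
#'   (`NA` where the model produced no output).
#' @export
model_duration_table <- function(params, conditions = NULL, dt = 0.005) {
  if (is.null(conditions)) conditions <- enumerate_conditions(dt)
  tbl <- model_trial_table_cpp(as_param_vector(params),
                               encode_conditions(conditions, dt), dt,
                               0.3, 9.7, 10, round(0.075 / dt))
  data.frame(condition = condition_labels(conditions),
             bout_ms = tbl[, 1], interbout_ms = tbl[, 2],
             stringsAsFactors = FALSE)
}

#' Qualitative acute-reaction checks
#'
#' Evaluates the orderings that characterize the acute reaction across the
#' condition battery: longer bouts under open-loop than normal and high
#' gain; longer interbouts at the gain extremes than at gain 1; bout
#' duration non-decreasing in lag; longer interbouts after non-shunted than
#' shunted 300 ms lag; a stronger bout-prolonging effect of early than late
#' gain drops (0111 vs 1110); and a stronger interbout-shortening effect of
#' late than early gain drops (1100 vs 0011).
#'
#' @param tbl a duration table from [model_duration_table()].
#' @return named logical vector of the individual checks.
#' @export
acute_ordering_checks <- function(tbl) {
  g <- function(cond, col) tbl[[col]][match(cond, tbl$condition)]
  lag_bouts <- g(c("normal", "lag_75", "lag_150", "lag_225", "lag_300",
                   "open_loop"), "bout_ms")
  c(bout_gain0_gt_gain1 = g("open_loop", "bout_ms") > g("normal", "bout_ms"),
    bout_gain0_gt_gain2 = g("open_loop", "bout_ms") > g("gain_2", "bout_ms"),
    interbout_gain0_gt_gain1 =
      g("open_loop", "interbout_ms") > g("normal", "interbout_ms"),
    interbout_gain2_gt_gain1 =
      g("gain_2", "interbout_ms") > g("normal", "interbout_ms"),
    bout_monotone_in_lag = !is.unsorted(lag_bouts),
    interbout_lag300_nonshunted_gt_shunted =
      g("lag_300", "interbout_ms") > g("shunted_lag_300", "interbout_ms"),
    bout_0111_gt_1110 =
      g("shunted_lag_75", "bout_ms") > g("gain_drop_1110", "bout_ms"),
    interbout_1100_lt_0011 =
      g("gain_drop_1100", "interbout_ms") < g("shunted_lag_150", "interbout_ms"))
}
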