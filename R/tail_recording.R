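#' Tail recording container
#'
#' The raw record of one closed-loop session: tail angle (cumulative sum of
#' the eight tail-segment angles, radians), the commanded and actually shown
#' grating velocities (mm/s, positive = forward, caudal-to-rostral), vigor
#' (sliding SD of the tail trace, radians), estimated forward velocity
#' (mm/s) and the online bout flag, all on one uniform time grid, together
#' with per-trial and per-bout annotations.
#'
#' @param dt sampling period in seconds.
#' @param tail_angle,grating_cmd,grating_shown,vigor,est_velocity,bout_flag
#'   numeric series of one common length (vigor/est_velocity may be `NA`
#'   when not yet computed).
#' @param trial_id integer trial index per sample (0 = outside trials).
#' @param phase character phase label per trial (see [build_protocol()]),
#'   or `NULL`.
#' @param bouts data frame of ground-truth or online bouts with columns
#'   `onset`, `offset` (sample indices) and `condition` (label), or `NULL`.
#' @param multiplier vigor-to-velocity multiplier (mm/s per radian), or `NA`.
#' @return an object of class `tail_recording`.
#' @export
tail_recording <- function(dt, tail_angle, grating_cmd,
                           grating_shown = grating_cmd,
                           vigor = NA_real_, est_velocity = NA_real_,
                           bout_flag = NULL, trial_id = NULL, phase = NULL,
                           bouts = NULL, multiplier = NA_real_) {
  stopifnot_scalar(dt, "dt")
  if (dt <= 0) stop("sampling period must be > 0")
  n <- length(tail_angle)
  rec <- structure(list(
    dt = dt,
    tail_angle = as.numeric(tail_angle),
    grating_cmd = rep_len(as.numeric(grating_cmd), n),
    grating_shown = rep_len(as.numeric(grating_shown), n),
    vigor = rep_len(as.numeric(vigor), n),
    est_velocity = rep_len(as.numeric(est_velocity), n),
    bout_flag = rep_len(if (is.null(bout_flag)) 0L else as.integer(bout_flag), n),
    trial_id = rep_len(if (is.null(trial_id)) 0L else as.integer(trial_id), n),
    phase = phase, bouts = bouts, multiplier = multiplier),
    class = "tail_recording")
  validate_tail_recording(rec)
}

validate_tail_recording <- function(rec) {
  n <- length(rec$tail_angle)
  series <- c("grating_cmd", "grating_shown", "vigor", "est_velocity",
              "bout_flag", "trial_id")
  for (s in series)
    if (length(rec[[s]]) != n)
      stop("all series of a tail recording must share one time base")
  if (!all(rec$bout_flag %in% c(0L, 1L)))
    stop("bout_flag must be 0/1")
  ev <- rec$est_velocity[!is.na(rec$est_velocity)]
  if (length(ev) && any(ev < 0)) stop("est_velocity must be >= 0")
  rec
}

#' @export
print.tail_recording <- function(x, ...) {
  n <- length(x$tail_angle)
  cat(sprintf("<tail_recording: %d samples at %.0f Hz (%.1f s)>\n",
              n, 1 / x$dt, n * x$dt))
  cat(sprintf("  trials: %d  bouts: %d  multiplier: %s\n",
              max(x$trial_id), if (is.null(x$bouts)) 0L else nrow(x$bouts),
              format(x$multiplier)))
  invisible(x)
}

#' @export
as.data.frame.tail_recording <- function(x, ...) {
  data.frame(time = (seq_along(x$tail_angle) - 1) * x$dt,
             tail_angle = x$tail_angle, grating_cmd = x$grating_cmd,
             grating_shown = x$grating_shown, vigor = x$vigor,
             est_velocity = x$est_velocity, bout_flag = x$bout_flag,
             trial_id = x$trial_id)
}

#' Read and write tail recordings as flat CSV
#'
#' Series are stored one column per channel; the sampling period and
#' calibration multiplier travel in commented header lines so a recording
#' round-trips losslessly through plain text.
#'
#' @param rec a [tail_recording()].
#' @param path file path.
#' @return `read_tail_recording` returns a [tail_recording()];
#'   `write_tail_recording` returns `path` invisibly.
#' @export
write_tail_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt: %.17g", rec$dt),
               sprintf("# multiplier: %.17g", rec$multiplier)), con)
  write.csv(as.data.frame(rec)[, -1], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tail_recording
#' @export
read_tail_recording <- function(path) {
  hdr <- readLines(path, n = 2L)
  get_num <- function(key) {
    line <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ": *"), "", line))
  }
  df <- read.csv(path, comment.char = "#")
  tail_recording(dt = get_num("dt"), tail_angle = df$tail_angle,
                 grating_cmd = df$grating_cmd,
                 grating_shown = df$grating_shown, vigor = df$vigor,
                 est_velocity = df$est_velocity, bout_flag = df$bout_flag,
                 trial_id = df$trial_id, multiplier = get_num("multiplier"))
}
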