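#' Reafference conditions
#'
#' A reafference condition describes how the estimated swim velocity of a
#' head-restrained larva is transformed into the grating motion it sees while
#' swimming. Three families are used: `gain` (the estimated velocity is
#' scaled by a multiplier before being subtracted from the base grating
#' velocity), `lag` (gain-1 reafference is delayed relative to bout onset;
#' in the *shunted* variant the delayed stream is cut off at bout offset),
#' and `gain_drop` (the first 300 ms of each bout are divided into four
#' 75 ms segments whose gain is given by a 4-digit binary profile; gain is 1
#' beyond 300 ms).
#'
#' Allowed values mirror the experimental battery: gains
#' \{0, 0.33, 0.66, 1, 1.33, 1.66, 2\}, lags \{0, 75, 150, 225, 300, Inf\} ms,
#' profiles \{1111, 0111, 0011, 0001, 0000, 1110, 1100, 1000\}. Several
#' entries induce the same velocity mapping (gain 0 is open-loop, as is
#' infinite lag; profile 0011 equals a 150 ms shunted lag); use
#' [enumerate_conditions()] for the deduplicated set.
#'
#' @param kind one of `"gain"`, `"lag"`, `"gain_drop"`.
#' @param gain loop gain (for `kind = "gain"`).
#' @param lag reafference delay in ms, possibly `Inf` (for `kind = "lag"`).
#' @param shunted logical; cut the delayed stream at bout offset?
#' @param profile 4-character binary string (for `kind = "gain_drop"`).
#' @return an object of class `reaff_condition`.
#' @examples
#' reaff_condition("lag", lag = 225)
#' reaff_condition("gain_drop", profile = "1100")
#' @export
reaff_condition <- function(kind = c("gain", "lag", "gain_drop"),
                            gain = NULL, lag = NULL, shunted = FALSE,
                            profile = NULL) {
  kind <- match.arg(kind)
  gains_ok <- c(0, 0.33, 0.66, 1, 1.33, 1.66, 2)
  lags_ok <- c(0, 75, 150, 225, 300, Inf)
  profiles_ok <- c("1111", "0111", "0011", "0001", "0000",
                   "1110", "1100", "1000")
  cond <- switch(kind,
    gain = {
      if (is.null(gain) || !gain %in% gains_ok)
        stop("`gain` must be one of ", paste(gains_ok, collapse = ", "))
      list(kind = "gain", gain = gain)
    },
    lag = {
      if (is.null(lag) || !lag %in% lags_ok)
        stop("`lag` must be one of ", paste(lags_ok, collapse = ", "), " ms")
      list(kind = "lag", lag = lag, shunted = isTRUE(shunted))
    },
    gain_drop = {
      if (is.null(profile) || !profile %in% profiles_ok)
        stop("`profile` must be one of ", paste(profiles_ok, collapse = ", "))
      list(kind = "gain_drop", profile = profile)
    })
  structure(cond, class = "reaff_condition")
}

#' @export
format.reaff_condition <- function(x, ...) condition_label(x)

#' @export
print.reaff_condition <- function(x, ...) {
  cat("<reafference condition:", condition_label(x), ">\n")
  invisible(x)
}

#' Descriptive label of a reafference condition
#'
#' @param cond a [reaff_condition()].
#' @return a single string such as `"gain_0.66"` or `"shunted_lag_150"`.
#' @export
condition_label <- function(cond) {
  switch(cond$kind,
    gain = paste0("gain_", cond$gain),
    lag = paste0(if (isTRUE(cond$shunted)) "shunted_lag_" else "lag_",
                 cond$lag),
    gain_drop = paste0("gain_drop_", cond$profile))
}

#' Normal-reafference and open-loop conditions
#'
#' Convenience constructors for the two reference points of the condition
#' battery: gain 1 (the calibrated free-swimming equivalent) and gain 0
#' (tail movements have no visual consequence).
#' @return a [reaff_condition()].
#' @export
reaff_normal <- function() reaff_condition("gain", gain = 1)

#' @rdname reaff_normal
#' @export
reaff_open_loop <- function() reaff_condition("gain", gain = 0)

# Numeric encoding consumed by the C++ stepper: kind code, gain,
# lag in samples (-1 = Inf), shunted flag, four profile digits.
encode_condition <- function(cond, dt) {
  out <- c(0, 1, 0, 0, 1, 1, 1, 1)
  if (cond$kind == "gain") {
    out[1] <- 0; out[2] <- cond$gain
  } else if (cond$kind == "lag") {
    out[1] <- 1
    out[3] <- if (is.infinite(cond$lag)) -1 else round(cond$lag / 1000 / dt)
    out[4] <- as.numeric(isTRUE(cond$shunted))
  } else {
    out[1] <- 2
    out[5:8] <- as.numeric(strsplit(cond$profile, "")[[1]])
  }
  out
}

encode_conditions <- function(conds, dt) {
  do.call(rbind, lapply(conds, encode_condition, dt = dt))
}

#' Apply a reafference transformation to an estimated-velocity trace
#'
#' Computes the grating velocity actually shown to the animal: the base
#' (command) velocity minus the reafference stream that the condition
#' derives from the estimated swim velocity. Outside bouts (and wherever a
#' delayed stream has not yet arrived or has been shunted away) the shown
#' velocity equals the base velocity.
#'
#' @param est_velocity estimated forward swim velocity (mm/s), one value per
#'   sample.
#' @param bout_flag 0/1 vector marking in-bout samples, same length.
#' @param cond a [reaff_condition()].
#' @param base_velocity base grating command, a scalar or a vector (mm/s).
#' @param dt sampling period in seconds.
#' @return numeric vector of shown grating velocity (mm/s).
#' @examples
#' v <- c(0, 0, 20, 20, 20, 0, 0)
#' b <- c(0, 0, 1, 1, 1, 0, 0)
#' apply_reafference(v, b, reaff_open_loop())      # stays at base velocity
#' apply_reafference(v, b, reaff_normal())         # 10 - 20 during the bout
#' @export
apply_reafference <- function(est_velocity, bout_flag, cond,
                              base_velocity = 10, dt = 0.005) {
  if (!inherits(cond, "reaff_condition")) stop("`cond` is not a reafference condition")
  n <- length(est_velocity)
  if (length(bout_flag) != n) stop("series must share one time base")
  if (!all(bout_flag %in% c(0, 1))) stop("`bout_flag` must be 0/1")
  vb <- est_velocity * bout_flag
  r <- numeric(n)
  runs <- flag_runs(bout_flag)
  seg <- round(0.075 / dt)
  if (cond$kind == "gain") {
    r <- cond$gain * vb
  } else if (cond$kind == "lag") {
    if (!is.infinite(cond$lag)) {
      l <- round(cond$lag / 1000 / dt)
      if (nrow(runs)) for (k in seq_len(nrow(runs))) {
        on <- runs$onset[k]; off <- runs$offset[k]
        idx <- (on:off) + l
        keep <- idx <= if (isTRUE(cond$shunted)) off else n
        r[idx[keep]] <- r[idx[keep]] + vb[(on:off)[keep]]
      }
    }
  } else {
    dig <- as.numeric(strsplit(cond$profile, "")[[1]])
    if (nrow(runs)) for (k in seq_len(nrow(runs))) {
      on <- runs$onset[k]; off <- runs$offset[k]
      kseg <- ((on:off) - on) %/% seg
      g <- ifelse(kseg < 4, dig[pmin(kseg, 3) + 1], 1)
      r[on:off] <- r[on:off] + g * vb[on:off]
    }
  }
  base_velocity - r
}

# Runs of 1s in a 0/1 flag as onset/offset sample indices (1-based).
flag_runs <- function(flag) {
  r <- rle(as.integer(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(onset = starts[keep], offset = ends[keep])
}

# The redundant condition battery as used on the rig: 7 gains, 6 lags,
# 6 shunted lags, 8 gain-drop profiles.
redundant_conditions <- function() {
  gains <- c(0, 0.33, 0.66, 1, 1.33, 1.66, 2)
  lags <- c(0, 75, 150, 225, 300, Inf)
  profiles <- c("1111", "0111", "0011", "0001", "0000", "1110", "1100", "1000")
  c(lapply(gains, function(g) reaff_condition("gain", gain = g)),
    lapply(lags, function(l) reaff_condition("lag", lag = l)),
    lapply(lags, function(l) reaff_condition("lag", lag = l, shunted = TRUE)),
    lapply(profiles, function(p) reaff_condition("gain_drop", profile = p)))
}

#' Enumerate the unique reafference conditions
#'
#' Builds the redundant battery (7 gains, 6 lags, 6 shunted lags, 8
#' gain-drop profiles) and merges entries that induce identical
#' velocity mappings, established by applying every entry to a probe
#' velocity trace containing a single constant-velocity bout followed by
#' quiescence long enough to expose delayed streams. Gain 0, infinite lag
#' and infinite shunted lag collapse to one open-loop condition; gain 1,
#' lag 0 and profile 1111 collapse to the normal condition; profiles
#' 0111/0011/0001/0000 collapse onto the shunted lags 75/150/225/300 ms.
#'
#' @param dt sampling period (s) of the probe trace.
#' @return a list of 18 `reaff_condition` objects. Each element carries
#'   attributes `label` (canonical name, `"normal"` and `"open_loop"` for the
#'   two reference classes) and `equivalents` (labels of all battery entries
#'   in its equivalence class).
#' @examples
#' length(enumerate_conditions())  # 18
#' @export
enumerate_conditions <- function(dt = 0.005) {
  all_conds <- redundant_conditions()
  # probe: 0.5 s rest, 0.4 s bout at 20 mm/s, 1.6 s rest (covers lag tails)
  n <- round(2.5 / dt)
  b <- numeric(n)
  b[(round(0.5 / dt) + 1):round(0.9 / dt)] <- 1
  v <- 20 * b
  sig <- vapply(all_conds, function(cc)
    paste(round(apply_reafference(v, b, cc, 10, dt), 9), collapse = ","),
    character(1))
  labs <- vapply(all_conds, condition_label, character(1))
  classes <- split(seq_along(all_conds), factor(sig, levels = unique(sig)))
  lapply(unname(classes), function(idx) {
    members <- labs[idx]
    lab <- if ("gain_1" %in% members) "normal"
      else if ("gain_0" %in% members) "open_loop"
      else members[1]
    rep_cond <- all_conds[[idx[1]]]
    attr(rep_cond, "label") <- lab
    attr(rep_cond, "equivalents") <- members
    rep_cond
  })
}

# Canonical labels of the deduplicated battery, in enumeration order.
condition_labels <- function(conds = enumerate_conditions()) {
  vapply(conds, function(x) attr(x, "label") %||% condition_label(x),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
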