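#' Preprocess a fluorescence trace
#'
#' Whole-brain mode: a 4th-order low-pass Butterworth at 0.56 Hz de-noises
#' the trace (0.56 Hz corresponds to the 1.8 s half-decay of GCaMP6s:
#' faster fluorescence oscillations are unlikely to be biological), a
#' second low-pass at 3.3 mHz estimates the slow drifting baseline which is
#' subtracted, and the result is z-scored. Purkinje-cell mode: a 4th-order
#' high-pass at 3.3 mHz removes the drift directly, then z-scoring.
#' Filters are applied forward-backward (zero phase) with odd-reflection
#' padding to suppress edge transients.
#'
#' @param trace fluorescence trace (a.u.).
#' @param fs sampling rate (Hz).
#' @param mode `"whole_brain"` or `"pc"`.
#' @param lp_cutoff,baseline_cutoff cutoffs in Hz.
#' @return the detrended, z-scored trace.
#' @export
preprocess_trace <- function(trace, fs, mode = c("whole_brain", "pc"),
                             lp_cutoff = 0.56, baseline_cutoff = 0.0033) {
  mode <- match.arg(mode)
  if (max(lp_cutoff * (mode == "whole_brain"), baseline_cutoff) >= fs / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  x <- as.numeric(trace)
  if (sd(x) == 0) stop("trace is constant")
  if (mode == "whole_brain") {
    x <- butter_pad(x, lp_cutoff, fs, "low")
    x <- x - butter_pad(x, baseline_cutoff, fs, "low")
  } else {
    x <- butter_pad(x, baseline_cutoff, fs, "high")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("trace is constant after filtering")
  (x - mean(x)) / s
}

# Zero-phase Butterworth with odd-reflection padding (order 4).
butter_pad <- function(x, cutoff, fs, type, order = 4L) {
  W <- cutoff / (fs / 2)
  bf <- signal::butter(order, W, type = type)
  n <- length(x)
  padlen <- min(n - 1L, ceiling(3 / W))
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(padlen + 1L):(padlen + n)]
}

#' Event-triggered traces and their average
#'
#' Selects sections of length `len_s` starting `pre_s` before each trigger.
#' Triggers with another trigger in the preceding second are dropped; if
#' another trigger occurs inside a selected window, samples from that point
#' on are masked (`NaN`) so responses are not contaminated by the following
#' event. The pre-trigger mean within the window is subtracted from each
#' section.
#'
#' @param trace fluorescence trace.
#' @param fs sampling rate (Hz).
#' @param triggers_s trigger times (s, relative to the trace start).
#' @param len_s window length (5 s for grating/bout windows, 2.2 s for the
#'   first-bout windows of the Purkinje-cell analysis).
#' @param pre_s time before the trigger included in the window (s).
#' @param refractory_s minimal trigger-free interval required before an
#'   admissible trigger (s).
#' @return `triggered_traces`: a triggers x samples matrix (attribute
#'   `time_s` gives window time relative to the trigger).
#'   `triggered_average`: list with `mean`, `sem`, `n`, `time_s`.
#' @export
triggered_traces <- function(trace, fs, triggers_s, len_s = 5, pre_s = 1,
                             refractory_s = 1) {
  w <- trigger_windows(length(trace), fs, triggers_s, len_s, pre_s,
                       refractory_s)
  vals <- matrix(trace[w$idx], nrow(w$idx), ncol(w$idx))
  vals[is.na(w$idx)] <- NaN
  base <- rowMeans(vals[, seq_len(w$npre), drop = FALSE], na.rm = TRUE)
  out <- vals - base
  attr(out, "time_s") <- w$time_s
  attr(out, "triggers_s") <- w$triggers_s
  out
}

# Admissible trigger windows as an index matrix (NA where a later trigger
# masks the window or the window leaves the trace).
trigger_windows <- function(n, fs, triggers_s, len_s, pre_s, refractory_s) {
  trg <- sort(triggers_s)
  ok <- vapply(seq_along(trg), function(i)
    !any(trg < trg[i] & trg >= trg[i] - refractory_s), logical(1))
  trg <- trg[ok]
  nwin <- round(len_s * fs)
  npre <- round(pre_s * fs)
  rows <- list(); kept <- numeric()
  for (tt in trg) {
    i0 <- round(tt * fs) + 1L - npre
    if (i0 < 1L || i0 + nwin - 1L > n) next
    idx <- i0:(i0 + nwin - 1L)
    later <- triggers_s[triggers_s > tt & triggers_s < tt + (len_s - pre_s)]
    if (length(later)) {
      j <- round((min(later) - tt) * fs) + npre + 1L
      if (j <= nwin) idx[j:nwin] <- NA_integer_
    }
    rows[[length(rows) + 1L]] <- idx
    kept <- c(kept, tt)
  }
  if (!length(rows)) stop("no admissible triggers")
  list(idx = do.call(rbind, rows), npre = npre,
       time_s = (seq_len(nwin) - 1L - npre) / fs, triggers_s = kept)
}

#' Per-trial first-bout-triggered responses
#'
#' The Purkinje-cell response measure: for each trial's first bout, a 2.2 s
#' window starting 1 s before the bout is selected, baseline-subtracted,
#' and averaged over 0-1.2 s after bout onset. Trials without a first bout
#' (or whose window falls outside the trace) get `NA`.
#'
#' @param trace z-scored fluorescence trace.
#' @param fs sampling rate (Hz).
#' @param first_bout_onsets_s first-bout onset times (s).
#' @param trials trial index of each onset.
#' @param n_trials total trial count.
#' @param len_s,pre_s,resp_win window geometry (s).
#' @return numeric vector of per-trial responses.
#' @export
first_bout_responses <- function(trace, fs, first_bout_onsets_s, trials,
                                 n_trials, len_s = 2.2, pre_s = 1,
                                 resp_win = c(0, 1.2)) {
  resp <- rep(NA_real_, n_trials)
  m <- triggered_traces(trace, fs, first_bout_onsets_s, len_s = len_s,
                        pre_s = pre_s, refractory_s = 0)
  used <- attr(m, "triggers_s")
  win <- attr(m, "time_s") >= resp_win[1] & attr(m, "time_s") <= resp_win[2]
  vals <- rowMeans(m[, win, drop = FALSE], na.rm = TRUE)
  resp[trials[match(used, first_bout_onsets_s)]] <- vals
  resp
}

#' @rdname triggered_traces
#' @export
triggered_average <- function(trace, fs, triggers_s, len_s = 5, pre_s = 1,
                              refractory_s = 1) {
  m <- triggered_traces(trace, fs, triggers_s, len_s, pre_s, refractory_s)
  nn <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sem <- apply(m, 2, function(v) sd(v, na.rm = TRUE)) / sqrt(pmax(nn, 1))
  list(mean = mu, sem = sem, n = nrow(m), time_s = attr(m, "time_s"))
}

#' Sensory and motor scores with a section-shuffle null
#'
#' The sensory score of a trace is the mean of its grating-onset-triggered
#' average over 0-4 s post-onset; the motor score the mean of its
#' bout-onset-triggered average over 0-2 s. Null distributions are built by
#' cutting the trace into 23 s sections, shuffling the sections (which
#' preserves local autocorrelation) and recomputing both scores; a score is
#' significant when it exceeds the 95th percentile of its null. A trace is
#' classified *sensory* if its sensory score is significant, and *motor*
#' only if its motor score is significant while the sensory one is not
#' (most sensory units keep responding during bouts, so a significant
#' motor score alone is not diagnostic).
#'
#' @param trace z-scored fluorescence trace.
#' @param fs sampling rate (Hz).
#' @param grating_onsets_s,bout_onsets_s trigger times (s).
#' @param n_shuffles number of section shuffles.
#' @param section_s section length (s).
#' @param seed RNG seed for the shuffles.
#' @return list with `sensory_score`, `motor_score`, the two null 95th
#'   percentiles, logical `sensory_significant`/`motor_significant` and
#'   `class` (`"sensory"`, `"motor"` or `"unclassified"`).
#' @export
sensory_motor_scores <- function(trace, fs, grating_onsets_s, bout_onsets_s,
                                 n_shuffles = 1000, section_s = 23,
                                 seed = NULL) {
  n <- length(trace)
  sec_len <- round(section_s * fs)
  n_sec <- floor(n / sec_len)
  if (n_sec < 2L) stop("trace too short for section shuffling")
  ws <- trigger_windows(n, fs, grating_onsets_s, 5, 1, 1)
  wm <- trigger_windows(n, fs, bout_onsets_s, 5, 1, 1)
  score <- function(x, w, hi_s) {
    vals <- matrix(x[w$idx], nrow(w$idx), ncol(w$idx))
    base <- rowMeans(vals[, seq_len(w$npre), drop = FALSE], na.rm = TRUE)
    prof <- colMeans(vals - base, na.rm = TRUE)
    mean(prof[w$time_s >= 0 & w$time_s <= hi_s], na.rm = TRUE)
  }
  sens <- score(trace, ws, 4)
  mot <- score(trace, wm, 2)
  null_s <- null_m <- numeric(n_shuffles)
  with_seed(seed, {
    for (k in seq_len(n_shuffles)) {
      perm <- sample.int(n_sec)
      idx <- as.vector(outer(seq_len(sec_len), (perm - 1L) * sec_len, `+`))
      xs <- trace
      xs[seq_len(n_sec * sec_len)] <- trace[idx]
      null_s[k] <- score(xs, ws, 4)
      null_m[k] <- score(xs, wm, 2)
    }
  })
  q_s <- quantile(null_s, 0.95, na.rm = TRUE, names = FALSE)
  q_m <- quantile(null_m, 0.95, na.rm = TRUE, names = FALSE)
  sig_s <- is.finite(sens) && sens > q_s
  sig_m <- is.finite(mot) && mot > q_m
  list(sensory_score = sens, motor_score = mot,
       sensory_null_q95 = q_s, motor_null_q95 = q_m,
       sensory_significant = sig_s, motor_significant = sig_m,
       class = if (sig_s) "sensory" else if (sig_m) "motor" else
         "unclassified")
}

# Leaky integration of a stimulus (exponential-Euler) and causal
# convolution with an exponential indicator kernel of given half-decay.
leaky_integrate <- function(stimulus, tau, fs) {
  a <- exp(-1 / (fs * tau))
  as.numeric(stats::filter((1 - a) * stimulus, a, method = "recursive"))
}

indicator_convolve <- function(x, fs, half_decay = 1.8) {
  a <- exp(-log(2) / (fs * half_decay))
  as.numeric(stats::filter(x, a, method = "recursive"))
}

#' Fit a leaky-integrator time constant to a sensory trace
#'
#' Iterates over a grid of time constants (0.5-10 s in 0.5 s steps),
#' forward-models the fluorescence as the leaky-integrated forward
#' component of the stimulus velocity convolved with a GCaMP6s kernel
#' (exponential, 1.8 s half-decay), and returns the time constant with the
#' highest Pearson correlation to the trace. Traces with a best constant
#' of at most 1.5 s are labelled *sensors*, slower ones *integrators*.
#'
#' @param trace fluorescence trace (any affine scaling; correlation is
#'   scale-invariant).
#' @param stimulus grating velocity series aligned with the trace (mm/s);
#'   negative (reverse) velocities are clipped to zero before integration.
#' @param fs sampling rate (Hz).
#' @param tau_grid candidate time constants (s).
#' @param half_decay indicator kernel half-decay (s).
#' @param sensor_max largest time constant still labelled a sensor (s).
#' @return list with `tau` (s), `class`, `correlations` over the grid.
#' @export
fit_time_constant <- function(trace, stimulus, fs,
                              tau_grid = seq(0.5, 10, by = 0.5),
                              half_decay = 1.8, sensor_max = 1.5) {
  if (length(trace) != length(stimulus))
    stop("trace and stimulus must be aligned")
  if (sd(trace) == 0) stop("constant trace: correlation undefined")
  s <- pmax(stimulus, 0)
  cors <- vapply(tau_grid, function(tau) {
    pred <- indicator_convolve(leaky_integrate(s, tau, fs), fs, half_decay)
    if (sd(pred) == 0) return(NA_real_)
    cor(pred, trace)
  }, numeric(1))
  best <- which.max(cors)
  list(tau = tau_grid[best],
       class = if (tau_grid[best] <= sensor_max) "sensor" else "integrator",
       correlations = setNames(cors, tau_grid))
}

#' Change in sensory time constants across adaptation
#'
#' Per-unit difference between time constants estimated at the end and the
#' beginning of the adaptation phase, a smoothed histogram of the
#' differences (Gaussian kernel, 0.1 s width) and a flag for units whose
#' constant decreased by more than 0.4 s.
#'
#' @param tau_begin,tau_end per-unit time constants (s) for the first and
#'   last block of adaptation trials; units with a missing block are
#'   skipped.
#' @param kernel_width smoothing kernel width (s).
#' @param decrease_threshold flagging threshold (s).
#' @return list with `delta` (s), `flagged` (logical), `flagged_fraction`
#'   and `density`.
#' @export
tau_change <- function(tau_begin, tau_end, kernel_width = 0.1,
                       decrease_threshold = 0.4) {
  ok <- !is.na(tau_begin) & !is.na(tau_end)
  delta <- tau_end[ok] - tau_begin[ok]
  flagged <- delta < -decrease_threshold
  dens <- if (length(delta) > 1L) density(delta, bw = kernel_width)
  list(delta = delta, flagged = flagged,
       flagged_fraction = mean(flagged), density = dens)
}

#' Motor regressor from the bout flag
#'
#' Convolves the binary swim variable with the calcium-indicator impulse
#' response (exponential with 1.8 s half-decay), giving the fluorescence
#' trace an ideal purely motor unit would show.
#'
#' @param bout_flag 0/1 vector per acquisition frame.
#' @param fs acquisition rate (Hz).
#' @param half_decay indicator half-decay (s).
#' @return the regressor trace.
#' @export
motor_regressor <- function(bout_flag, fs, half_decay = 1.8) {
  if (!all(bout_flag %in% c(0, 1))) stop("bout_flag must be binary")
  indicator_convolve(as.numeric(bout_flag), fs, half_decay)
}

# Block index helper used by the protocol-transition criteria: the last
# `block` trials of pre-adaptation, first/last `block` of adaptation,
# first/last `block` of post-adaptation.
criterion_blocks <- function(phase, block = 10L) {
  pre <- which(phase == "pre_adaptation")
  ad <- which(phase == "adaptation")
  post <- which(phase == "post_adaptation")
  if (!length(pre) || !length(ad) || !length(post))
    stop("phase labels must cover pre_adaptation, adaptation and post_adaptation")
  list(pre = utils::tail(pre, block),
       ad1 = utils::head(ad, block), ad2 = utils::tail(ad, block),
       post1 = utils::head(post, block), post2 = utils::tail(post, block))
}

#' Protocol-transition criteria of a trial-resolved response
#'
#' Averages a per-trial response (canonically the mean first-bout-triggered
#' fluorescence 0-1.2 s after bout onset) within blocks of ten trials and
#' takes four differences across the protocol transitions: (1) first ten
#' adaptation trials minus pre-adaptation, (2) last minus first ten
#' adaptation trials, (3) first ten post-adaptation minus last ten
#' adaptation trials, (4) last minus first ten post-adaptation trials.
#' Trials without a response (`NA`) are skipped within blocks.
#'
#' @param responses per-trial response values, ordered by trial.
#' @param phase phase label per trial.
#' @param block block length in trials.
#' @return named numeric vector `c1..c4`.
#' @export
compute_criteria <- function(responses, phase, block = 10L) {
  if (length(responses) != length(phase))
    stop("responses/phase length mismatch")
  bl <- criterion_blocks(phase, block)
  m <- vapply(bl, function(idx) {
    v <- responses[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  c(c1 = m[["ad1"]] - m[["pre"]], c2 = m[["ad2"]] - m[["ad1"]],
    c3 = m[["post1"]] - m[["ad2"]], c4 = m[["post2"]] - m[["post1"]])
}

#' Ternary response barcode from a trial-shuffle null
#'
#' Converts the four protocol-transition criteria of a trace into a
#' 4-character barcode over \{+, 0, -\}. The null distribution assumes the
#' response changes are unrelated to the protocol transitions: trials
#' (excluding the calibration phase) are randomly permuted, and all four
#' criteria are recomputed per permutation. A criterion above the 97.5th
#' percentile of its null becomes `+`, below the 2.5th percentile `-`,
#' otherwise `0`. The decline-and-recovery profile characteristic of an
#' internal-model readout is `0-0+`.
#'
#' @param responses per-trial response values, ordered by trial.
#' @param phase phase label per trial.
#' @param n_shuffles number of trial permutations.
#' @param seed RNG seed.
#' @param probs lower/upper percentile cut points.
#' @param block block length in trials.
#' @return list with `barcode` (string), `symbols`, `criteria`, `lower`,
#'   `upper` (the null cut points).
#' @export
barcode <- function(responses, phase, n_shuffles = 100000, seed = NULL,
                    probs = c(0.025, 0.975), block = 10L) {
  idx <- which(phase != "calibration")
  if (length(idx) < 2L * block) stop("too few non-calibration trials")
  obs <- compute_criteria(responses, phase, block)
  bl <- criterion_blocks(phase, block)
  # all criterion blocks live inside the shuffled (non-calibration) trials,
  # so the null can be computed from block positions within the permutation
  v <- responses[idx]
  pos <- lapply(bl, function(b) match(b, idx))
  if (any(is.na(unlist(pos))))
    stop("criterion blocks must lie outside the calibration phase")
  null <- matrix(NA_real_, n_shuffles, 4)
  with_seed(seed, {
    chunk <- 2000L
    done <- 0L
    while (done < n_shuffles) {
      k <- min(chunk, n_shuffles - done)
      P <- vapply(seq_len(k), function(i) sample.int(length(idx)),
                  integer(length(idx)))
      bm <- lapply(pos, function(pp)
        colMeans(matrix(v[P[pp, , drop = FALSE]], length(pp), k),
                 na.rm = TRUE))
      null[done + seq_len(k), ] <-
        cbind(bm$ad1 - bm$pre, bm$ad2 - bm$ad1, bm$post1 - bm$ad2,
              bm$post2 - bm$post1)
      done <- done + k
    }
  })
  lo <- apply(null, 2, quantile, probs = probs[1], na.rm = TRUE)
  hi <- apply(null, 2, quantile, probs = probs[2], na.rm = TRUE)
  sym <- ifelse(obs > hi, "+", ifelse(obs < lo, "-", "0"))
  sym[is.na(obs)] <- "0"
  list(barcode = paste(sym, collapse = ""), symbols = sym, criteria = obs,
       lower = lo, upper = hi)
}

#' Cluster fractions and group enrichment of response barcodes
#'
#' Computes, within each fish, the fraction of its units assigned to each
#' barcode cluster, then tests each cluster's fractions across experimental
#' groups with a Kruskal-Wallis test. Clusters whose mean fraction reaches
#' `min_frac` in at least one group are marked `reported` (the display
#' floor used for presentation).
#'
#' @param df a data frame with columns `fish`, `group`, `barcode` (one row
#'   per unit).
#' @param min_frac reporting floor on the within-group mean fraction.
#' @param alpha significance level.
#' @return a data frame per cluster: group means, `p`, `significant`,
#'   `reported`.
#' @export
cluster_enrichment <- function(df, min_frac = 0.02, alpha = 0.05) {
  need <- c("fish", "group", "barcode")
  if (!all(need %in% names(df))) stop("`df` must have columns ",
                                      paste(need, collapse = ", "))
  df$group <- as.factor(df$group)
  if (nlevels(droplevels(df$group)) < 2L) stop("need at least 2 groups")
  if (any(tapply(df$fish, df$group, function(x) length(unique(x))) == 0))
    stop("every group needs at least one fish")
  clusters <- sort(unique(df$barcode))
  fish <- unique(df[, c("fish", "group")])
  frac <- sapply(clusters, function(cl)
    vapply(seq_len(nrow(fish)), function(i) {
      sel <- df$fish == fish$fish[i]
      mean(df$barcode[sel] == cl)
    }, numeric(1)))
  frac <- matrix(frac, nrow = nrow(fish),
                 dimnames = list(NULL, clusters))
  res <- lapply(clusters, function(cl) {
    v <- frac[, cl]
    p <- if (length(unique(v)) < 2L) 1 else
      kruskal.test(v, fish$group)$p.value
    gm <- tapply(v, fish$group, mean)
    data.frame(cluster = cl, t(gm), p = p,
               significant = is.finite(p) && p < alpha,
               reported = any(gm >= min_frac), check.names = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
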