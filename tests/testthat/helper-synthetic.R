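# Shrink a protocol to few trials per phase so closed-loop sessions stay
# cheap; phase structure and policies are preserved.
shrink_protocol <- function(protocol, calibration = 2, pre = 2, adaptation = 4,
                            post = 2) {
  tr <- protocol$trials
  pick <- c(head(which(tr$phase == "calibration"), calibration),
            head(which(tr$phase == "pre_adaptation"), pre),
            head(which(tr$phase == "adaptation"), adaptation),
            head(which(tr$phase == "post_adaptation"), post))
  protocol$trials <- tr[pick, ]
  protocol$trials$trial <- seq_len(nrow(protocol$trials))
  protocol
}

# A minimal recording wrapping a bare tail trace on the 5 ms grid, with the
# whole session inside one forward-motion trial.
bare_recording <- function(tail_angle, dt = 0.005, bout_flag = NULL,
                           grating_cmd = 10) {
  tail_recording(dt = dt, tail_angle = tail_angle,
                 grating_cmd = grating_cmd, bout_flag = bout_flag,
                 trial_id = 1L)
}

# Deterministic zigzag trace with prescribed extrema values at prescribed
# sample indices (linear segments in between, flat elsewhere).
zigzag_trace <- function(n, at, values) {
  x <- numeric(n)
  pts <- c(1L, at, n)
  vals <- c(0, values, 0)
  for (i in seq_len(length(pts) - 1L)) {
    seg <- pts[i]:pts[i + 1L]
    x[seg] <- seq(vals[i], vals[i + 1L], length.out = length(seg))
  }
  x
}
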