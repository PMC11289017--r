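# Independent oracles and small constructors shared across tests.

# Build a gaze_stream from bare vectors (defaults: all valid, no confidence).
make_stream <- function(t_ms, x_px, y_px, confidence = NA_real_,
                        validity = TRUE, source = "test", rate_hz = NA_real_,
                        confidence_mode = NA_character_) {
  gaze_stream(data.frame(t_ms = t_ms, x_px = x_px, y_px = y_px,
                         confidence = confidence, validity = validity),
              source = source, nominal_rate_hz = rate_hz,
              confidence_mode = confidence_mode)
}

# Wrap bare samples as a ground-truth object for observe_tracker().
make_truth <- function(t_ms, x_px, y_px, state = "fixation", rate_hz = 500) {
  structure(list(samples = data.frame(t_ms = t_ms, x_px = x_px, y_px = y_px,
                                      state = state),
                 presses = data.frame(trial_id = integer(0),
                                      press_t_ms = numeric(0),
                                      press_dur_ms = numeric(0)),
                 schedule = NULL, rate_hz = rate_hz),
            class = "ground_truth_gaze")
}

# Brute-force dispersion: explicit double loop over all pairs.
brute_dispersion <- function(m) {
  if (nrow(m) < 2) return(0)
  worst <- 0
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      d <- sqrt(sum((m[i, ] - m[j, ])^2))
      if (d > worst) worst <- d
    }
  }
  worst
}

# Exhaustive maximal-window fixation oracle (no slide, no relative-change
# rule): from each scan position, open at the first index whose min_points
# window satisfies the dispersion predicate, extend to the largest window
# still satisfying it (dispersion recomputed from scratch each time), emit,
# and resume after the window. Mirrors the detector's contract on its
# fixation boundaries.
oracle_fixations <- function(t, x, y, valid, threshold, min_points = 3) {
  n <- length(t)
  out <- NULL
  i <- 1L
  while (i + min_points - 1L <= n) {
    win <- i:(i + min_points - 1L)
    if (any(!valid[win])) { i <- win[max(which(!valid[win]))] + 1L; next }
    if (brute_dispersion(cbind(x[win], y[win])) > threshold) { i <- i + 1L; next }
    hi <- i + min_points - 1L
    while (hi + 1L <= n && valid[hi + 1L] &&
           brute_dispersion(cbind(x[i:(hi + 1L)], y[i:(hi + 1L)])) <= threshold) {
      hi <- hi + 1L
    }
    out <- rbind(out, c(start = i, end = hi))
    i <- if (hi + 1L <= n && !valid[hi + 1L]) hi + 2L else hi + 1L
  }
  out
}

# Closed-form correlation of two noisy observers of a shared signal.
attenuated_r <- function(sigma_s, sigma_1, sigma_2) {
  sigma_s^2 / sqrt((sigma_s^2 + sigma_1^2) * (sigma_s^2 + sigma_2^2))
}
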