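#' Stimulus schedules for the test battery
#'
#' A stimulus schedule lists the trials of one battery task: when each trial
#' runs, where its target is, and any per-trial metadata (grid indices, head
#' roll angle, image id). Trials never overlap and are sorted by onset; all
#' target positions lie within the screen.
#'
#' @name stimulus_schedule
#' @keywords internal
NULL

new_schedule <- function(task, trials, paths = NULL) {
  stopifnot(all(diff(trials$onset_ms) > 0),
            all(trials$offset_ms > trials$onset_ms))
  if (nrow(trials) > 1) {
    stopifnot(all(trials$onset_ms[-1] >= trials$offset_ms[-nrow(trials)]))
  }
  structure(list(task = task, trials = trials, paths = paths),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("stimulus_schedule '%s': %d trials, %.1f s\n", x$task,
              nrow(x$trials), max(x$trials$offset_ms) / 1000))
  invisible(x)
}

trial_frame <- function(task, n, onset0_ms, trial_dur_ms, gap_ms) {
  onset <- onset0_ms + (seq_len(n) - 1) * (trial_dur_ms + gap_ms)
  data.frame(trial_id = seq_len(n), task = task, onset_ms = onset,
             offset_ms = onset + trial_dur_ms, target_x_px = NA_real_,
             target_y_px = NA_real_, grid_row = NA_integer_,
             grid_col = NA_integer_, meta = NA_real_,
             press_required = FALSE)
}

#' Generate the fixation-grid ("Large Grid") task
#'
#' Places `rows * cols` targets at equidistant positions on a margin-inset
#' rectangle and presents one per trial in an order randomized by `seed`.
#' Each trial expects a confirmation key press near target offset (the press
#' itself is simulated by [gen_ground_truth_gaze()]).
#'
#' The default 7 x 8 grid yields the 56 targets of the standard battery.
#'
#' @param rows,cols Grid size; both at least 2.
#' @param margin_px Inset from the screen edges, pixels.
#' @param seed Integer seed controlling the trial permutation.
#' @param geom A [screen_geometry()].
#' @param trial_dur_ms,gap_ms Trial duration and inter-trial gap (ms).
#' @return A `stimulus_schedule` with grid row/column indices per trial.
#' @export
gen_large_grid <- function(rows = 7, cols = 8, margin_px = 60, seed = 1,
                           geom = default_screen(), trial_dur_ms = 1500,
                           gap_ms = 500) {
  if (rows < 2 || cols < 2) stop("rows and cols must be >= 2", call. = FALSE)
  if (2 * margin_px >= geom$width_px || 2 * margin_px >= geom$height_px) {
    stop("grid does not fit on screen with this margin", call. = FALSE)
  }
  xs <- margin_px + (seq_len(cols) - 1) * (geom$width_px - 2 * margin_px) / (cols - 1)
  ys <- margin_px + (seq_len(rows) - 1) * (geom$height_px - 2 * margin_px) / (rows - 1)
  grid <- expand.grid(grid_col = seq_len(cols), grid_row = seq_len(rows))
  ord <- with_seed(seed, sample.int(nrow(grid)))
  trials <- trial_frame("large_grid", nrow(grid), 500, trial_dur_ms, gap_ms)
  trials$target_x_px <- xs[grid$grid_col[ord]]
  trials$target_y_px <- ys[grid$grid_row[ord]]
  trials$grid_row <- grid$grid_row[ord]
  trials$grid_col <- grid$grid_col[ord]
  trials$press_required <- TRUE
  new_schedule("large_grid", trials)
}

#' Generate one Brownian-direction smooth-pursuit target path
#'
#' The target moves at constant speed while its direction angle performs a
#' Brownian motion: over a step of `dt_s` seconds the angle changes by a
#' Normal(0, `direction_var_deg2_s * dt_s`) increment (variance in deg^2/s,
#' the battery's standard setting being 887 deg^2/s). The target reflects
#' specularly off the bounding rectangle and never leaves it; samples whose
#' step involved a reflection are flagged so diffusion estimates can exclude
#' them.
#'
#' @param duration_s Path duration, seconds.
#' @param dt_s Time step, seconds (e.g. 1/30 for a 30 Hz display).
#' @param speed_px_s Constant target speed, pixels/second.
#' @param direction_var_deg2_s Diffusion variance of the direction angle,
#'   deg^2 per second.
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)` in pixels.
#' @param seed Integer seed.
#' @param start_px Optional start position (defaults to the bounds centre).
#' @param start_dir_deg Optional initial direction (default drawn uniformly).
#' @return Data frame `t_ms`, `x_px`, `y_px`, `dir_deg`, `reflected`.
#' @seealso [pursuit_direction_variance()]
#' @export
gen_pursuit_target <- function(duration_s, dt_s, speed_px_s,
                               direction_var_deg2_s = 887,
                               bounds = c(0, 1440, 0, 900), seed = 1,
                               start_px = NULL, start_dir_deg = NULL) {
  if (dt_s <= 0 || duration_s < dt_s || speed_px_s <= 0) {
    stop("need dt_s > 0, duration_s >= dt_s, speed_px_s > 0", call. = FALSE)
  }
  n <- floor(duration_s / dt_s)
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  start_px <- start_px %||% c((xmin + xmax) / 2, (ymin + ymax) / 2)
  with_seed(seed, {
    dir0 <- start_dir_deg %||% stats::runif(1, 0, 360)
    eps <- stats::rnorm(n, 0, sqrt(direction_var_deg2_s * dt_s))
    x <- numeric(n + 1); y <- numeric(n + 1); th <- numeric(n + 1)
    refl <- logical(n + 1)
    x[1] <- start_px[1]; y[1] <- start_px[2]; th[1] <- dir0
    step_px <- speed_px_s * dt_s
    for (k in seq_len(n)) {
      theta <- th[k] + eps[k]
      nx <- x[k] + step_px * cos(theta * pi / 180)
      ny <- y[k] + step_px * sin(theta * pi / 180)
      hit <- FALSE
      # specular reflection; repeat in case a corner is clipped
      while (nx < xmin || nx > xmax || ny < ymin || ny > ymax) {
        hit <- TRUE
        if (nx < xmin) { nx <- 2 * xmin - nx; theta <- 180 - theta }
        else if (nx > xmax) { nx <- 2 * xmax - nx; theta <- 180 - theta }
        if (ny < ymin) { ny <- 2 * ymin - ny; theta <- -theta }
        else if (ny > ymax) { ny <- 2 * ymax - ny; theta <- -theta }
      }
      x[k + 1] <- nx; y[k + 1] <- ny; th[k + 1] <- theta; refl[k + 1] <- hit
    }
    data.frame(t_ms = (0:n) * dt_s * 1000, x_px = x, y_px = y, dir_deg = th,
               reflected = refl)
  })
}

#' Estimate the direction-angle diffusion variance of a pursuit path
#'
#' Sample variance of consecutive direction-angle increments divided by the
#' time step, in deg^2/s. Increments whose step involved an edge reflection
#' are excluded (reflections change the angle deterministically).
#'
#' @param path A path from [gen_pursuit_target()].
#' @return Estimated diffusion variance in deg^2 per second.
#' @export
pursuit_direction_variance <- function(path) {
  stopifnot(all(c("t_ms", "dir_deg", "reflected") %in% names(path)))
  dt_s <- stats::median(diff(path$t_ms)) / 1000
  dth <- diff(path$dir_deg)
  keep <- !path$reflected[-1]
  stats::var(dth[keep]) / dt_s
}

#' Generate the smooth-pursuit task schedule
#'
#' Each trial shows one Brownian-direction target path (see
#' [gen_pursuit_target()]); the per-trial speed is drawn uniformly from
#' `speed_range_px_s`.
#'
#' @param n_trials Number of pursuit trials.
#' @param trial_dur_s Duration of each trial, seconds.
#' @param dt_s Path time step, seconds.
#' @param speed_range_px_s Range the constant per-trial speed is drawn from.
#' @param direction_var_deg2_s Direction-angle diffusion variance, deg^2/s.
#' @param margin_px Inset of the bounce rectangle from the screen edges.
#' @inheritParams gen_large_grid
#' @return A `stimulus_schedule` with one path per trial in `$paths`.
#' @export
gen_pursuit_schedule <- function(n_trials = 4, trial_dur_s = 15, dt_s = 1 / 30,
                                 speed_range_px_s = c(100, 400),
                                 direction_var_deg2_s = 887, margin_px = 40,
                                 seed = 1, geom = default_screen(),
                                 gap_ms = 500) {
  trials <- trial_frame("smooth_pursuit", n_trials, 500, trial_dur_s * 1000,
                        gap_ms)
  bounds <- c(margin_px, geom$width_px - margin_px,
              margin_px, geom$height_px - margin_px)
  speeds <- with_seed(seed, stats::runif(n_trials, speed_range_px_s[1],
                                         speed_range_px_s[2]))
  paths <- lapply(seq_len(n_trials), function(i) {
    gen_pursuit_target(trial_dur_s, dt_s, speeds[i], direction_var_deg2_s,
                       bounds, seed = child_seed(seed, i))
  })
  trials$target_x_px <- vapply(paths, function(p) p$x_px[1], 0)
  trials$target_y_px <- vapply(paths, function(p) p$y_px[1], 0)
  trials$meta <- speeds
  new_schedule("smooth_pursuit", trials, paths = paths)
}

#' Generate a head-movement task schedule (roll or yaw)
#'
#' Roll: seven trials with a centred line rotated by -15, -10, -5, 0, 5, 10,
#' 15 degrees in randomized order; gaze stays on the screen centre. Yaw: 15
#' trials, one target per trial on a 3-row x 5-column lattice in randomized
#' order. Every trial ends with a confirmation key press.
#'
#' @param kind `"roll"` or `"yaw"`.
#' @inheritParams gen_large_grid
#' @return A `stimulus_schedule`; roll angles are stored in the `meta` column.
#' @export
gen_head_task <- function(kind = c("roll", "yaw"), seed = 1,
                          geom = default_screen(), trial_dur_ms = 2000,
                          gap_ms = 500) {
  kind <- match.arg(kind)
  if (kind == "roll") {
    angles <- c(-15, -10, -5, 0, 5, 10, 15)
    ord <- with_seed(seed, sample.int(length(angles)))
    trials <- trial_frame("head_roll", length(angles), 500, trial_dur_ms, gap_ms)
    trials$target_x_px <- geom$width_px / 2
    trials$target_y_px <- geom$height_px / 2
    trials$meta <- angles[ord]
    trials$press_required <- TRUE
    new_schedule("head_roll", trials)
  } else {
    rows <- 3; cols <- 5; margin <- 150
    xs <- margin + (seq_len(cols) - 1) * (geom$width_px - 2 * margin) / (cols - 1)
    ys <- margin + (seq_len(rows) - 1) * (geom$height_px - 2 * margin) / (rows - 1)
    grid <- expand.grid(grid_col = seq_len(cols), grid_row = seq_len(rows))
    ord <- with_seed(seed, sample.int(nrow(grid)))
    trials <- trial_frame("head_yaw", nrow(grid), 500, trial_dur_ms, gap_ms)
    trials$target_x_px <- xs[grid$grid_col[ord]]
    trials$target_y_px <- ys[grid$grid_row[ord]]
    trials$grid_row <- grid$grid_row[ord]
    trials$grid_col <- grid$grid_col[ord]
    trials$press_required <- TRUE
    new_schedule("head_yaw", trials)
  }
}

#' Generate the free-viewing task schedule
#'
#' A sequence of natural-image trials (default 18 images of 900 x 720 px,
#' centred, 6 s each). There is no instructed target; simulated viewers
#' produce a small set of fixation clusters per image (see
#' [gen_ground_truth_gaze()]), since only between-tracker correlations are
#' computed downstream.
#'
#' @param n_images Number of image trials.
#' @param image_px Image width and height in pixels.
#' @param duration_ms Presentation time per image.
#' @inheritParams gen_large_grid
#' @return A `stimulus_schedule`.
#' @export
gen_free_view <- function(n_images = 18, image_px = c(900, 720),
                          duration_ms = 6000, seed = 1,
                          geom = default_screen(), gap_ms = 500) {
  trials <- trial_frame("free_view", n_images, 500, duration_ms, gap_ms)
  trials$target_x_px <- geom$width_px / 2
  trials$target_y_px <- geom$height_px / 2
  trials$meta <- seq_len(n_images)
  sched <- new_schedule("free_view", trials)
  sched$image_px <- image_px
  sched
}

#' Parametric tracker observation model
#'
#' Describes how one eye tracker observes a ground-truth scanpath: nominal
#' sampling rate with Gaussian timestamp jitter, processing latency, a fixed
#' clock offset against the reference clock, a systematic accuracy bias and
#' per-sample Gaussian noise (both applied in degree space), random per-sample
#' dropouts, and tracker-side signal-loss episodes. `confidence_mode`
#' controls how loss is reported: `"confidence_column"` keeps lost rows with
#' confidence 0 (webcam-style), `"missing_samples"` drops them from the file
#' (lab-style).
#'
#' @param name Tracker label.
#' @param rate_hz Nominal sampling rate, Hz.
#' @param timing_jitter_sd_ms SD of per-sample timestamp jitter, ms.
#' @param latency_ms Processing latency: the sample reported at time t
#'   reflects gaze at t - latency.
#' @param bias_deg Length-2 systematic offset (x, y), degrees.
#' @param noise_sd_deg Length-2 per-sample noise SD (x, y), degrees.
#' @param dropout_prob Per-sample probability of random loss.
#' @param blink_rate_hz Rate of tracker-side loss episodes, per second.
#' @param blink_dur_range_ms Duration range of those episodes.
#' @param confidence_mode `"confidence_column"` or `"missing_samples"`.
#' @param clock_offset_ms Constant offset added to reported timestamps.
#' @return An object of class `tracker_model`.
#' @seealso [tracker_preset()], [observe_tracker()]
#' @export
tracker_model <- function(name, rate_hz, timing_jitter_sd_ms = 0,
                          latency_ms = 0, bias_deg = c(0, 0),
                          noise_sd_deg = c(0, 0), dropout_prob = 0,
                          blink_rate_hz = 0, blink_dur_range_ms = c(100, 300),
                          confidence_mode = c("confidence_column",
                                              "missing_samples"),
                          clock_offset_ms = 0) {
  confidence_mode <- match.arg(confidence_mode)
  if (rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop("dropout_prob must be in [0, 1]", call. = FALSE)
  }
  if (any(noise_sd_deg < 0) || timing_jitter_sd_ms < 0 || blink_rate_hz < 0) {
    stop("noise SDs, jitter SD and blink rate must be >= 0", call. = FALSE)
  }
  structure(list(name = name, rate_hz = rate_hz,
                 timing_jitter_sd_ms = timing_jitter_sd_ms,
                 latency_ms = latency_ms, bias_deg = rep_len(bias_deg, 2),
                 noise_sd_deg = rep_len(noise_sd_deg, 2),
                 dropout_prob = dropout_prob, blink_rate_hz = blink_rate_hz,
                 blink_dur_range_ms = blink_dur_range_ms,
                 confidence_mode = confidence_mode,
                 clock_offset_ms = clock_offset_ms),
            class = "tracker_model")
}

#' Tracker presets bracketing the two systems under comparison
#'
#' `"lab"`: 500 Hz, bias magnitude 0.5 deg, noise 0.3 deg/axis, loss reported
#' as missing samples. `"webcam"`: 30 Hz, bias magnitude 1.0 deg, noise
#' 0.7 deg/axis, loss reported through a confidence column. These are
#' simulation presets chosen to bracket the magnitudes typical of the two
#' device classes, not measurements of any particular device.
#'
#' @param name `"lab"` or `"webcam"`.
#' @param ... Overrides passed to [tracker_model()] fields.
#' @return A `tracker_model`.
#' @export
tracker_preset <- function(name = c("lab", "webcam"), ...) {
  name <- match.arg(name)
  base <- if (name == "lab") {
    list(name = "lab", rate_hz = 500, timing_jitter_sd_ms = 0.1,
         latency_ms = 2, bias_deg = c(0.3, 0.4), noise_sd_deg = c(0.3, 0.3),
         dropout_prob = 0.002, blink_rate_hz = 0,
         confidence_mode = "missing_samples", clock_offset_ms = 0)
  } else {
    list(name = "webcam", rate_hz = 30, timing_jitter_sd_ms = 1,
         latency_ms = 10, bias_deg = c(0.6, 0.8), noise_sd_deg = c(0.7, 0.7),
         dropout_prob = 0.01, blink_rate_hz = 0,
         confidence_mode = "confidence_column", clock_offset_ms = 0)
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(tracker_model, base)
}

default_oculomotor <- function() {
  list(fixation_tremor_sd_deg = 0.05, saccade_dur_ms = 40,
       pursuit_gain = 0.95, pursuit_lag_ms = 100,
       blink_rate_hz = 0.1, blink_dur_range_ms = c(100, 300),
       press_reaction_mean_ms = 250, press_reaction_sd_ms = 50,
       press_dur_meanlog = log(250), press_dur_sdlog = 0.35,
       free_view_clusters = c(3, 6))
}

#' Simulate the viewer: ground-truth gaze for a stimulus schedule
#'
#' Produces the scanpath of a compliant participant at a fine, regular
#' sampling rate. During fixation-type trials gaze sits on the target plus a
#' small tremor; transitions between targets are constant-duration saccade
#' ramps; pursuit trials follow the target path with a gain and a lag;
#' free-viewing trials visit a few random fixation clusters per image.
#' Blinks are inserted as `state == "blink"` intervals, and each
#' press-requiring trial gets a key press shortly after target offset with a
#' log-normal press duration (so a configurable share of presses exceeds the
#' 500 ms rejection bound used by the offset-fixation rule).
#'
#' @param schedule A `stimulus_schedule`.
#' @param oculomotor Named list of behaviour parameters; unnamed entries fall
#'   back to the documented defaults (tremor SD 0.05 deg, 40 ms saccades,
#'   pursuit gain 0.95, pursuit lag 100 ms, 0.1 Hz blinks of 100-300 ms,
#'   press reaction 250 +/- 50 ms, press duration log-normal with median
#'   250 ms).
#' @param seed Integer seed.
#' @param geom A [screen_geometry()].
#' @param rate_hz Sampling rate of the truth timeline (>= any tracker rate).
#' @return An object of class `ground_truth_gaze`: `$samples` (t_ms, x_px,
#'   y_px, state), `$presses` (trial_id, press_t_ms, press_dur_ms),
#'   `$schedule`, `$rate_hz`.
#' @export
gen_ground_truth_gaze <- function(schedule, oculomotor = list(), seed = 1,
                                  geom = default_screen(), rate_hz = 500) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  oc <- default_oculomotor()
  oc[names(oculomotor)] <- oculomotor
  trials <- schedule$trials
  t_end <- max(trials$offset_ms) + 500
  dt <- 1000 / rate_hz
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  ctr <- c(geom$width_px / 2, geom$height_px / 2)

  with_seed(seed, {
    x <- rep(ctr[1], n); y <- rep(ctr[2], n)
    state <- rep("fixation", n)
    cur <- ctr  # position held between segments

    move_to <- function(t0, target) {
      # saccade ramp from `cur` to `target` over [t0, t0 + saccade_dur]
      idx <- which(t >= t0 & t < t0 + oc$saccade_dur_ms)
      if (length(idx)) {
        w <- (t[idx] - t0) / oc$saccade_dur_ms
        x[idx] <<- cur[1] + w * (target[1] - cur[1])
        y[idx] <<- cur[2] + w * (target[2] - cur[2])
        state[idx] <<- "saccade"
      }
      cur <<- target
    }
    hold <- function(t0, t1, st = "fixation") {
      idx <- which(t >= t0 & t < t1)
      if (length(idx)) {
        x[idx] <<- cur[1]; y[idx] <<- cur[2]; state[idx] <<- st
      }
    }

    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      nxt <- if (i < nrow(trials)) trials$onset_ms[i + 1] else t_end + dt
      if (schedule$task == "smooth_pursuit") {
        path <- schedule$paths[[i]]
        p0 <- c(path$x_px[1], path$y_px[1])
        move_to(tr$onset_ms, p0)
        idx <- which(t >= tr$onset_ms + oc$saccade_dur_ms & t < tr$offset_ms)
        if (length(idx)) {
          tq <- pmax(t[idx] - tr$onset_ms - oc$pursuit_lag_ms, 0)
          px <- stats::approx(path$t_ms, path$x_px, xout = tq, rule = 2)$y
          py <- stats::approx(path$t_ms, path$y_px, xout = tq, rule = 2)$y
          x[idx] <- ctr[1] + oc$pursuit_gain * (px - ctr[1])
          y[idx] <- ctr[2] + oc$pursuit_gain * (py - ctr[2])
          state[idx] <- "pursuit"
          cur <- c(x[max(idx)], y[max(idx)])
        }
        hold(tr$offset_ms, nxt)
      } else if (schedule$task == "free_view") {
        img <- schedule$image_px %||% c(900, 720)
        k <- sample(oc$free_view_clusters[1]:oc$free_view_clusters[2], 1)
        cl <- cbind(stats::runif(k, ctr[1] - img[1] / 2, ctr[1] + img[1] / 2),
                    stats::runif(k, ctr[2] - img[2] / 2, ctr[2] + img[2] / 2))
        cuts <- sort(stats::runif(k - 1, tr$onset_ms, tr$offset_ms))
        seg_t <- c(tr$onset_ms, cuts, tr$offset_ms)
        for (j in seq_len(k)) {
          move_to(seg_t[j], cl[j, ])
          hold(seg_t[j] + oc$saccade_dur_ms, seg_t[j + 1])
        }
        hold(tr$offset_ms, nxt)
      } else {
        target <- c(tr$target_x_px, tr$target_y_px)
        move_to(tr$onset_ms, target)
        hold(tr$onset_ms + oc$saccade_dur_ms, nxt)
      }
    }

    # oculomotor tremor, applied in degree space
    if (oc$fixation_tremor_sd_deg > 0) {
      deg <- px_to_deg(cbind(x, y), geom)
      deg <- deg + matrix(stats::rnorm(2 * n, 0, oc$fixation_tremor_sd_deg),
                          ncol = 2)
      pxy <- deg_to_px(deg, geom)
      x <- pxy[, 1]; y <- pxy[, 2]
    }

    # blinks: Poisson episodes; gaze position is held, state marks the loss
    if (oc$blink_rate_hz > 0) {
      nb <- stats::rpois(1, oc$blink_rate_hz * t_end / 1000)
      if (nb > 0) {
        bs <- stats::runif(nb, 0, t_end)
        bd <- stats::runif(nb, oc$blink_dur_range_ms[1], oc$blink_dur_range_ms[2])
        for (b in seq_len(nb)) {
          state[t >= bs[b] & t < bs[b] + bd[b]] <- "blink"
        }
      }
    }

    press_rows <- trials[trials$press_required, , drop = FALSE]
    presses <- data.frame(trial_id = integer(0), press_t_ms = numeric(0),
                          press_dur_ms = numeric(0))
    if (nrow(press_rows)) {
      rt <- stats::rnorm(nrow(press_rows), oc$press_reaction_mean_ms,
                         oc$press_reaction_sd_ms)
      rt <- pmin(pmax(rt, 100), 450)
      presses <- data.frame(
        trial_id = press_rows$trial_id,
        press_t_ms = press_rows$offset_ms + rt,
        press_dur_ms = stats::rlnorm(nrow(press_rows), oc$press_dur_meanlog,
                                     oc$press_dur_sdlog))
    }

    structure(list(samples = data.frame(t_ms = t, x_px = x, y_px = y,
                                        state = state),
                   presses = presses, schedule = schedule, rate_hz = rate_hz,
                   oculomotor = oc),
              class = "ground_truth_gaze")
  })
}

#' @export
print.ground_truth_gaze <- function(x, ...) {
  cat(sprintf("ground_truth_gaze: %d samples at %g Hz (%s task), %d presses\n",
              nrow(x$samples), x$rate_hz, x$schedule$task, nrow(x$presses)))
  invisible(x)
}

#' Observe a ground-truth scanpath through a tracker model
#'
#' Samples the truth at the model's nominal rate with timestamp jitter, reads
#' gaze at `t - latency_ms`, adds the systematic bias and per-sample Gaussian
#' noise in degree space (then maps back to pixels), shifts reported
#' timestamps by the model's clock offset, and applies loss (truth blinks,
#' random dropouts, tracker-side loss episodes). Depending on
#' `confidence_mode`, lost rows are retained with confidence 0 or removed
#' from the stream.
#'
#' @param truth A `ground_truth_gaze`.
#' @param model A [tracker_model()].
#' @param geom A [screen_geometry()].
#' @param seed Integer seed for the observation noise.
#' @return A [gaze_stream()].
#' @export
observe_tracker <- function(truth, model, geom = default_screen(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth_gaze"),
            inherits(model, "tracker_model"))
  if (model$rate_hz > truth$rate_hz) {
    stop("tracker rate_hz exceeds the truth timeline resolution", call. = FALSE)
  }
  ts <- truth$samples
  with_seed(seed, {
    t_nom <- seq(min(ts$t_ms), max(ts$t_ms), by = 1000 / model$rate_hz)
    if (model$timing_jitter_sd_ms > 0) {
      t_nom <- sort(t_nom + stats::rnorm(length(t_nom), 0,
                                         model$timing_jitter_sd_ms))
      keep <- c(TRUE, diff(t_nom) > 1e-6)
      t_nom <- t_nom[keep]
    }
    t_read <- t_nom - model$latency_ms
    inside <- t_read >= min(ts$t_ms) & t_read <= max(ts$t_ms)
    t_nom <- t_nom[inside]; t_read <- t_read[inside]
    n <- length(t_nom)

    gx <- stats::approx(ts$t_ms, ts$x_px, xout = t_read)$y
    gy <- stats::approx(ts$t_ms, ts$y_px, xout = t_read)$y
    # nearest truth sample decides whether the eye was in a blink
    near <- pmin(pmax(round((t_read - ts$t_ms[1]) / (1000 / truth$rate_hz)) + 1,
                      1), nrow(ts))
    blinked <- ts$state[near] == "blink"

    deg <- px_to_deg(cbind(gx, gy), geom)
    deg[, 1] <- deg[, 1] + model$bias_deg[1] +
      stats::rnorm(n, 0, model$noise_sd_deg[1])
    deg[, 2] <- deg[, 2] + model$bias_deg[2] +
      stats::rnorm(n, 0, model$noise_sd_deg[2])
    pxy <- deg_to_px(deg, geom)

    lost <- blinked | (stats::runif(n) < model$dropout_prob)
    if (model$blink_rate_hz > 0) {
      span_s <- (max(t_nom) - min(t_nom)) / 1000
      nb <- stats::rpois(1, model$blink_rate_hz * span_s)
      if (nb > 0) {
        bs <- stats::runif(nb, min(t_nom), max(t_nom))
        bd <- stats::runif(nb, model$blink_dur_range_ms[1],
                           model$blink_dur_range_ms[2])
        for (b in seq_len(nb)) lost <- lost | (t_nom >= bs[b] & t_nom < bs[b] + bd[b])
      }
    }

    t_rep <- t_nom + model$clock_offset_ms
    if (model$confidence_mode == "confidence_column") {
      df <- data.frame(t_ms = t_rep, x_px = pxy[, 1], y_px = pxy[, 2],
                       confidence = as.numeric(!lost), validity = !lost)
      df$x_px[lost] <- NA_real_
      df$y_px[lost] <- NA_real_
    } else {
      df <- data.frame(t_ms = t_rep[!lost], x_px = pxy[!lost, 1],
                       y_px = pxy[!lost, 2], confidence = NA_real_,
                       validity = TRUE)
    }
    gaze_stream(df, source = model$name, nominal_rate_hz = model$rate_hz,
                confidence_mode = model$confidence_mode)
  })
}
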