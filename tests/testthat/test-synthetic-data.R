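test_that("gen_large_grid lays out distinct equidistant targets deterministically", {
  s <- gen_large_grid(7, 8, 60, seed = 5)
  expect_equal(nrow(s$trials), 56)
  expect_equal(nrow(unique(s$trials[c("target_x_px", "target_y_px")])), 56)
  g <- default_screen()
  expect_true(all(s$trials$target_x_px >= 0 & s$trials$target_x_px <= g$width_px))
  expect_true(all(s$trials$target_y_px >= 0 & s$trials$target_y_px <= g$height_px))

  # degenerate 2 x 2, no margin: the screen corners
  s2 <- gen_large_grid(2, 2, 0, seed = 1)
  expect_setequal(s2$trials$target_x_px, c(0, g$width_px))
  expect_setequal(s2$trials$target_y_px, c(0, g$height_px))

  expect_identical(gen_large_grid(seed = 9)$trials, gen_large_grid(seed = 9)$trials)
  expect_false(identical(gen_large_grid(seed = 9)$trials$target_x_px,
                         gen_large_grid(seed = 10)$trials$target_x_px))

  expect_error(gen_large_grid(margin_px = 800), "fit")
})

test_that("pursuit target diffuses at the configured rate and honours bounds", {
  # zero-diffusion limit: straight horizontal path until the first bounce
  p0 <- gen_pursuit_target(2, 1 / 30, 200, direction_var_deg2_s = 0,
                           bounds = c(0, 1440, 0, 900), seed = 1,
                           start_dir_deg = 0)
  pre <- p0[!cumsum(p0$reflected) > 0, ]
  expect_true(all(abs(diff(pre$y_px)) < 1e-9))
  expect_true(all(diff(pre$x_px) > 0))

  # diffusion recovery over a long path
  p <- gen_pursuit_target(300, 1 / 30, 300, 887, seed = 3)
  expect_equal(pursuit_direction_variance(p), 887, tolerance = 0.08)

  # reflection invariant over many seeds
  for (s in 1:50) {
    q <- gen_pursuit_target(10, 1 / 30, 600, 887, bounds = c(100, 700, 100, 500),
                            seed = s)
    expect_true(all(q$x_px >= 100 & q$x_px <= 700 &
                    q$y_px >= 100 & q$y_px <= 500))
  }
})

test_that("head tasks carry the prescribed angles and grid", {
  roll <- gen_head_task("roll", seed = 2)
  expect_setequal(roll$trials$meta, c(-15, -10, -5, 0, 5, 10, 15))
  yaw <- gen_head_task("yaw", seed = 2)
  expect_equal(nrow(yaw$trials), 15)
  expect_equal(nrow(unique(yaw$trials[c("target_x_px", "target_y_px")])), 15)
  expect_equal(length(unique(yaw$trials$target_x_px)), 5)
  expect_equal(length(unique(yaw$trials$target_y_px)), 3)
  expect_identical(gen_head_task("yaw", seed = 4)$trials,
                   gen_head_task("yaw", seed = 4)$trials)
})

test_that("ground-truth gaze reproduces the schedule in the noiseless limit", {
  sched <- gen_large_grid(3, 3, 200, seed = 6, trial_dur_ms = 600, gap_ms = 300)
  truth <- gen_ground_truth_gaze(
    sched, oculomotor = list(fixation_tremor_sd_deg = 0, blink_rate_hz = 0),
    seed = 7)
  sm <- truth$samples
  for (i in seq_len(nrow(sched$trials))) {
    tr <- sched$trials[i, ]
    idx <- sm$t_ms >= tr$onset_ms + 50 & sm$t_ms < tr$offset_ms
    expect_equal(unique(sm$x_px[idx]), tr$target_x_px)
    expect_equal(unique(sm$y_px[idx]), tr$target_y_px)
    expect_true(all(sm$state[idx] == "fixation"))
  }
  # a saccade separates consecutive distinct targets
  expect_true(any(sm$state == "saccade"))

  # CLT bound on the fixation mean under tremor
  truth2 <- gen_ground_truth_gaze(
    sched, oculomotor = list(fixation_tremor_sd_deg = 0.2, blink_rate_hz = 0),
    seed = 8)
  g <- default_screen()
  sm2 <- truth2$samples
  tr <- sched$trials[1, ]
  idx <- sm2$t_ms >= tr$onset_ms + 50 & sm2$t_ms < tr$offset_ms
  mean_deg <- colMeans(px_to_deg(cbind(sm2$x_px[idx], sm2$y_px[idx]), g))
  target_deg <- px_to_deg(c(tr$target_x_px, tr$target_y_px), g)
  expect_true(all(abs(mean_deg - target_deg) < 3 * 0.2 / sqrt(sum(idx))))
})

test_that("observe_tracker reproduces the configured observation model", {
  sched <- gen_large_grid(3, 3, 200, seed = 1, trial_dur_ms = 800, gap_ms = 200)
  truth <- gen_ground_truth_gaze(
    sched, oculomotor = list(fixation_tremor_sd_deg = 0, blink_rate_hz = 0),
    seed = 2)
  g <- default_screen()

  # identity model: stream equals truth at the nominal sample times
  ident <- tracker_model("ident", rate_hz = 100)
  st <- observe_tracker(truth, ident, g, seed = 3)
  tx <- approx(truth$samples$t_ms, truth$samples$x_px, xout = st$t_ms)$y
  expect_equal(st$x_px, tx, tolerance = 1e-9)
  expect_true(all(st$validity))

  # pure bias: every sample displaced by exactly 1 degree horizontally
  biased <- tracker_model("b", rate_hz = 100, bias_deg = c(1, 0))
  sb <- observe_tracker(truth, biased, g, seed = 3)
  d_obs <- px_to_deg(cbind(sb$x_px, sb$y_px), g)
  d_tru <- px_to_deg(cbind(tx, approx(truth$samples$t_ms, truth$samples$y_px,
                                      xout = sb$t_ms)$y), g)
  expect_equal(d_obs[, 1] - d_tru[, 1], rep(1, nrow(sb)), tolerance = 1e-9)
  expect_equal(d_obs[, 2], d_tru[, 2], tolerance = 1e-9)

  # noise SD recovery over ~1e4 samples (chi-square concentration)
  long <- make_truth(seq(0, 25000, by = 2), 720, 450)
  noisy <- tracker_model("n", rate_hz = 400, noise_sd_deg = c(0.5, 0.25))
  sn <- observe_tracker(long, noisy, g, seed = 4)
  dn <- px_to_deg(cbind(sn$x_px, sn$y_px), g)
  expect_equal(sd(dn[, 1]), 0.5, tolerance = 0.05)
  expect_equal(sd(dn[, 2]), 0.25, tolerance = 0.05)

  # effective rate matches the nominal rate
  expect_equal((nrow(sn) - 1) / diff(range(sn$t_ms)) * 1000, 400,
               tolerance = 0.01)

  expect_error(observe_tracker(truth, tracker_model("fast", rate_hz = 1000), g),
               "resolution")
})

test_that("dropout and confidence modes report loss as configured", {
  long <- make_truth(seq(0, 40000, by = 2), 720, 450)
  g <- default_screen()
  m <- tracker_model("d", rate_hz = 250, dropout_prob = 0.05,
                     confidence_mode = "confidence_column")
  st <- observe_tracker(long, m, g, seed = 9)
  expect_equal(mean(st$confidence == 0) * 100, 5, tolerance = 0.15)
  expect_true(all(is.na(st$x_px[st$confidence == 0])))

  m2 <- tracker_model("d2", rate_hz = 250, dropout_prob = 0.05,
                      confidence_mode = "missing_samples")
  st2 <- observe_tracker(long, m2, g, seed = 9)
  expect_equal(data_loss_fraction(st2), 5, tolerance = 0.8)
})
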