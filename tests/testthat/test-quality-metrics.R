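test_that("fixation accuracy is the planar angular error", {
  expect_equal(fixation_accuracy(c(1, 2), c(1, 2)), 0)
  expect_equal(fixation_accuracy(c(0.3, 0.4), c(0, 0)), 0.5)
  expect_equal(fixation_accuracy(rbind(c(1, 0), c(0, 2)),
                                 rbind(c(0, 0), c(0, 0))), c(1, 2))
})

test_that("eccentricity classification uses the boundary ring", {
  expect_equal(classify_eccentricity(1, 1, 7, 8), "outer")
  expect_equal(classify_eccentricity(4, 5, 7, 8), "inner")
  grid <- expand.grid(r = 1:7, c = 1:8)
  cls <- classify_eccentricity(grid$r, grid$c, 7, 8)
  # counting oracle: rows*cols - (2r + 2c - 4) inner cells
  expect_equal(sum(cls == "inner"), 7 * 8 - (2 * 7 + 2 * 8 - 4))
  expect_equal(sum(cls == "inner"), 30)
  expect_equal(sum(cls == "outer"), 26)
  expect_error(classify_eccentricity(0, 1, 7, 8), "outside")
})

test_that("across-subject precision composes between- and within-subject spread", {
  base <- data.frame(subject = c("a", "b"), tracker = "t", location = "L",
                     cx_deg = c(1, 1), cy_deg = c(2, 2))
  p0 <- precision_across_subjects(base)
  expect_equal(p0$per_location$sd_x, 0)

  two <- data.frame(subject = c("a", "b"), tracker = "t", location = "L",
                    cx_deg = c(-1, 1), cy_deg = c(0, 0))
  expect_equal(precision_across_subjects(two)$per_location$sd_x, sqrt(2))

  # single-contributor locations are excluded, not imputed
  mix <- rbind(two, data.frame(subject = "a", tracker = "t", location = "M",
                               cx_deg = 0, cy_deg = 0))
  pm <- precision_across_subjects(mix)
  expect_equal(pm$excluded$location, "M")
  expect_false("M" %in% pm$per_location$location)

  # variance-composition oracle: subject bias SD beta + centroid noise
  withr::with_seed(61, {
    beta <- 0.5; sig_c <- 0.2; n_subj <- 40
    bias <- rnorm(n_subj, 0, beta)
    df <- do.call(rbind, lapply(1:50, function(loc) {
      data.frame(subject = seq_len(n_subj), tracker = "t",
                 location = paste0("L", loc),
                 cx_deg = bias + rnorm(n_subj, 0, sig_c),
                 cy_deg = bias + rnorm(n_subj, 0, sig_c))
    }))
    ps <- precision_across_subjects(df)$summary
    expect_equal(ps$mean_sd[ps$axis == "x"], sqrt(beta^2 + sig_c^2),
                 tolerance = 0.15)
  })
})

test_that("RMS-S2S matches closed forms and skips invalid spans", {
  expect_equal(rms_s2s(rep(3, 10)), 0)
  expect_equal(rms_s2s(c(0, 1, 0, 1)), 1)
  expect_true(is.na(rms_s2s(c(1))))

  # i.i.d. noise of SD sigma gives sigma * sqrt(2)
  withr::with_seed(71, {
    x <- rnorm(20000, 0, 0.7)
    expect_equal(rms_s2s(x), 0.7 * sqrt(2), tolerance = 0.02)
  })

  # pairs spanning an invalid sample are excluded
  v <- c(0, 100, 0.5)
  expect_equal(rms_s2s(v, valid = c(TRUE, FALSE, TRUE)), NA_real_)
  v2 <- c(0, 1, 100, 2, 3)
  expect_equal(rms_s2s(v2, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE)), 1)
})

test_that("data loss covers both reporting modes", {
  st <- make_stream(seq(0, 90, by = 10), 1, 1,
                    confidence = c(rep(1, 8), 0, 0),
                    validity = c(rep(TRUE, 8), FALSE, FALSE),
                    confidence_mode = "confidence_column")
  expect_equal(data_loss_fraction(st), 20)

  # complete 30 Hz stream over 10 s: 0 %
  t30 <- seq(0, 10000, by = 1000 / 30)
  full <- make_stream(t30, 1, 1, rate_hz = 30,
                      confidence_mode = "missing_samples")
  expect_equal(data_loss_fraction(full), 0)
  # half the samples gone: 50 %
  half <- make_stream(t30[seq(1, length(t30), by = 2)], 1, 1, rate_hz = 30,
                      confidence_mode = "missing_samples")
  expect_equal(data_loss_fraction(half, interval = c(0, 10000)), 50,
               tolerance = 0.02)
})

test_that("axis correlations respect the joint-validity mask and attenuation", {
  withr::with_seed(83, {
    n <- 10000
    s <- rnorm(n, 0, 3)
    m <- structure(data.frame(t_ms = seq_len(n), x_a_deg = s + rnorm(n),
                              y_a_deg = s + rnorm(n), valid_a = TRUE,
                              x_b_deg = s + rnorm(n), y_b_deg = s + rnorm(n),
                              valid_b = TRUE),
                   class = c("merged_series", "data.frame"))
    m$valid <- m$valid_a & m$valid_b
    ax <- axis_correlations(m)
    expect_equal(ax$r_x, attenuated_r(3, 1, 1), tolerance = 0.02)
    expect_equal(ax$r_y, attenuated_r(3, 1, 1), tolerance = 0.02)

    # affine invariance and the exact-copy limit
    m2 <- m
    m2$x_b_deg <- 3 * m2$x_a_deg - 7
    expect_equal(axis_correlations(m2)$r_x, 1)

    # independent columns stay near zero
    m3 <- m
    m3$x_a_deg <- rnorm(n); m3$x_b_deg <- rnorm(n)
    expect_lt(abs(axis_correlations(m3)$r_x), 0.05)

    # too few jointly valid rows flags exclusion
    m4 <- m
    m4$valid <- c(rep(TRUE, 10), rep(FALSE, n - 10))
    expect_true(axis_correlations(m4)$excluded)
  })
  expect_equal(cohort_correlation(c(0.8, 0.9, NA)), 0.85)
  expect_equal(cohort_correlation(c(0.8, 0.9), fisher_z = TRUE),
               tanh(mean(atanh(c(0.8, 0.9)))))
})

test_that("drift correction recovers constant bias and never harms it", {
  targets <- cbind(c(-5, 0, 5, -5, 0, 5, 0), c(-3, -3, -3, 3, 3, 3, 0))

  # zero offsets: no correction, unchanged stream
  d0 <- drift_correct(targets, targets,
                      samples_deg = data.frame(x_deg = 1:3, y_deg = 4:6))
  expect_equal(d0$correction_deg, c(0, 0))
  expect_equal(d0$residual_deg, 0)
  expect_equal(d0$corrected$x_deg, 1:3)

  # constant injected bias is recovered exactly
  bias <- c(1, -0.5)
  d1 <- drift_correct(sweep(targets, 2, -bias), targets)
  expect_equal(d1$correction_deg, bias)
  expect_equal(d1$residual_deg, 0, tolerance = 1e-12)

  # bias + noise: residual on the noise scale, corrected beats uncorrected
  withr::with_seed(97, {
    noisy <- sweep(targets, 2, -bias) + matrix(rnorm(14, 0, 0.2), ncol = 2)
    d2 <- drift_correct(noisy, targets)
    expect_lt(d2$residual_deg, 5 * 0.2)
    trial_centroids <- cbind(rnorm(30, bias[1], 0.2), rnorm(30, bias[2], 0.2))
    uncorrected <- mean(sqrt(rowSums(trial_centroids^2)))
    corrected <- mean(sqrt(rowSums(sweep(trial_centroids, 2,
                                         d2$correction_deg)^2)))
    expect_lt(corrected, uncorrected)
  })

  expect_error(drift_correct(targets[1:2, ], targets[1:2, ]), ">= 3")
})
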