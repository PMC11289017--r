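test_that("Type-II ANOVA matches the hand-computed balanced 2x2 decomposition", {
  # duplicated cells {10,10},{12,12},{20,20},{26,26}; hand decomposition:
  # grand mean 17; A means 11/23 -> SS_A = 4*36 + 4*36 = 288;
  # B means 15/19 -> SS_B = 4*4 + 4*4 = 32; interaction deviations +-1 -> 8;
  # residual 0; total 328
  df <- data.frame(A = rep(c("a1", "a1", "a2", "a2"), each = 2),
                   B = rep(c("b1", "b2", "b1", "b2"), each = 2),
                   y = c(10, 10, 12, 12, 20, 20, 26, 26))
  tab <- factorial_anova(df, c("A", "B"), "y")
  expect_equal(tab$sum_sq[tab$effect == "A"], 288)
  expect_equal(tab$sum_sq[tab$effect == "B"], 32)
  expect_equal(tab$sum_sq[tab$effect == "A:B"], 8)
  expect_equal(tab$sum_sq[tab$effect == "residual"], 0, tolerance = 1e-10)
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(sum(tab$sum_sq), 328, tolerance = 1e-10)
  expect_equal(tab$eta_sq[1:3], c(288, 32, 8) / 328, tolerance = 1e-10)

  # constant response: every effect SS is zero
  dfc <- df; dfc$y <- 5
  tabc <- factorial_anova(dfc, c("A", "B"), "y")
  expect_equal(tabc$sum_sq, rep(0, 4), tolerance = 1e-12)
})

test_that("Type-II sums of squares are order-invariant and additive when balanced", {
  withr::with_seed(101, {
    # unbalanced three-factor data: order invariance of Type-II SS
    n <- 90
    df <- data.frame(A = sample(c("x", "y"), n, TRUE),
                     B = sample(c("u", "v"), n, TRUE),
                     C = sample(c("p", "q"), n, TRUE),
                     y = rnorm(n))
    t1 <- factorial_anova(df, c("A", "B", "C"), "y")
    t2 <- factorial_anova(df, c("C", "A", "B"), "y")
    ss_total <- sum((df$y - mean(df$y))^2)
    for (eff in c("A", "B", "C", "A:B", "residual")) {
      expect_lt(abs(t1$sum_sq[t1$effect == eff] -
                    t2$sum_sq[t2$effect == eff]), 1e-10 * ss_total)
    }

    # independent cross-check against car's Type-II decomposition
    fit <- lm(y ~ A * B * C, data = df)
    ca <- as.data.frame(car::Anova(fit, type = 2))
    for (eff in setdiff(t1$effect, "residual")) {
      expect_equal(t1$sum_sq[t1$effect == eff], ca[eff, "Sum Sq"],
                   tolerance = 1e-10)
      expect_equal(t1$F[t1$effect == eff], ca[eff, "F value"],
                   tolerance = 1e-10)
    }

    # balanced design: SS add up to the total corrected SS
    bal <- expand.grid(A = c("x", "y"), B = c("u", "v"), C = c("p", "q"),
                       rep = 1:5)
    bal$y <- rnorm(nrow(bal))
    tb <- factorial_anova(bal, c("A", "B", "C"), "y")
    expect_equal(sum(tb$sum_sq), sum((bal$y - mean(bal$y))^2),
                 tolerance = 1e-8)
  })
})

test_that("degenerate ANOVA designs fail loudly", {
  df <- data.frame(A = c("a1", "a1", "a2", "a2"), B = c("b1", "b2", "b1", "b1"),
                   y = 1:4)
  # empty cell a2:b2
  expect_error(factorial_anova(df, c("A", "B"), "y"), "A=a2.*B=b2|empty")
  df2 <- data.frame(A = rep("a1", 4), y = 1:4)
  expect_error(factorial_anova(df2, "A", "y"), "levels")
})

test_that("paired t test matches hand calculation and guards degeneracy", {
  # differences {1, 2, 3}: t = 2 / (1 / sqrt(3))
  b <- c(5, 5, 5)
  a <- b + c(1, 2, 3)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)

  # identity with the one-sample t on differences
  withr::with_seed(113, {
    x <- rnorm(12); y <- rnorm(12)
    ht <- t.test(x - y)
    tt2 <- paired_ttest(x, y)
    expect_equal(tt2$t, unname(ht$statistic))
    expect_equal(tt2$p, ht$p.value)
  })

  # zero-variance differences (including a == b) are an error, not Inf/NaN
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  expect_error(paired_ttest(1, 1), "length")
})

test_that("calibration summaries are column means at two decimals", {
  tab <- load_calibration_table()
  expect_equal(nrow(tab), 19)
  s <- summarize_calibration(tab)
  expect_equal(unname(s["eyelink_mean_deg"]), 0.50)
  expect_equal(unname(s["webcam_mean_deg"]), 1.44)

  one <- tab[3, ]
  s1 <- summarize_calibration(one)
  expect_equal(unname(s1), unlist(one[-1], use.names = FALSE))

  expect_error(summarize_calibration(tab[0, ]), "empty")
  expect_error(summarize_calibration(rbind(tab, tab[1, ])), "unique")
})

test_that("gaze heatmaps normalize to a unit peak and integrate to one", {
  # single point: unimodal, peak 1 at the nearest cell
  k1 <- kde_heatmap(matrix(c(3, 4), ncol = 2), n = 33,
                    lims = c(0, 6, 1, 7), bandwidth = 0.5)
  expect_equal(max(k1$z), 1)
  peak <- which(k1$z == 1, arr.ind = TRUE)
  expect_equal(k1$x[peak[1]], 3, tolerance = 0.2)
  expect_equal(k1$y[peak[2]], 4, tolerance = 0.2)

  # two far-separated mirror-image clusters: equal local maxima within 1 %
  withr::with_seed(131, {
    dx <- rnorm(400, 0, 0.5); dy <- rnorm(400, 0, 0.5)
    pts <- rbind(cbind(-10 + dx, dy), cbind(10 - dx, dy))
    k2 <- kde_heatmap(pts, n = 101, lims = c(-15, 15, -5, 5), bandwidth = 0.5)
    left <- max(k2$z[k2$x < 0, ])
    right <- max(k2$z[k2$x > 0, ])
    expect_equal(left, right, tolerance = 0.01)

    # quadrature check of the unnormalized density
    k3 <- kde_heatmap(cbind(rnorm(500), rnorm(500)), n = 151,
                      lims = c(-8, 8, -8, 8))
    dx <- diff(k3$x[1:2]); dy <- diff(k3$y[1:2])
    expect_equal(sum(k3$density) * dx * dy, 1, tolerance = 0.02)
  })
})
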