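#' Factorial ANOVA with Type-II sums of squares
#'
#' Fits the full factorial model (all main effects and interactions) of the
#' given categorical factors on a numeric response and decomposes the
#' variance with Type-II sums of squares, which are invariant to factor
#' order and the convention for two-level designs with mild imbalance.
#' Effect sizes are reported as eta squared, effect SS over total corrected
#' SS. No multiple-testing correction is applied: p values are uncorrected.
#'
#' @param data Data frame of records (e.g. one row per analyzed fixation).
#' @param factors Character vector of factor column names (each >= 2 levels).
#' @param response Numeric response column name.
#' @return Data frame with one row per effect plus a residual row:
#'   `effect`, `sum_sq`, `df`, `mean_sq`, `F`, `p_uncorrected`, `eta_sq`.
#' @export
factorial_anova <- function(data, factors, response) {
  stopifnot(all(c(factors, response) %in% names(data)))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
    }
  }
  cells <- table(data[factors])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    lab <- paste(mapply(function(f, i) paste0(f, "=", dimnames(cells)[[f]][i]),
                        factors, empty), collapse = ", ")
    stop("empty design cell makes Type-II sums of squares inestimable: ",
         lab, call. = FALSE)
  }
  fml <- stats::reformulate(paste(factors, collapse = " * "),
                            response = response)
  fit <- stats::lm(fml, data = data)
  df_res <- stats::df.residual(fit)
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  rss_full <- sum(stats::residuals(fit)^2)

  # Type-II SS by model comparison: for each term, the RSS drop from adding
  # it to the model holding every term that does not contain it (marginality
  # respected). Equivalent to car::Anova(type = 2) but defined even when the
  # full model fits exactly (zero residual).
  terms_all <- attr(stats::terms(fit), "term.labels")
  term_vars <- lapply(strsplit(terms_all, ":", fixed = TRUE), sort)
  y <- data[[response]]
  rss_of <- function(labels) {
    f <- if (length(labels)) stats::reformulate(labels, response = response)
         else stats::as.formula(paste(response, "~ 1"))
    m <- stats::lm(f, data = data)
    c(rss = sum(stats::residuals(m)^2), rank = m$rank)
  }
  ss <- numeric(length(terms_all))
  df_eff <- integer(length(terms_all))
  for (k in seq_along(terms_all)) {
    vk <- term_vars[[k]]
    keep <- vapply(term_vars, function(v) !all(vk %in% v), TRUE)
    m0 <- rss_of(terms_all[keep])
    m1 <- rss_of(c(terms_all[keep], terms_all[k]))
    ss[k] <- m0[["rss"]] - m1[["rss"]]
    df_eff[k] <- m1[["rank"]] - m0[["rank"]]
  }

  ss_total <- sum((y - mean(y))^2)
  ms_res <- rss_full / df_res
  fstat <- (ss / df_eff) / ms_res
  out <- data.frame(effect = c(terms_all, "residual"),
                    sum_sq = c(ss, rss_full), df = c(df_eff, df_res),
                    mean_sq = c(ss / df_eff, ms_res),
                    F = c(fstat, NA_real_),
                    p_uncorrected = c(stats::pf(fstat, df_eff, df_res,
                                                lower.tail = FALSE), NA_real_),
                    eta_sq = c(ss / ss_total, NA_real_))
  rownames(out) <- NULL
  out
}

#' Paired t test with an explicit degenerate-variance guard
#'
#' The classic paired two-sided t test on per-subject differences. A
#' zero-variance difference vector raises an error rather than returning an
#' infinite statistic, since in this pipeline it signals a degenerate
#' simulation or duplicated input.
#'
#' @param a,b Paired per-subject values, equal length >= 2.
#' @return List `t`, `df`, `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must be paired vectors of equal length >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t statistic is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Load the packaged per-participant calibration-error table
#'
#' Per-participant calibration output of the two trackers in the comparison
#' study this battery models: mean (and, for the laboratory tracker, max)
#' calibration error in degrees for 19 participants.
#'
#' @param path Optional path to a compatible CSV; defaults to the packaged
#'   table.
#' @return Data frame `participant`, `eyelink_mean_deg`, `eyelink_max_deg`,
#'   `webcam_mean_deg`.
#' @export
load_calibration_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "calibration_table1.csv",
                                package = "gazebench", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize a per-participant calibration table
#'
#' Arithmetic mean of every numeric error column across participants,
#' reported to two decimals (the conventional printing precision for
#' degree-scale calibration errors).
#'
#' @param table A calibration table as from [load_calibration_table()].
#' @return Named numeric vector of column means, rounded to 2 decimals.
#' @export
summarize_calibration <- function(table) {
  if (!nrow(table)) stop("calibration table is empty", call. = FALSE)
  if (anyDuplicated(table$participant)) {
    stop("participant ids must be unique", call. = FALSE)
  }
  num <- names(table)[vapply(table, is.numeric, TRUE)]
  num <- setdiff(num, "participant")
  round(colMeans(table[num]), 2)
}

#' Gaussian-kernel density heatmap of gaze positions
#'
#' Bivariate Gaussian KDE evaluated on a raster and normalized by its
#' maximum, so values lie in [0, 1] with the peak exactly 1 (the standard
#' display scale for gaze heatmaps). The default bandwidth follows Scott's
#' rule per axis, `sd * n^(-1/6)`.
#'
#' @param points n x 2 matrix or data frame of gaze positions (any planar
#'   unit; degrees or pixels).
#' @param n Raster size, `c(nx, ny)` or a scalar.
#' @param lims `c(xmin, xmax, ymin, ymax)`; defaults to the point range
#'   padded by three bandwidths.
#' @param bandwidth Per-axis Gaussian kernel SD; scalar or length 2.
#' @return List `x`, `y` (raster coordinates), `z` (normalized density, max
#'   1), `density` (unnormalized, integrates to ~1), `bandwidth`.
#' @export
kde_heatmap <- function(points, n = 64, lims = NULL, bandwidth = NULL) {
  m <- as_xy_matrix(as.matrix(points))
  if (!nrow(m)) stop("need at least one point", call. = FALSE)
  n <- rep_len(n, 2)
  if (is.null(bandwidth)) {
    bw <- apply(m, 2, stats::sd) * nrow(m)^(-1 / 6)
    bw[!is.finite(bw) | bw <= 0] <- 1
    bandwidth <- bw
  } else {
    bandwidth <- rep_len(bandwidth, 2)
    if (any(bandwidth <= 0)) stop("bandwidth must be > 0", call. = FALSE)
  }
  lims <- lims %||% c(min(m[, 1]) - 3 * bandwidth[1],
                      max(m[, 1]) + 3 * bandwidth[1],
                      min(m[, 2]) - 3 * bandwidth[2],
                      max(m[, 2]) + 3 * bandwidth[2])
  # MASS::kde2d uses h/4 as the Gaussian kernel SD
  k <- MASS::kde2d(m[, 1], m[, 2], h = 4 * bandwidth, n = n, lims = lims)
  list(x = k$x, y = k$y, z = k$z / max(k$z), density = k$z,
       bandwidth = bandwidth)
}
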