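#' Angular accuracy of a fixation against its target
#'
#' Euclidean norm of the centroid-minus-target difference in degree space.
#'
#' @param centroid_deg,target_deg Length-2 vectors or n x 2 matrices of
#'   degree coordinates.
#' @return Non-negative error(s) in degrees.
#' @export
fixation_accuracy <- function(centroid_deg, target_deg) {
  a <- as_xy_matrix(centroid_deg)
  b <- as_xy_matrix(target_deg)
  out <- sqrt(rowSums((a - b)^2))
  if (!is.matrix(centroid_deg) && !is.matrix(target_deg)) out <- drop(out)
  out
}

#' Classify grid targets as inner or outer
#'
#' A target is `"outer"` when it lies on the boundary ring of the stimulus
#' grid (first or last row, first or last column) and `"inner"` otherwise.
#' On the 7 x 8 battery grid this yields 26 outer and 30 inner targets.
#' Indices are 1-based.
#'
#' @param row_index,col_index Grid indices (vectors allowed).
#' @param rows,cols Grid size.
#' @return Character vector, `"inner"` or `"outer"`.
#' @export
classify_eccentricity <- function(row_index, col_index, rows, cols) {
  if (any(row_index < 1 | row_index > rows | col_index < 1 | col_index > cols)) {
    stop("grid index outside the grid", call. = FALSE)
  }
  outer <- row_index == 1 | row_index == rows | col_index == 1 | col_index == cols
  ifelse(outer, "outer", "inner")
}

#' Across-subject precision at shared target locations
#'
#' The battery grid shows each target once per subject, so within-subject
#' spread cannot be computed; instead, the per-axis sample SD (n - 1
#' denominator) of fixation centroids is taken across subjects at each grid
#' location, separately per tracker, followed by the grand mean and SD of
#' those SDs across locations. Locations with fewer than two contributing
#' subjects are excluded and reported.
#'
#' @param centroids Data frame with columns `subject`, `tracker`, `location`,
#'   `cx_deg`, `cy_deg` (one selected fixation per subject and location).
#' @return List with `per_location` (tracker, location, n, sd_x, sd_y),
#'   `summary` (tracker, axis, mean_sd, sd_sd), and `excluded` (locations
#'   dropped for having a single contributor).
#' @export
precision_across_subjects <- function(centroids) {
  need <- c("subject", "tracker", "location", "cx_deg", "cy_deg")
  stopifnot(all(need %in% names(centroids)))
  key <- interaction(centroids$tracker, centroids$location, drop = TRUE)
  per <- do.call(rbind, lapply(split(centroids, key), function(g) {
    data.frame(tracker = g$tracker[1], location = g$location[1],
               n = nrow(g),
               sd_x = if (nrow(g) >= 2) stats::sd(g$cx_deg) else NA_real_,
               sd_y = if (nrow(g) >= 2) stats::sd(g$cy_deg) else NA_real_)
  }))
  rownames(per) <- NULL
  excluded <- per[per$n < 2, c("tracker", "location", "n"), drop = FALSE]
  kept <- per[per$n >= 2, , drop = FALSE]
  summary <- do.call(rbind, lapply(split(kept, kept$tracker), function(g) {
    data.frame(tracker = g$tracker[1], axis = c("x", "y"),
               mean_sd = c(mean(g$sd_x), mean(g$sd_y)),
               sd_sd = c(stats::sd(g$sd_x), stats::sd(g$sd_y)))
  }))
  rownames(summary) <- NULL
  list(per_location = kept, summary = summary, excluded = excluded)
}

#' RMS of successive sample-to-sample displacements
#'
#' `sqrt(mean(diff(values)^2))` over consecutive valid sample pairs along one
#' axis; pairs spanning an invalid sample are excluded. A within-recording
#' noise measure: for i.i.d. noise of SD sigma it converges to sigma * sqrt(2).
#'
#' @param values Gaze positions along one axis, degrees.
#' @param valid Optional logical mask.
#' @return RMS-S2S in degrees, or `NA` with fewer than two consecutive valid
#'   samples.
#' @export
rms_s2s <- function(values, valid = NULL) {
  valid <- (valid %||% rep(TRUE, length(values))) & is.finite(values)
  pair <- valid[-length(valid)] & valid[-1]
  if (!any(pair)) return(NA_real_)
  d <- diff(values)[pair]
  sqrt(mean(d^2))
}

#' Fraction of lost gaze data, in percent
#'
#' For a confidence-reporting stream (webcam-style), the share of samples
#' with confidence exactly 0. For a missing-samples stream (lab-style),
#' one minus observed/expected sample count, with the expected count being
#' the interval length times the nominal rate (rounded down).
#'
#' @param stream A [gaze_stream()].
#' @param interval Optional `c(t0, t1)` ms window; defaults to the stream
#'   span.
#' @param mode Loss-reporting mode; defaults to the stream's
#'   `confidence_mode` attribute, falling back to `"confidence_column"` when
#'   any confidence value is present.
#' @param nominal_rate_hz Expected rate for missing-samples mode; defaults
#'   to the stream attribute.
#' @return Percentage in [0, 100].
#' @export
data_loss_fraction <- function(stream, interval = NULL, mode = NULL,
                               nominal_rate_hz = NULL) {
  interval <- interval %||% range(stream$t_ms)
  mode <- mode %||% attr(stream, "confidence_mode")
  if (is.null(mode) || is.na(mode)) {
    mode <- if (any(!is.na(stream$confidence))) "confidence_column"
            else "missing_samples"
  }
  rows <- stream$t_ms >= interval[1] & stream$t_ms <= interval[2]
  if (mode == "confidence_column") {
    conf <- stream$confidence[rows]
    if (!length(conf)) return(NA_real_)
    100 * mean(conf == 0, na.rm = TRUE)
  } else {
    rate <- nominal_rate_hz %||% attr(stream, "nominal_rate_hz")
    expected <- floor((interval[2] - interval[1]) / 1000 * rate)
    if (expected <= 0) return(NA_real_)
    100 * max(0, 1 - sum(rows) / expected)
  }
}

#' Per-axis Pearson correlation between the two merged trackers
#'
#' Computed on jointly valid rows only (both trackers reporting reliable
#' data, the joint-validity mask). Subjects with fewer than `min_valid`
#' jointly valid rows are flagged for exclusion from cohort averages.
#'
#' @param merged A `merged_series` from [merge_streams()].
#' @param min_valid Minimum jointly valid rows for a usable estimate.
#' @return List `r_x`, `r_y`, `n` (jointly valid rows), `excluded`.
#' @export
axis_correlations <- function(merged, min_valid = 30) {
  ok <- merged$valid
  n <- sum(ok)
  if (n < min_valid) {
    return(list(r_x = NA_real_, r_y = NA_real_, n = n, excluded = TRUE))
  }
  list(r_x = stats::cor(merged$x_a_deg[ok], merged$x_b_deg[ok]),
       r_y = stats::cor(merged$y_a_deg[ok], merged$y_b_deg[ok]),
       n = n, excluded = FALSE)
}

#' Average per-subject correlations into a cohort value
#'
#' The plain arithmetic mean of per-subject r (the conventional report);
#' Fisher-z averaging (`tanh(mean(atanh(r)))`) is available behind a flag.
#' `NA` entries (excluded subjects) are dropped.
#'
#' @param r Per-subject correlation coefficients.
#' @param fisher_z Average on the Fisher-z scale instead.
#' @return Cohort correlation.
#' @export
cohort_correlation <- function(r, fisher_z = FALSE) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  if (fisher_z) tanh(mean(atanh(r))) else mean(r)
}

#' Drift correction from a recalibration fixation grid
#'
#' Estimates the systematic gaze offset from matched recalibration
#' fixation/target pairs (per-axis median of centroid minus target by
#' default; mean behind the flag) and subtracts it from subsequent samples.
#' The reported residual is leave-one-out cross-validated: each point's
#' error after a correction fitted on the remaining points, averaged — a
#' continuous reliability measure that does not reward overfitting the
#' recalibration points themselves.
#'
#' @param recal_centroids,recal_targets n x 2 matrices (degrees), n >= 3.
#' @param samples_deg Optional data frame with `x_deg`, `y_deg` columns to
#'   correct (the samples recorded after this recalibration).
#' @param stat `"median"` (robust default) or `"mean"`.
#' @return List `correction_deg` (length 2), `residual_deg` (mean held-out
#'   error), and `corrected` (the corrected samples, if given).
#' @export
drift_correct <- function(recal_centroids, recal_targets, samples_deg = NULL,
                          stat = c("median", "mean")) {
  stat <- match.arg(stat)
  cen <- as_xy_matrix(recal_centroids)
  tar <- as_xy_matrix(recal_targets)
  if (nrow(cen) != nrow(tar) || nrow(cen) < 3) {
    stop("need >= 3 matched recalibration fixation/target pairs", call. = FALSE)
  }
  f <- if (stat == "median") stats::median else mean
  offsets <- cen - tar
  held_out <- vapply(seq_len(nrow(offsets)), function(i) {
    corr_i <- apply(offsets[-i, , drop = FALSE], 2, f)
    sqrt(sum((offsets[i, ] - corr_i)^2))
  }, 0)
  correction <- apply(offsets, 2, f)
  corrected <- NULL
  if (!is.null(samples_deg)) {
    corrected <- samples_deg
    corrected$x_deg <- corrected$x_deg - correction[1]
    corrected$y_deg <- corrected$y_deg - correction[2]
  }
  list(correction_deg = unname(correction), residual_deg = mean(held_out),
       corrected = corrected)
}
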