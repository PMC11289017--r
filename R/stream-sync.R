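#' Gaze stream container
#'
#' A time-sorted table of gaze samples from one tracker with columns `t_ms`,
#' `x_px`, `y_px`, `confidence`, `validity`. Timestamps are epoch-style
#' milliseconds and must be strictly increasing; confidence, when present,
#' lies in [0, 1]; a missing position implies `validity == FALSE`.
#'
#' @param samples Data frame with the five canonical columns.
#' @param source Tracker label.
#' @param nominal_rate_hz Nominal sampling rate, Hz.
#' @param confidence_mode `"confidence_column"` or `"missing_samples"`
#'   (how this tracker reports loss); may be `NA` for externally read files.
#' @return An object of class `gaze_stream` (a data frame).
#' @export
gaze_stream <- function(samples, source = "tracker", nominal_rate_hz = NA_real_,
                        confidence_mode = NA_character_) {
  required <- c("t_ms", "x_px", "y_px", "confidence", "validity")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- samples[required]
  samples$validity <- as.logical(samples$validity)
  bad_t <- which(diff(samples$t_ms) <= 0)
  if (length(bad_t)) {
    stop(sprintf("non-increasing timestamp at row %d", bad_t[1] + 1L),
         call. = FALSE)
  }
  conf <- samples$confidence
  bad_c <- which(!is.na(conf) & (conf < 0 | conf > 1))
  if (length(bad_c)) {
    stop(sprintf("confidence out of [0, 1] at row %d", bad_c[1]), call. = FALSE)
  }
  bad_v <- which((is.na(samples$x_px) | is.na(samples$y_px)) & samples$validity)
  if (length(bad_v)) {
    stop(sprintf("missing position marked valid at row %d", bad_v[1]),
         call. = FALSE)
  }
  structure(samples, source = source, nominal_rate_hz = nominal_rate_hz,
            confidence_mode = confidence_mode,
            class = c("gaze_stream", "data.frame"))
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("gaze_stream '%s': %d samples, nominal %g Hz, %.1f s span\n",
              attr(x, "source"), nrow(x), attr(x, "nominal_rate_hz"),
              (max(x$t_ms) - min(x$t_ms)) / 1000))
  invisible(x)
}

#' Read / write a gaze stream CSV
#'
#' The CSV dialect has header `t_ms,x_px,y_px,confidence,validity`, UTF-8,
#' with empty fields for missing positions. Files violating the stream
#' invariants (non-monotone time, confidence outside [0, 1], missing position
#' marked valid) are rejected with the offending row number.
#'
#' @param path File path.
#' @param source,nominal_rate_hz Metadata attached to the stream.
#' @return [read_gaze_stream()] returns a [gaze_stream()];
#'   [write_gaze_stream()] returns the path invisibly.
#' @export
read_gaze_stream <- function(path, source = basename(path),
                             nominal_rate_hz = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("t_ms", "x_px", "y_px", "confidence", "validity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("t_ms", "x_px", "y_px", "confidence")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$validity <- as.logical(df$validity)
  tryCatch(gaze_stream(df, source = source, nominal_rate_hz = nominal_rate_hz),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' @rdname read_gaze_stream
#' @param stream A [gaze_stream()].
#' @export
write_gaze_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a stimulus schedule CSV
#'
#' Dialect: `trial_id,task,onset_ms,offset_ms,target_x_px,target_y_px,meta`.
#'
#' @param schedule A `stimulus_schedule` or its trial table.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  tr <- if (inherits(schedule, "stimulus_schedule")) schedule$trials else schedule
  cols <- c("trial_id", "task", "onset_ms", "offset_ms", "target_x_px",
            "target_y_px", "meta")
  utils::write.csv(tr[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a key-press table CSV
#'
#' Dialect: `trial_id,press_t_ms,press_dur_ms`.
#'
#' @param presses Data frame with the three canonical columns.
#' @param path File path.
#' @export
write_presses <- function(presses, path) {
  utils::write.csv(presses[c("trial_id", "press_t_ms", "press_dur_ms")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_presses
#' @export
read_presses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Snap a stream's valid samples onto a uniform grid (origin g0, step ms);
# samples landing in the same cell are averaged. Returns dense vectors.
snap_to_grid <- function(stream, g0, step) {
  ok <- stream$validity & is.finite(stream$x_px) & is.finite(stream$y_px)
  s <- stream[ok, , drop = FALSE]
  if (!nrow(s)) return(list(idx0 = 0L, x = numeric(0), y = numeric(0)))
  cell <- as.integer(round((s$t_ms - g0) / step))
  lo <- min(cell); hi <- max(cell)
  x <- rep(NA_real_, hi - lo + 1L)
  y <- rep(NA_real_, hi - lo + 1L)
  mx <- tapply(s$x_px, cell, mean)
  my <- tapply(s$y_px, cell, mean)
  pos <- as.integer(names(mx)) - lo + 1L
  x[pos] <- mx; y[pos] <- my
  list(idx0 = lo, x = x, y = y)
}

#' Estimate the clock lag between two gaze streams
#'
#' Time-lag cross-correlation: both streams are snapped onto a uniform
#' auxiliary grid and the integer-step shift maximizing the mean of the x-
#' and y-axis Pearson correlations (over jointly observed cells) is returned,
#' converted to milliseconds. Ties are broken toward the smaller absolute
#' lag. A positive value means `other`'s clock runs ahead of `ref`'s, i.e.
#' subtracting the lag from `other`'s timestamps aligns the two streams.
#'
#' The grid step defaults to the reference (resampling-target) stream's
#' nominal rate, which is also the precision to which the lag is resolved;
#' a finer grid can be requested via `grid_hz`.
#'
#' @param ref Reference [gaze_stream()] (the eventual merge timebase).
#' @param other Stream whose clock offset is sought.
#' @param max_lag_ms Largest absolute lag searched, ms.
#' @param grid_hz Auxiliary grid rate; default `ref`'s nominal rate (or the
#'   rate implied by its median sampling interval if unknown).
#' @param min_pairs Minimum jointly observed cells required at a candidate
#'   lag for its correlation to count.
#' @return Estimated lag in ms (a multiple of the grid step).
#' @export
estimate_lag <- function(ref, other, max_lag_ms = 2000, grid_hz = NULL,
                         min_pairs = 100) {
  if (max_lag_ms <= 0) stop("max_lag_ms must be > 0", call. = FALSE)
  grid_hz <- grid_hz %||% attr(ref, "nominal_rate_hz")
  if (is.null(grid_hz) || !is.finite(grid_hz)) {
    grid_hz <- 1000 / stats::median(diff(ref$t_ms))
  }
  step <- 1000 / grid_hz
  g0 <- min(ref$t_ms)
  r <- snap_to_grid(ref, g0, step)
  o <- snap_to_grid(other, g0, step)
  K <- as.integer(floor(max_lag_ms / step))
  shifts <- (-K):K
  score <- rep(NA_real_, length(shifts))
  npairs <- integer(length(shifts))
  r_hi <- r$idx0 + length(r$x) - 1L
  o_hi <- o$idx0 + length(o$x) - 1L
  for (si in seq_along(shifts)) {
    s <- shifts[si]
    # pair ref cell i with other cell i + s
    lo <- max(r$idx0, o$idx0 - s)
    hi <- min(r_hi, o_hi - s)
    if (hi < lo) next
    ri <- (lo:hi) - r$idx0 + 1L
    oi <- (lo:hi) + s - o$idx0 + 1L
    ok <- !is.na(r$x[ri]) & !is.na(o$x[oi])
    npairs[si] <- sum(ok)
    if (npairs[si] < min_pairs) next
    cx <- suppressWarnings(stats::cor(r$x[ri][ok], o$x[oi][ok]))
    cy <- suppressWarnings(stats::cor(r$y[ri][ok], o$y[oi][ok]))
    score[si] <- mean(c(cx, cy), na.rm = TRUE)
  }
  if (all(is.na(score))) {
    stop("insufficient overlap: fewer than ", min_pairs,
         " jointly valid samples at every candidate lag", call. = FALSE)
  }
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-12)
  cand <- cand[which.min(abs(shifts[cand]))]
  shifts[cand] * step
}

#' Resample a gaze stream at arbitrary target times
#'
#' Linear interpolation of x and y at each target time from the two
#' bracketing valid samples. A query is marked invalid when a bracket is
#' missing (no extrapolation beyond the stream ends) or when the bracketing
#' span exceeds `max_gap_ms` — so dropouts and blinks are never bridged.
#' Queries landing exactly on a valid sample return it unchanged.
#'
#' @param target_times Strictly increasing query timestamps, ms.
#' @param stream A [gaze_stream()].
#' @param max_gap_ms Largest bracketing span that may be interpolated across.
#' @return Data frame `t_ms`, `x_px`, `y_px`, `valid`.
#' @export
align_and_resample <- function(target_times, stream, max_gap_ms = 100) {
  if (is.unsorted(target_times, strictly = TRUE)) {
    stop("target_times must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(t_ms = target_times, x_px = NA_real_, y_px = NA_real_,
                    valid = FALSE)
  ok <- stream$validity & is.finite(stream$x_px) & is.finite(stream$y_px)
  s <- stream[ok, , drop = FALSE]
  if (nrow(s) < 1) return(out)
  j <- findInterval(target_times, s$t_ms)
  exact <- j >= 1 & j <= nrow(s) & target_times == s$t_ms[pmax(j, 1)]
  out$x_px[exact] <- s$x_px[j[exact]]
  out$y_px[exact] <- s$y_px[j[exact]]
  out$valid[exact] <- TRUE
  interp <- !exact & j >= 1 & j < nrow(s)
  if (any(interp)) {
    jj <- j[interp]
    gap_ok <- (s$t_ms[jj + 1] - s$t_ms[jj]) <= max_gap_ms
    ii <- which(interp)[gap_ok]
    jj <- jj[gap_ok]
    w <- (target_times[ii] - s$t_ms[jj]) / (s$t_ms[jj + 1] - s$t_ms[jj])
    out$x_px[ii] <- s$x_px[jj] + w * (s$x_px[jj + 1] - s$x_px[jj])
    out$y_px[ii] <- s$y_px[jj] + w * (s$y_px[jj + 1] - s$y_px[jj])
    out$valid[ii] <- TRUE
  }
  out
}

#' Convert a gaze stream to degrees of visual angle
#'
#' @param stream A [gaze_stream()] (or any data frame with `t_ms`, `x_px`,
#'   `y_px` and optionally `validity`).
#' @param geom A [screen_geometry()].
#' @return Data frame `t_ms`, `x_deg`, `y_deg`, `valid`.
#' @export
stream_to_deg <- function(stream, geom) {
  deg <- px_to_deg(cbind(stream$x_px, stream$y_px), geom)
  valid <- if ("validity" %in% names(stream)) stream$validity else
    if ("valid" %in% names(stream)) stream$valid else TRUE
  data.frame(t_ms = stream$t_ms, x_deg = deg[, 1], y_deg = deg[, 2],
             valid = valid & is.finite(deg[, 1]) & is.finite(deg[, 2]))
}

#' Merge two gaze streams onto one common timebase
#'
#' Estimates and removes the inter-stream clock lag, resamples the second
#' stream onto the first stream's native timestamps, and converts both to
#' degrees. The first argument supplies the common timebase and should be
#' the lower-rate stream (the usual convention: the high-rate laboratory
#' stream is brought down to the webcam's rate). A merged row is valid only
#' where both sources are.
#'
#' @param low_rate Timebase [gaze_stream()] (typically the lower-rate one).
#' @param high_rate Stream to be lag-corrected and resampled.
#' @param geom A [screen_geometry()].
#' @param max_lag_ms,grid_hz Passed to [estimate_lag()].
#' @param max_gap_ms Passed to [align_and_resample()].
#' @return A `merged_series` data frame with columns `t_ms`, `x_a_deg`,
#'   `y_a_deg`, `valid_a` (timebase stream), `x_b_deg`, `y_b_deg`, `valid_b`
#'   (resampled stream), `valid`; attributes `estimated_lag_ms` and
#'   `sources`.
#' @export
merge_streams <- function(low_rate, high_rate, geom = default_screen(),
                          max_lag_ms = 2000, max_gap_ms = 100, grid_hz = NULL) {
  if (!nrow(low_rate) || !nrow(high_rate)) {
    stop("both streams must be non-empty", call. = FALSE)
  }
  lag <- estimate_lag(low_rate, high_rate, max_lag_ms = max_lag_ms,
                      grid_hz = grid_hz)
  shifted <- high_rate
  shifted$t_ms <- shifted$t_ms - lag
  res <- align_and_resample(low_rate$t_ms, shifted, max_gap_ms = max_gap_ms)
  a <- stream_to_deg(low_rate, geom)
  b <- stream_to_deg(res, geom)
  out <- data.frame(t_ms = low_rate$t_ms,
                    x_a_deg = a$x_deg, y_a_deg = a$y_deg, valid_a = a$valid,
                    x_b_deg = b$x_deg, y_b_deg = b$y_deg, valid_b = b$valid)
  out$valid <- out$valid_a & out$valid_b
  structure(out, estimated_lag_ms = lag,
            sources = c(a = attr(low_rate, "source"),
                        b = attr(high_rate, "source")),
            class = c("merged_series", "data.frame"))
}

#' @export
print.merged_series <- function(x, ...) {
  src <- attr(x, "sources")
  cat(sprintf(
    "merged_series: %d rows (%s as timebase, %s resampled), lag %.1f ms, %.0f%% jointly valid\n",
    nrow(x), src[["a"]], src[["b"]], attr(x, "estimated_lag_ms"),
    100 * mean(x$valid)))
  invisible(x)
}
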