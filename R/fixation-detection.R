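#' Parameters of the dispersion-based fixation detector
#'
#' @param dispersion_threshold_deg Largest dispersion (degrees) a fixation
#'   may reach; must be > 0.
#' @param min_points Samples needed to open a fixation; at least 3.
#' @param max_relative_change Largest allowed relative growth of the
#'   dispersion, `(new - old) / old`, when adding one sample. `Inf` disables
#'   the test.
#' @param min_duration_ms Optional minimum fixation duration applied after
#'   detection; `NULL` disables the filter.
#' @param measure Dispersion functional: `"max_pairwise"` (maximum pairwise
#'   angular distance, rotation-invariant; the default) or `"bounding_box"`
#'   (the classic I-DT width + height measure, kept for cross-checks).
#' @param slide Enable the evict-oldest step that can keep a fixation open by
#'   trading its oldest sample for the newest one.
#' @return An object of class `dispersion_params`.
#' @export
dispersion_params <- function(dispersion_threshold_deg = 1.0, min_points = 3,
                              max_relative_change = 0.5,
                              min_duration_ms = 100,
                              measure = c("max_pairwise", "bounding_box"),
                              slide = TRUE) {
  measure <- match.arg(measure)
  if (dispersion_threshold_deg <= 0) {
    stop("dispersion_threshold_deg must be > 0", call. = FALSE)
  }
  if (min_points < 3) stop("min_points must be >= 3", call. = FALSE)
  structure(list(dispersion_threshold_deg = dispersion_threshold_deg,
                 min_points = as.integer(min_points),
                 max_relative_change = max_relative_change,
                 min_duration_ms = min_duration_ms, measure = measure,
                 slide = slide),
            class = "dispersion_params")
}

#' Dispersion of a set of gaze points
#'
#' The default functional is the maximum pairwise Euclidean distance in
#' degree space (0 for a single point); `"bounding_box"` gives the classic
#' I-DT measure, x-extent plus y-extent.
#'
#' @param points An n x 2 matrix (degrees), or a length-2 vector for one
#'   point.
#' @param measure `"max_pairwise"` or `"bounding_box"`.
#' @return Dispersion in degrees.
#' @export
dispersion <- function(points, measure = c("max_pairwise", "bounding_box")) {
  measure <- match.arg(measure)
  m <- as_xy_matrix(points)
  if (nrow(m) == 0) stop("dispersion of an empty point set", call. = FALSE)
  if (nrow(m) == 1) return(0)
  if (measure == "max_pairwise") max(stats::dist(m))
  else diff(range(m[, 1])) + diff(range(m[, 2]))
}

# dispersion of the window [lo, hi] given coordinate vectors (O(n^2) only for
# max_pairwise; used at slide evictions and candidate openings)
window_dispersion <- function(x, y, lo, hi, measure) {
  if (hi == lo) return(0)
  if (measure == "max_pairwise") {
    max(stats::dist(cbind(x[lo:hi], y[lo:hi])))
  } else {
    diff(range(x[lo:hi])) + diff(range(y[lo:hi]))
  }
}

# dispersion after adding point j to a window with known dispersion cur
grown_dispersion <- function(x, y, lo, hi, j, cur, measure) {
  if (measure == "max_pairwise") {
    max(cur, sqrt((x[lo:hi] - x[j])^2 + (y[lo:hi] - y[j])^2))
  } else {
    diff(range(x[lo:hi], x[j])) + diff(range(y[lo:hi], y[j]))
  }
}

#' Detect fixations with a real-time dispersion criterion
#'
#' Single left-to-right pass, no lookahead. A fixation candidate opens when
#' `min_points` consecutive valid samples have dispersion at or below the
#' threshold. Each following sample is added while (a) the dispersion stays
#' at or below the threshold and (b) its relative growth stays at or below
#' `max_relative_change` (growth from an exactly-zero dispersion is always
#' accepted). When only the relative-growth test fails, the detector may
#' instead slide the window — add the new sample and evict the oldest one —
#' provided that lowers (or keeps) the dispersion; evicted samples remain
#' members of the fixation, so every valid sample belongs to at most one
#' fixation. Any other failure, and any invalid sample, closes the fixation:
#' its centroid is the mean of all member samples and its dispersion the
#' closing window's dispersion. Scanning resumes at the first sample after
#' the last member. An optional minimum-duration filter is applied last.
#'
#' @param x A [gaze_stream()] (pass `geom` too) or a data frame with columns
#'   `t_ms`, `x_deg`, `y_deg` and optionally `valid`.
#' @param params A [dispersion_params()].
#' @param geom Required when `x` is a pixel-space gaze stream.
#' @return Data frame with one row per fixation: `start_ms`, `end_ms`,
#'   `cx_deg`, `cy_deg`, `dispersion_deg`, `n`.
#' @export
detect_fixations <- function(x, params = dispersion_params(), geom = NULL) {
  stopifnot(inherits(params, "dispersion_params"))
  if (inherits(x, "gaze_stream")) {
    if (is.null(geom)) stop("geom is required for a pixel-space gaze stream",
                            call. = FALSE)
    x <- stream_to_deg(x, geom)
  }
  t <- x$t_ms
  px <- x$x_deg
  py <- x$y_deg
  valid <- if ("valid" %in% names(x)) x$valid else rep(TRUE, length(t))
  valid <- valid & is.finite(px) & is.finite(py)
  n <- length(t)
  mp <- params$min_points
  thr <- params$dispersion_threshold_deg
  mrc <- params$max_relative_change
  meas <- params$measure

  res <- list()
  close_fix <- function(start, hi, disp) {
    idx <- start:hi
    res[[length(res) + 1L]] <<- c(t[start], t[hi], mean(px[idx]),
                                  mean(py[idx]), disp, length(idx))
  }

  i <- 1L
  while (i + mp - 1L <= n) {
    win <- i:(i + mp - 1L)
    bad <- which(!valid[win])
    if (length(bad)) { i <- win[max(bad)] + 1L; next }
    d0 <- window_dispersion(px, py, i, i + mp - 1L, meas)
    if (d0 > thr) { i <- i + 1L; next }

    start <- i; lo <- i; hi <- i + mp - 1L; cur <- d0
    j <- hi + 1L
    closed_by_invalid <- FALSE
    while (j <= n) {
      if (!valid[j]) { closed_by_invalid <- TRUE; break }
      nd <- grown_dispersion(px, py, lo, hi, j, cur, meas)
      rel_ok <- cur == 0 || (nd - cur) / cur <= mrc
      if (nd <= thr && rel_ok) {
        hi <- j; cur <- nd; j <- j + 1L
      } else if (nd <= thr && !rel_ok && params$slide) {
        slid <- window_dispersion(px, py, lo + 1L, j, meas)
        if (slid <= cur) {
          lo <- lo + 1L; hi <- j; cur <- slid; j <- j + 1L
        } else break
      } else break
    }
    close_fix(start, hi, cur)
    i <- if (closed_by_invalid) j + 1L else hi + 1L
  }

  out <- as.data.frame(do.call(rbind, res))
  if (!nrow(out)) {
    out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      cx_deg = numeric(0), cy_deg = numeric(0),
                      dispersion_deg = numeric(0), n = integer(0))
    return(out)
  }
  names(out) <- c("start_ms", "end_ms", "cx_deg", "cy_deg", "dispersion_deg", "n")
  out$n <- as.integer(out$n)
  if (!is.null(params$min_duration_ms)) {
    out <- out[out$end_ms - out$start_ms >= params$min_duration_ms, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Select the offset-related fixation of each trial
#'
#' A trial's fixation qualifies when the confirmation key press falls inside
#' the fixation interval and the press lasted under 500 ms; trials whose
#' press violates either rule get no fixation. When several fixations
#' qualify, the one overlapping the trial interval longest wins. The
#' criteria are meant to be evaluated per tracker: call once per tracker's
#' fixation list.
#'
#' @param fixations Output of [detect_fixations()].
#' @param trials Trial table with `trial_id`, `onset_ms`, `offset_ms`.
#' @param presses Press table with `trial_id`, `press_t_ms`, `press_dur_ms`.
#' @param max_press_dur_ms Rejection bound on press duration (exclusive).
#' @return One row per trial: the trial columns, the selected fixation's
#'   columns (NA when none qualified), and `selected`.
#' @export
select_offset_fixations <- function(fixations, trials, presses,
                                    max_press_dur_ms = 500) {
  if (inherits(trials, "stimulus_schedule")) trials <- trials$trials
  out <- trials
  fix_cols <- c("start_ms", "end_ms", "cx_deg", "cy_deg", "dispersion_deg", "n")
  for (col in fix_cols) out[[col]] <- NA_real_
  out$press_t_ms <- NA_real_
  out$press_dur_ms <- NA_real_
  out$selected <- FALSE
  for (k in seq_len(nrow(out))) {
    pr <- presses[presses$trial_id == out$trial_id[k], , drop = FALSE]
    if (!nrow(pr)) next
    best <- NULL; best_ov <- -Inf
    for (p in seq_len(nrow(pr))) {
      if (pr$press_dur_ms[p] >= max_press_dur_ms) next
      hits <- which(fixations$start_ms <= pr$press_t_ms[p] &
                    fixations$end_ms >= pr$press_t_ms[p])
      for (h in hits) {
        ov <- min(fixations$end_ms[h], out$offset_ms[k]) -
          max(fixations$start_ms[h], out$onset_ms[k])
        if (ov > best_ov) { best <- c(h, p); best_ov <- ov }
      }
    }
    if (!is.null(best)) {
      out[k, fix_cols] <- fixations[best[1], fix_cols]
      out$press_t_ms[k] <- pr$press_t_ms[best[2]]
      out$press_dur_ms[k] <- pr$press_dur_ms[best[2]]
      out$selected[k] <- TRUE
    }
  }
  out$n <- as.integer(out$n)
  out
}
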