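#' Default simulation scenario for the full test battery
#'
#' Describes a complete simulated comparison study: screen geometry, the two
#' tracker models, viewer behaviour, the five task configurations, fixation
#' detection settings and synchronization settings. The tracker presets and
#' task layouts follow the standard battery (7 x 8 fixation grid,
#' Brownian-direction pursuit at 887 deg^2/s, free viewing, head roll with
#' seven line angles, head yaw over a 3 x 5 grid); cohort size and trial
#' durations are simulation choices sized for quick, well-powered runs.
#'
#' The scenario's dispersion threshold (3 deg) is deliberately about four
#' times the webcam preset's per-axis noise SD: a dispersion threshold below
#' the spread of sample noise cannot admit three consecutive samples and
#' would detect no fixations at all on the noisier stream.
#'
#' @param n_subjects Number of simulated participants.
#' @return A nested scenario list, YAML-serializable.
#' @seealso [run_battery()], [scenario_from_yaml()]
#' @export
default_scenario <- function(n_subjects = 6) {
  list(
    n_subjects = n_subjects,
    screen = list(diagonal_mm = 381, width_px = 1440, height_px = 900,
                  distance_mm = 600),
    trackers = list(
      webcam = list(preset = "webcam", subject_bias_sd_deg = 0.7),
      lab = list(preset = "lab", clock_offset_ms = 150,
                 subject_bias_sd_deg = 0.5)
    ),
    oculomotor = list(),
    detection = list(dispersion_threshold_deg = 3.0, min_points = 3,
                     max_relative_change = 0.5, min_duration_ms = 100),
    sync = list(max_lag_ms = 2000, max_gap_ms = 100),
    min_valid_corr = 30,
    tasks = list(
      large_grid = list(rows = 7, cols = 8, margin_px = 60,
                        trial_dur_ms = 1500, gap_ms = 500),
      smooth_pursuit = list(n_trials = 2, trial_dur_s = 15),
      free_view = list(n_images = 6, duration_ms = 4000),
      head_yaw = list(trial_dur_ms = 2000),
      head_roll = list(trial_dur_ms = 2000)
    )
  )
}

#' Read a scenario from a YAML file
#'
#' Fields present in the file override the defaults of
#' [default_scenario()]; everything else keeps its default.
#'
#' @param path Path to a YAML scenario file.
#' @return A scenario list.
#' @export
scenario_from_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_lists(default_scenario(), user)
}

scenario_tracker <- function(cfg) {
  preset <- cfg$preset
  cfg$preset <- NULL
  cfg$subject_bias_sd_deg <- NULL
  do.call(tracker_preset, c(list(name = preset), cfg))
}

scenario_schedule <- function(task, cfg, seed, geom) {
  switch(task,
    large_grid = do.call(gen_large_grid,
                         c(cfg, list(seed = seed, geom = geom))),
    smooth_pursuit = do.call(gen_pursuit_schedule,
                             c(cfg, list(seed = seed, geom = geom))),
    free_view = do.call(gen_free_view,
                        c(cfg, list(seed = seed, geom = geom))),
    head_roll = do.call(gen_head_task,
                        c(cfg, list(kind = "roll", seed = seed, geom = geom))),
    head_yaw = do.call(gen_head_task,
                       c(cfg, list(kind = "yaw", seed = seed, geom = geom))),
    stop("unknown task: ", task))
}

# pooled RMS-S2S over the valid samples inside a set of fixation intervals
pooled_fixation_rms <- function(deg, fixsel) {
  ssq_x <- 0; ssq_y <- 0; npairs <- 0
  for (k in which(fixsel$selected)) {
    idx <- which(deg$t_ms >= fixsel$start_ms[k] & deg$t_ms <= fixsel$end_ms[k])
    if (length(idx) < 2) next
    v <- deg$valid[idx]
    pair <- v[-length(v)] & v[-1]
    if (!any(pair)) next
    dx <- diff(deg$x_deg[idx])[pair]
    dy <- diff(deg$y_deg[idx])[pair]
    ssq_x <- ssq_x + sum(dx^2)
    ssq_y <- ssq_y + sum(dy^2)
    npairs <- npairs + sum(pair)
  }
  if (npairs == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = sqrt(ssq_x / npairs), y = sqrt(ssq_y / npairs))
}

#' Run the full simulated dual-tracker test battery
#'
#' Simulates every subject through the five battery tasks, observes each
#' task with both tracker models, synchronizes and merges the two streams,
#' detects fixations, computes the quality metrics, and runs the statistical
#' summary stage. All randomness derives from `seed`, so a rerun with the
#' same scenario and seed reproduces the report bit-identically.
#'
#' The analysis follows the standard comparison pipeline: per-task clock lag
#' estimated by time-lag cross-correlation and removed (the timebase-clock
#' tracker, here the webcam, shares the display clock with the stimulus
#' schedule), the high-rate stream resampled onto the low-rate timestamps,
#' per-axis Pearson correlations on jointly valid rows, offset-related
#' fixations selected per tracker by the press-inside-fixation and
#' press-under-500-ms rules, a tracker x eccentricity x task-half Type-II
#' ANOVA on fixation accuracy, tracker x eccentricity ANOVAs on
#' across-subject precision per axis, and paired t tests on head-task data
#' loss.
#'
#' @param scenario A scenario list (see [default_scenario()]).
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, writes
#'   `summary_table5.csv`, `anova_accuracy.csv`, `anova_precision_x.csv`,
#'   `anova_precision_y.csv`, `ttest_loss.csv`, `quality.csv` and `run.log`.
#' @return A list: `summary` (battery-wide metric table), `quality`
#'   (per-subject/task/tracker rows), `correlations`, `accuracy_records`,
#'   `precision`, `anova_accuracy`, `anova_precision_x`,
#'   `anova_precision_y`, `ttest_loss`, `lags`, `scenario`, `seed`.
#' @export
run_battery <- function(scenario = default_scenario(), seed = 1,
                        out_dir = NULL) {
  geom <- with(scenario$screen,
               screen_from_diagonal(diagonal_mm, width_px, height_px,
                                    distance_mm))
  models <- lapply(scenario$trackers, scenario_tracker)
  if (length(models) != 2) stop("scenario needs exactly two trackers",
                                call. = FALSE)
  rates <- vapply(models, function(m) m$rate_hz, 0)
  low_name <- names(models)[which.min(rates)]
  high_name <- names(models)[which.max(rates)]
  truth_rate <- max(500, max(rates))
  det <- do.call(dispersion_params, scenario$detection)
  tasks <- names(scenario$tasks)
  corr_tasks <- intersect(tasks, c("large_grid", "smooth_pursuit", "free_view"))

  quality <- list(); corrs <- list(); acc_rec <- list(); cent <- list()
  rms_rows <- list(); lag_rows <- list()

  for (s in seq_len(scenario$n_subjects)) {
    # each subject carries their own calibration bias around the preset one
    models_s <- models
    for (k in seq_along(models)) {
      nm <- names(models)[k]
      bsd <- scenario$trackers[[nm]]$subject_bias_sd_deg %||% 0
      if (bsd > 0) {
        models_s[[nm]]$bias_deg <- models[[nm]]$bias_deg +
          with_seed(child_seed(seed, 100L * s + k), stats::rnorm(2, 0, bsd))
      }
    }
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      base <- 100L * s + 10L * ti
      sched <- scenario_schedule(task, scenario$tasks[[task]],
                                 child_seed(seed, base + 1L), geom)
      truth <- gen_ground_truth_gaze(sched, scenario$oculomotor,
                                     seed = child_seed(seed, base + 2L),
                                     geom = geom, rate_hz = truth_rate)
      st <- list()
      st[[low_name]] <- observe_tracker(truth, models_s[[low_name]], geom,
                                        seed = child_seed(seed, base + 3L))
      st[[high_name]] <- observe_tracker(truth, models_s[[high_name]], geom,
                                         seed = child_seed(seed, base + 4L))

      lag <- NA_real_
      if (task %in% corr_tasks) {
        merged <- merge_streams(st[[low_name]], st[[high_name]], geom,
                                max_lag_ms = scenario$sync$max_lag_ms,
                                max_gap_ms = scenario$sync$max_gap_ms)
        lag <- attr(merged, "estimated_lag_ms")
        ax <- axis_correlations(merged, min_valid = scenario$min_valid_corr)
        corrs[[length(corrs) + 1L]] <-
          data.frame(subject = s, task = task, r_x = ax$r_x, r_y = ax$r_y,
                     n_valid = ax$n, excluded = ax$excluded)
        lag_rows[[length(lag_rows) + 1L]] <-
          data.frame(subject = s, task = task, lag_ms = lag)
      }

      # bring the high-rate stream onto the schedule clock before detection
      st_det <- st
      if (!is.na(lag)) st_det[[high_name]]$t_ms <- st[[high_name]]$t_ms - lag

      fix <- lapply(st_det, detect_fixations, params = det, geom = geom)

      for (tr in names(models)) {
        loss <- data_loss_fraction(st[[tr]])
        quality[[length(quality) + 1L]] <-
          data.frame(subject = s, task = task, tracker = tr,
                     loss_pct = loss, n_fixations = nrow(fix[[tr]]),
                     n_offset_fixations = NA_integer_)
      }

      if (task == "large_grid") {
        cfg <- scenario$tasks$large_grid
        qi <- length(quality)
        for (tr in names(models)) {
          sel <- select_offset_fixations(fix[[tr]], sched$trials,
                                         truth$presses)
          picked <- sel[sel$selected, , drop = FALSE]
          tgt_deg <- px_to_deg(cbind(picked$target_x_px, picked$target_y_px),
                               geom)
          if (nrow(picked)) {
            acc_rec[[length(acc_rec) + 1L]] <- data.frame(
              subject = s, tracker = tr, trial_id = picked$trial_id,
              error_deg = fixation_accuracy(cbind(picked$cx_deg,
                                                  picked$cy_deg), tgt_deg),
              eccentricity = classify_eccentricity(picked$grid_row,
                                                   picked$grid_col,
                                                   cfg$rows, cfg$cols),
              half = ifelse(picked$trial_id <= nrow(sched$trials) / 2,
                            "first", "second"))
            cent[[length(cent) + 1L]] <- data.frame(
              subject = s, tracker = tr,
              location = paste0("r", picked$grid_row, "c", picked$grid_col),
              eccentricity = classify_eccentricity(picked$grid_row,
                                                   picked$grid_col,
                                                   cfg$rows, cfg$cols),
              cx_deg = picked$cx_deg, cy_deg = picked$cy_deg)
          }
          rms <- pooled_fixation_rms(stream_to_deg(st_det[[tr]], geom), sel)
          rms_rows[[length(rms_rows) + 1L]] <-
            data.frame(subject = s, tracker = tr, rms_x_deg = rms[["x"]],
                       rms_y_deg = rms[["y"]])
          # back-fill offset-fixation count on this task's quality rows
          for (q in seq_len(qi)) {
            if (quality[[q]]$subject == s && quality[[q]]$task == task &&
                quality[[q]]$tracker == tr) {
              quality[[q]]$n_offset_fixations <- sum(sel$selected)
            }
          }
        }
      }
    }
  }

  quality <- do.call(rbind, quality)
  corrs <- do.call(rbind, corrs)
  acc <- do.call(rbind, acc_rec)
  cent <- do.call(rbind, cent)
  rms_df <- do.call(rbind, rms_rows)
  lags <- do.call(rbind, lag_rows)

  prec <- precision_across_subjects(cent)
  ecc_of <- cent$eccentricity[!duplicated(paste(cent$tracker, cent$location))]
  names(ecc_of) <- paste(cent$tracker, cent$location)[
    !duplicated(paste(cent$tracker, cent$location))]
  prec$per_location$eccentricity <-
    ecc_of[paste(prec$per_location$tracker, prec$per_location$location)]

  anova_accuracy <- factorial_anova(acc, c("tracker", "eccentricity", "half"),
                                    "error_deg")
  anova_precision_x <- factorial_anova(prec$per_location,
                                       c("tracker", "eccentricity"), "sd_x")
  anova_precision_y <- factorial_anova(prec$per_location,
                                       c("tracker", "eccentricity"), "sd_y")

  ttest_loss <- do.call(rbind, lapply(
    intersect(tasks, c("head_roll", "head_yaw")), function(task) {
      w <- quality[quality$task == task & quality$tracker == low_name, ]
      l <- quality[quality$task == task & quality$tracker == high_name, ]
      w <- w[order(w$subject), ]; l <- l[order(l$subject), ]
      tt <- tryCatch(paired_ttest(w$loss_pct, l$loss_pct),
                     error = function(e) list(t = NA_real_, df = NA_real_,
                                              p = NA_real_))
      data.frame(task = task, t = tt$t, df = tt$df, p = tt$p)
    }))

  summary <- battery_summary(quality, corrs, acc, prec, tasks, names(models))

  out <- list(summary = summary, quality = quality, correlations = corrs,
              accuracy_records = acc, precision = prec, rms = rms_df,
              anova_accuracy = anova_accuracy,
              anova_precision_x = anova_precision_x,
              anova_precision_y = anova_precision_y,
              ttest_loss = ttest_loss, lags = lags, scenario = scenario,
              seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       na = "")
    }
    wr(summary, "summary_table5.csv")
    wr(anova_accuracy, "anova_accuracy.csv")
    wr(anova_precision_x, "anova_precision_x.csv")
    wr(anova_precision_y, "anova_precision_y.csv")
    wr(ttest_loss, "ttest_loss.csv")
    wr(quality, "quality.csv")
    cfg_file <- tempfile(fileext = ".yaml")
    yaml::write_yaml(scenario, cfg_file)
    cfg_hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    writeLines(c(sprintf("gazebench %s",
                         as.character(utils::packageVersion("gazebench"))),
                 sprintf("seed: %d", seed),
                 sprintf("scenario_md5: %s", cfg_hash),
                 sprintf("subjects: %d", scenario$n_subjects),
                 sprintf("tasks: %s", paste(tasks, collapse = ", "))),
               file.path(out_dir, "run.log"))
  }
  invisible(out)
}

# Table-5-shaped battery summary: one row per (metric, tracker), one column
# per task
battery_summary <- function(quality, corrs, acc, prec, tasks, trackers) {
  cell <- function(vals) if (length(vals) && any(!is.na(vals)))
    round(mean(vals, na.rm = TRUE), 2) else NA_real_
  rows <- list()
  add <- function(metric, tracker, by_task) {
    row <- data.frame(metric = metric, tracker = tracker)
    for (task in tasks) row[[task]] <- by_task[[task]] %||% NA_real_
    rows[[length(rows) + 1L]] <<- row
  }
  for (tr in trackers) {
    add("mean_loss_pct", tr, lapply(stats::setNames(tasks, tasks), function(task) {
      cell(quality$loss_pct[quality$task == task & quality$tracker == tr])
    }))
    add("sd_loss_pct", tr, lapply(stats::setNames(tasks, tasks), function(task) {
      v <- quality$loss_pct[quality$task == task & quality$tracker == tr]
      if (length(v) > 1) round(stats::sd(v), 2) else NA_real_
    }))
  }
  for (axis in c("x", "y")) {
    add(paste0("mean_corr_", axis), "pair",
        lapply(stats::setNames(tasks, tasks), function(task) {
          v <- corrs[corrs$task == task & !corrs$excluded, paste0("r_", axis)]
          if (length(v)) round(cohort_correlation(v), 2) else NA_real_
        }))
  }
  for (tr in trackers) {
    add("total_fixations", tr, lapply(stats::setNames(tasks, tasks), function(task) {
      sum(quality$n_fixations[quality$task == task & quality$tracker == tr])
    }))
    add("total_offset_fixations", tr,
        lapply(stats::setNames(tasks, tasks), function(task) {
          v <- quality$n_offset_fixations[quality$task == task &
                                          quality$tracker == tr]
          if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
        }))
    subj_mean <- tapply(acc$error_deg[acc$tracker == tr],
                        acc$subject[acc$tracker == tr], mean)
    add("mean_accuracy_deg", tr, list(large_grid = round(mean(subj_mean), 2)))
    add("sd_accuracy_deg", tr, list(large_grid = round(stats::sd(subj_mean), 2)))
    ps <- prec$summary[prec$summary$tracker == tr, ]
    add("mean_precision_deg", tr, list(large_grid = round(mean(ps$mean_sd), 2)))
    add("sd_precision_deg", tr, list(large_grid = round(mean(ps$sd_sd), 2)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
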