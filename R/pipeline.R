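#' End-to-end pipelines over recordings and cohorts
#'
#' Convenience wrappers that chain the module stages: filtering ->
#' segmentation -> (windows + features) or (gait events -> stride
#' parameters -> trial aggregation), over a whole simulated or loaded
#' cohort.
#'
#' @name pipeline
NULL

#' Gait spatio-temporal features for every trial of one participant
#'
#' Band-limits both ankle recordings, cuts the non-turning
#' straight-walking trials, detects gait events per leg, derives
#' temporal and height-normalized spatial stride parameters, computes
#' cadence/regularity/symmetry, and aggregates each trial into one
#' feature row.
#'
#' @param rec_L,rec_R ankle [imu_recording()]s (left/right).
#' @param annotations a [task_annotations()] data frame for these
#'   recordings.
#' @param height_m stature; defaults to the recording's.
#' @param ap_channel,sagittal_channel channel names for the
#'   anteroposterior acceleration and sagittal angular rate.
#' @param ... passed to [band_limit()].
#' @return data frame, one row per trial, `trial_index` plus
#'   `<param>_<stat>` columns; trials where gait detection or
#'   aggregation fails are skipped with a warning.
#' @export
gait_trial_features <- function(rec_L, rec_R, annotations,
                                height_m = NULL, ap_channel = "ax",
                                sagittal_channel = "gz", ...) {
  if (is.null(height_m)) height_m <- rec_L$height_m
  fl <- band_limit(rec_L, ...)
  fr <- band_limit(rec_R, ...)
  ann <- annotations[annotations$task == "straight_walking", , drop = FALSE]
  segs_L <- cut_task_segments(fl, ann)
  segs_R <- cut_task_segments(fr, ann)
  trials <- vapply(segs_L, `[[`, 0L, "trial_index")
  out <- list()
  for (i in seq_along(segs_L)) {
    row <- tryCatch({
      sL <- segs_L[[i]]
      sR <- segs_R[[which(vapply(segs_R, `[[`, 0L, "trial_index") ==
                            trials[i])[1]]]
      evL <- detect_gait_events(sL$accel[, ap_channel],
                                sL$gyro[, sagittal_channel], sL$fs)
      evR <- detect_gait_events(sR$accel[, ap_channel],
                                sR$gyro[, sagittal_channel], sR$fs)
      tp <- temporal_parameters(evL, evR)
      tp <- add_spatial_parameters(
        tp,
        spatial_parameters(sL$gyro[, sagittal_channel], sL$fs, evL, height_m),
        spatial_parameters(sR$gyro[, sagittal_channel], sR$fs, evR, height_m))
      reg <- regularity_symmetry(
        sL$accel[, ap_channel], sL$fs,
        mean(tp$steps$step_time[tp$steps$valid]),
        mean(tp$strides$stride_time[tp$strides$valid]))
      cbind(data.frame(trial_index = trials[i]),
            aggregate_trial(tp, regularity = reg))
    }, error = function(e) {
      warning("trial ", trials[i], " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

#' Trial-level gait feature table for a whole cohort
#'
#' Applies [gait_trial_features()] to every participant of a cohort
#' (as returned by [simulate_cohort()] or assembled from
#' [read_imu_csv()] output) and attaches the participant's group and
#' clinical label.
#'
#' @param cohort list with `recordings`, `annotations`,
#'   `participants` (see [simulate_cohort()]).
#' @param label_col column of the participant table to use as label.
#' @return data frame, one row per trial: `participant_id`, `group`,
#'   `label`, `trial_index`, features.
#' @export
cohort_gait_features <- function(cohort, label_col = "label") {
  parts <- cohort$participants
  out <- list()
  for (i in seq_len(nrow(parts))) {
    pid <- parts$participant_id[i]
    ann <- cohort$annotations[cohort$annotations$participant_id == pid, ]
    tf <- gait_trial_features(
      cohort$recordings[[sprintf("%s_ankle_L", pid)]],
      cohort$recordings[[sprintf("%s_ankle_R", pid)]],
      ann, height_m = parts$height_m[i])
    if (is.null(tf) || !nrow(tf)) next
    out[[pid]] <- cbind(data.frame(participant_id = pid,
                                   group = parts$group[i],
                                   label = as.character(parts[[label_col]][i])),
                        tf)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Window-level feature table for an upper-limb cohort
#'
#' Band-limits each wrist recording, cuts the annotated task trials,
#' slides fixed-size windows and extracts the full feature registry,
#' labeling windows from the participant table.
#'
#' @param cohort list with `recordings`, `annotations`, `participants`.
#' @param scheme label scheme recorded on the table.
#' @param window_s,overlap windowing parameters (defaults 3 s, 75%).
#' @param label_col participant-table column holding the label.
#' @return a `feature_table` (one row per window).
#' @export
cohort_window_features <- function(cohort, scheme = "updrs_item_score",
                                   window_s = 3.0, overlap = 0.75,
                                   label_col = "label") {
  parts <- cohort$participants
  windows <- list()
  for (nm in names(cohort$recordings)) {
    rec <- cohort$recordings[[nm]]
    if (!grepl("^wrist", rec$placement)) next
    side <- sub(".*_", "", rec$placement)
    ann <- cohort$annotations[
      cohort$annotations$participant_id == rec$participant_id &
        cohort$annotations$side == side, , drop = FALSE]
    if (!nrow(ann)) next
    filt <- band_limit(rec)
    for (seg in cut_task_segments(filt, ann)) {
      windows <- c(windows, slide_windows(seg, window_s, overlap))
    }
  }
  labels <- data.frame(participant_id = parts$participant_id,
                       value = parts[[label_col]])
  build_feature_table(windows, labels, scheme = scheme)
}
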