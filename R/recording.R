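#' IMU recording container
#'
#' One body-worn sensor's synchronized tri-axial accelerometer and
#' tri-axial gyroscope streams, with sampling rate, placement and
#' participant metadata.  Acceleration is in g, angular rate in deg/s,
#' matching the device-native ranges (nominally +/- 2 g and
#' +/- 500 deg/s at 512 Hz).
#'
#' @param participant_id character scalar.
#' @param placement one of `"wrist_L"`, `"wrist_R"`, `"ankle_L"`,
#'   `"ankle_R"`.
#' @param fs sampling rate in Hz (> 0).
#' @param t numeric vector of timestamps in seconds, strictly
#'   increasing with spacing within 1% of `1/fs`.
#' @param accel n x 3 numeric matrix, columns `ax, ay, az`, units g.
#' @param gyro n x 3 numeric matrix, columns `gx, gy, gz`, units deg/s.
#' @param height_m participant stature in m, or `NA` until the gait
#'   stage needs it.
#' @param check_range if `TRUE`, assert the device-native ranges
#'   (accel within +/- 2 g, gyro within +/- 500 deg/s).
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(participant_id, placement, fs, t, accel, gyro,
                          height_m = NA_real_, check_range = FALSE) {
  placement <- match.arg(placement,
                         c("wrist_L", "wrist_R", "ankle_L", "ankle_R"))
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (length(t) != nrow(accel) || length(t) != nrow(gyro)) {
    stop("t, accel and gyro must share one length")
  }
  if (ncol(accel) != 3 || ncol(gyro) != 3) {
    stop("accel and gyro must have 3 columns")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(dt - 1 / fs) > 0.01 / fs)) {
    stop("timestamp spacing deviates more than 1% from 1/fs; ",
         "resampling is out of scope, supply a uniformly sampled recording")
  }
  if (check_range) {
    if (max(abs(accel)) > 2) stop("acceleration exceeds device range of 2 g")
    if (max(abs(gyro)) > 500) stop("angular rate exceeds device range of 500 deg/s")
  }
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(
    list(participant_id = as.character(participant_id),
         placement = placement, fs = fs, t = as.numeric(t),
         accel = accel, gyro = gyro, height_m = height_m),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s @ %s | %.0f Hz | %.1f s (%d samples)\n",
              x$participant_id, x$placement, x$fs,
              diff(range(x$t)), length(x$t)))
  invisible(x)
}

#' Task annotation table
#'
#' Validates a data frame of task annotations (task name, side, trial
#' index, start/end time, turning flag) against an optional recording.
#'
#' @param df data frame with columns `task`, `side`, `trial_index`,
#'   `t_start`, `t_end`, `is_turning`.
#' @param recording optional [imu_recording()]; when given, every
#'   annotation must lie within the recording's time span.
#' @return the validated data frame, classed `task_annotations`.
#' @export
task_annotations <- function(df, recording = NULL) {
  needed <- c("task", "side", "trial_index", "t_start", "t_end", "is_turning")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tasks <- c("finger_to_nose", "pronation_supination", "leg_agility",
             "toe_tapping", "heel_toe_alternate", "heel_walking",
             "toe_walking", "straight_walking")
  bad <- setdiff(unique(df$task), tasks)
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "))
  if (!all(df$side %in% c("L", "R", "bilateral"))) {
    stop("side must be L, R or bilateral")
  }
  if (any(df$t_end <= df$t_start)) stop("annotations must have t_end > t_start")
  df$is_turning <- as.logical(df$is_turning)
  if (!is.null(recording)) {
    lo <- min(recording$t); hi <- max(recording$t)
    out <- which(df$t_start < lo - 1e-9 | df$t_end > hi + 1e-9)
    if (length(out)) {
      stop("annotation(s) outside recording span [", signif(lo, 4), ", ",
           signif(hi, 4), "] s: row(s) ", paste(out, collapse = ", "),
           " (", paste(sprintf("%s %.2f-%.2f s", df$task[out],
                               df$t_start[out], df$t_end[out]),
                       collapse = "; "), ")")
    }
  }
  class(df) <- c("task_annotations", class(df))
  df
}

#' Read one sensor recording from delimited text
#'
#' Expects the CSV dialect `t,ax,ay,az,gx,gy,gz` (header required;
#' units g and deg/s) and the filename pattern
#' `<participant>_<placement>.csv`, from which participant and
#' placement are taken unless supplied.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz; if `NULL`, estimated as the inverse
#'   median timestamp spacing.
#' @param participant_id,placement override the filename-derived
#'   metadata.
#' @param height_m optional stature in m.
#' @return an [imu_recording()].
#' @export
read_imu_csv <- function(path, fs = NULL, participant_id = NULL,
                         placement = NULL, height_m = NA_real_) {
  df <- read.csv(path)
  needed <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("IMU csv lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  base <- sub("\\.csv$", "", basename(path))
  if (is.null(placement)) {
    m <- regmatches(base, regexpr("(wrist|ankle)_(L|R)$", base))
    if (!length(m)) stop("cannot infer placement from filename '", base,
                         "'; pass placement explicitly")
    placement <- m
  }
  if (is.null(participant_id)) {
    participant_id <- sub(sprintf("_%s$", placement), "", base)
  }
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  imu_recording(participant_id, placement, fs, df$t,
                as.matrix(df[, c("ax", "ay", "az")]),
                as.matrix(df[, c("gx", "gy", "gz")]),
                height_m = height_m)
}

#' Write one sensor recording as delimited text
#'
#' Inverse of [read_imu_csv()]: emits `t,ax,ay,az,gx,gy,gz`.
#'
#' @param recording an [imu_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  df <- data.frame(t = recording$t, recording$accel, recording$gyro)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a task-annotation CSV
#'
#' Columns `task,side,trial_index,t_start,t_end,is_turning`; an
#' optional `participant_id` column allows one file to annotate a
#' whole cohort.
#'
#' @param path CSV file path.
#' @param recording optional recording for span validation.
#' @return a [task_annotations()] data frame.
#' @export
read_annotations_csv <- function(path, recording = NULL) {
  task_annotations(read.csv(path), recording = recording)
}

#' Read the participant table
#'
#' Columns `participant_id,group,height_m` plus any clinical label
#' columns (one column per label scheme).
#'
#' @param path CSV file path.
#' @return a data frame.
#' @export
read_participants_csv <- function(path) {
  df <- read.csv(path)
  needed <- c("participant_id", "group", "height_m")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("participant table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  df
}
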