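#' Synthetic IMU cohort generation
#'
#' Generates labeled wearable-sensor recordings with analytic ground
#' truth for every pipeline stage.  Gait signals are built per stride
#' from the same inverted-pendulum geometry the spatial-parameter
#' estimator assumes (shank excursion `theta` with stride length
#' `2 l sin(theta_sw/2) + 2 l sin(theta_st/2)`, `l = 0.53 * height`),
#' so normalized stride length is recoverable by construction.
#' Freezing-of-gait episodes are rendered as trembling-in-place
#' (6-8 Hz, low amplitude) -- one recognized freezing phenotype, a
#' modeling choice rather than a clinical claim.  Upper-limb task
#' signals are rhythmic rotations whose amplitude, rate and regularity
#' degrade monotonically with an ordinal severity parameter.
#'
#' @name synthdata
NULL

#' Configuration for the gait simulator
#'
#' @param fs sampling rate in Hz (>= 100; device default 512).
#' @param duration_s trial duration in s.
#' @param stride_time_mean,stride_time_sd stride time distribution (s);
#'   mean must lie in `[0.8, 2]`.
#' @param stride_length_norm_mean,stride_length_norm_sd height-normalized
#'   stride length distribution (dimensionless).
#' @param asymmetry right-vs-left fraction applied to stride
#'   amplitude/timing (0 = symmetric).
#' @param height_m participant stature (m).
#' @param freezing_n number of freezing episodes.
#' @param freezing_duration_s length-2 range of episode durations (s).
#' @param dystonia_intrusion amplitude (deg/s) of an irregular 1-3 Hz
#'   sagittal component (0 = none).
#' @param noise_frac additive Gaussian noise SD as a fraction of each
#'   channel's (demeaned) signal RMS.
#' @param seed RNG seed.
#' @return validated list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(fs = 512, duration_s = 30,
                            stride_time_mean = 1.2, stride_time_sd = 0.04,
                            stride_length_norm_mean = 0.60,
                            stride_length_norm_sd = 0.03,
                            asymmetry = 0, height_m = 1.70,
                            freezing_n = 0, freezing_duration_s = c(2, 4),
                            dystonia_intrusion = 0, noise_frac = 0.05,
                            seed = 1) {
  stopifnot(fs >= 100,
            stride_time_mean >= 0.8, stride_time_mean <= 2.0,
            stride_time_sd >= 0, stride_length_norm_sd >= 0,
            asymmetry >= 0, asymmetry < 1,
            height_m > 0, noise_frac >= 0,
            length(freezing_duration_s) == 2)
  structure(as.list(environment()), class = "gait_sim_config")
}

# one leg's stride plan: start times, durations, target lengths.
# Timing asymmetry shifts the right leg's step phase (step-time ratio
# (0.5 + a/2)/(0.5 - a/2)) so both legs keep a common stride rate;
# amplitude asymmetry scales the right stride length.
plan_strides <- function(cfg, leg) {
  sgn <- if (leg == "R") +1 else -1
  tm <- cfg$stride_time_mean
  lm <- cfg$stride_length_norm_mean * (1 + sgn * cfg$asymmetry / 2)
  t0 <- if (leg == "R") {
    0.05 + cfg$stride_time_mean * (0.5 + cfg$asymmetry / 2)
  } else 0.05
  starts <- durs <- lens <- numeric(0)
  t <- t0
  while (TRUE) {
    d <- rnorm(1, tm, cfg$stride_time_sd)
    d <- min(max(d, 0.5 * tm), 1.8 * tm)
    if (t + d > cfg$duration_s - 0.05) break
    sl <- rnorm(1, lm, cfg$stride_length_norm_sd)
    sl <- min(max(sl, 0.1), 2.0)
    starts <- c(starts, t); durs <- c(durs, d); lens <- c(lens, sl)
    t <- t + d
  }
  data.frame(start = starts, stride_time = durs, stride_length_norm = lens)
}

#' Simulate one straight-walking trial (both ankles)
#'
#' Builds each leg's sagittal angular rate stride by stride: a mild
#' negative stance arc and a tall positive mid-swing lobe whose
#' integrals are rescaled on the sample grid to the exact pendulum
#' excursion implied by the per-stride target length, plus sharp
#' negative troughs at IC and FC.  AP acceleration carries an impact
#' transient at each IC (and a smaller one at FC and at contralateral
#' contacts).  Freezing episodes replace whole strides with 6-8 Hz
#' low-amplitude trembling; a dystonic intrusion adds an irregular
#' 1-3 Hz sagittal component; Gaussian sensor noise is added last.
#'
#' @param config a [gait_sim_config()].
#' @return list with `ankle_L`, `ankle_R` ([imu_recording()]s, sagittal
#'   gyro in channel `gz`, AP acceleration in `ax`) and `ground_truth`:
#'   per leg `ic_times`, `fc_times`, a per-stride data frame, and the
#'   freezing windows actually carved out.
#' @export
simulate_gait <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  l_leg <- 0.53 * cfg$height_m
  stance_frac <- 0.6

  legs <- list(L = plan_strides(cfg, "L"), R = plan_strides(cfg, "R"))

  # freezing windows, shared across legs
  fz <- NULL
  if (cfg$freezing_n > 0) {
    lo <- 0.2 * cfg$duration_s
    hi <- 0.85 * cfg$duration_s
    starts <- sort(runif(cfg$freezing_n, lo, hi))
    durs <- runif(cfg$freezing_n, cfg$freezing_duration_s[1],
                  cfg$freezing_duration_s[2])
    fz <- data.frame(start = starts, end = starts + durs)
    # drop overlapping episodes
    if (nrow(fz) > 1) {
      keep <- c(TRUE, fz$start[-1] > fz$end[-nrow(fz)] + 1)
      fz <- fz[keep, ]
    }
  }

  build_leg <- function(plan, leg) {
    sgn <- if (leg == "R") +1 else -1
    gz <- numeric(n)
    ax <- numeric(n)
    # target excursion per stride from the pendulum geometry
    plan$theta <- 2 * asin(pmin(0.999, plan$stride_length_norm *
                                  cfg$height_m / (4 * l_leg)))
    plan$fc <- plan$start + stance_frac * plan$stride_time
    plan$frozen <- FALSE
    if (!is.null(fz)) {
      for (w in seq_len(nrow(fz))) {
        plan$frozen <- plan$frozen |
          (plan$start < fz$end[w] & plan$start + plan$stride_time > fz$start[w])
      }
    }
    idx_of <- function(x) pmin(n, pmax(1L, round(x * cfg$fs) + 1L))
    amp_sw_all <- numeric(0)
    for (k in seq_len(nrow(plan))) {
      if (plan$frozen[k]) next
      T <- plan$stride_time[k]
      th_deg <- plan$theta[k] * 180 / pi
      i1 <- idx_of(plan$start[k])
      ifc <- idx_of(plan$fc[k])
      i2 <- idx_of(plan$start[k] + T)
      u <- (seq(i1, i2) - i1) / (i2 - i1)
      a_st <- th_deg * pi / (2 * stance_frac * T)
      a_sw <- th_deg * pi / (2 * (1 - stance_frac) * T)
      amp_sw_all <- c(amp_sw_all, a_sw)
      w <- numeric(length(u))
      st <- u < stance_frac
      w[st] <- -a_st * sin(pi * u[st] / stance_frac)
      w[!st] <- a_sw * sin(pi * (u[!st] - stance_frac) / (1 - stance_frac))
      # IC / FC troughs (sharp negative spikes for event detection)
      w <- w - 0.8 * a_sw * exp(-((u - 0) / 0.030)^2) -
        0.7 * a_sw * exp(-((u - stance_frac) / 0.022)^2) -
        0.8 * a_sw * exp(-((u - 1) / 0.030)^2)
      gz[i1:i2] <- gz[i1:i2] + w
      # rescale phases to the exact excursion on the sample grid
      for (pass in 1:2) {
        a_stance <- trapz_(gz[i1:ifc], 1 / cfg$fs)
        a_swing <- trapz_(gz[ifc:i2], 1 / cfg$fs)
        if (a_stance < 0) {
          gz[i1:(ifc - 1)] <- gz[i1:(ifc - 1)] * (th_deg / abs(a_stance))
        }
        if (a_swing > 0) {
          gz[ifc:i2] <- gz[ifc:i2] * (th_deg / a_swing)
        }
      }
    }
    amp_ref <- if (length(amp_sw_all)) mean(amp_sw_all) else 100
    # AP acceleration: impact transients at own ICs (+ FC, smaller),
    # amplitude mirrored by the asymmetry fraction
    own_amp <- 0.8 * (1 + sgn * cfg$asymmetry / 2)
    ic_times <- plan$start[!plan$frozen]
    fc_times <- plan$fc[!plan$frozen]
    for (tc in ic_times) ax <- ax + own_amp * exp(-((tt - tc) / 0.015)^2)
    for (tc in fc_times) ax <- ax + 0.35 * own_amp *
        exp(-((tt - tc) / 0.015)^2)
    # smooth locomotor component at the step frequency (two cycles
    # per stride keeps the step-lag autocovariance positive)
    ax <- ax + 0.12 * sin(4 * pi * tt / cfg$stride_time_mean)
    list(gz = gz, ax = ax, plan = plan, amp_ref = amp_ref)
  }

  sim <- list(L = build_leg(legs$L, "L"), R = build_leg(legs$R, "R"))

  # contralateral contact transients (smaller) for step periodicity
  for (leg in c("L", "R")) {
    other <- setdiff(c("L", "R"), leg)
    op <- sim[[other]]$plan
    for (tc in op$start[!op$frozen]) {
      sim[[leg]]$ax <- sim[[leg]]$ax + 0.30 * exp(-((tt - tc) / 0.015)^2)
    }
  }

  finish_leg <- function(s, leg) {
    gz <- s$gz; ax <- s$ax
    # freezing: trembling in place, 6-8 Hz, low amplitude
    if (!is.null(fz)) {
      for (w in seq_len(nrow(fz))) {
        frozen <- s$plan$frozen &
          (s$plan$start < fz$end[w] &
             s$plan$start + s$plan$stride_time > fz$start[w])
        if (!any(frozen)) next
        w0 <- min(s$plan$start[frozen])
        w1 <- max(s$plan$start[frozen] + s$plan$stride_time[frozen])
        ii <- which(tt >= w0 & tt <= w1)
        f_tr <- runif(1, 6, 8)
        ph <- runif(1, 0, 2 * pi)
        env <- sin(pi * (tt[ii] - w0) / (w1 - w0))
        gz[ii] <- 0.05 * s$amp_ref * env * sin(2 * pi * f_tr * tt[ii] + ph)
        ax[ii] <- 0.05 * env * sin(2 * pi * f_tr * tt[ii] + ph + 0.5)
      }
    }
    if (cfg$dystonia_intrusion > 0) {
      dy <- numeric(n)
      for (j in 1:3) {
        fj <- runif(1, 1, 3); pj <- runif(1, 0, 2 * pi)
        dy <- dy + sin(2 * pi * fj * tt + pj)
      }
      am <- 1 + 0.3 * sin(2 * pi * 0.2 * tt + runif(1, 0, 2 * pi))
      gz <- gz + cfg$dystonia_intrusion / 3 * am * dy
    }
    gy <- 0.06 * s$amp_ref * sin(2 * pi * tt / cfg$stride_time_mean +
                                   runif(1, 0, 2 * pi))
    gx <- 0.04 * s$amp_ref * sin(4 * pi * tt / cfg$stride_time_mean +
                                   runif(1, 0, 2 * pi))
    ay <- 0.05 * sin(2 * pi * tt / cfg$stride_time_mean + runif(1, 0, 2 * pi))
    az <- 1 + 0.25 * abs(sin(2 * pi * tt / cfg$stride_time_mean))
    add_noise <- function(x) {
      s_rms <- sqrt(mean((x - mean(x))^2))
      x + rnorm(n, 0, cfg$noise_frac * max(s_rms, 1e-12))
    }
    accel <- cbind(ax = add_noise(ax), ay = add_noise(ay),
                   az = add_noise(az))
    gyro <- cbind(gx = add_noise(gx), gy = add_noise(gy),
                  gz = add_noise(gz))
    imu_recording(participant_id = "sim", placement = paste0("ankle_", leg),
                  fs = cfg$fs, t = tt, accel = accel, gyro = gyro,
                  height_m = cfg$height_m)
  }

  truth_leg <- function(plan) {
    kept <- plan[!plan$frozen, , drop = FALSE]
    # every generated stride carries its own closing IC trough, so IC
    # instants are all stride starts plus each run's closing contact
    ic <- sort(unique(round(c(kept$start, kept$start + kept$stride_time), 6)))
    list(ic_times = ic,
         fc_times = kept$fc,
         strides = data.frame(ic_time = kept$start,
                              stride_time = kept$stride_time,
                              stride_length_norm = kept$stride_length_norm,
                              theta = kept$theta))
  }

  list(ankle_L = finish_leg(sim$L, "L"),
       ankle_R = finish_leg(sim$R, "R"),
       ground_truth = list(L = truth_leg(sim$L$plan),
                           R = truth_leg(sim$R$plan),
                           freezing = fz),
       config = cfg)
}

#' Configuration for the upper-limb task simulator
#'
#' Severity (0 = normal .. 4 = severe) strictly orders the generating
#' parameters: base amplitude and movement rate decrease, per-cycle
#' amplitude decrement (sequence effect) and cycle-time jitter
#' increase.
#'
#' @param task `"pronation_supination"` or `"finger_to_nose"`.
#' @param rate_hz nominal movement rate (Hz).
#' @param amplitude peak angular rate scale (deg/s).
#' @param severity integer 0..4.
#' @param duration_s trial duration (s).
#' @param fs sampling rate (Hz).
#' @param dystonia_overlay amplitude (deg/s) of a sustained
#'   low-frequency torsional drift (0 = none).
#' @param noise_frac Gaussian noise SD as fraction of signal RMS.
#' @param seed RNG seed.
#' @return validated list of class `upper_limb_sim_config`.
#' @export
upper_limb_sim_config <- function(task = c("pronation_supination",
                                           "finger_to_nose"),
                                  rate_hz = 1.5, amplitude = 150,
                                  severity = 0, duration_s = 10, fs = 512,
                                  dystonia_overlay = 0, noise_frac = 0.05,
                                  seed = 1) {
  task <- match.arg(task)
  stopifnot(severity %in% 0:4, rate_hz > 0, amplitude >= 0,
            fs >= 100, duration_s > 0, noise_frac >= 0)
  structure(as.list(environment()), class = "upper_limb_sim_config")
}

#' Simulate one upper-limb task trial (one wrist)
#'
#' The task's rotation axis carries a rhythmic angular-rate signal at
#' the configured rate; severity shrinks amplitude and rate and adds
#' per-cycle decrement and cycle-time jitter, all monotonically.
#'
#' @param config an [upper_limb_sim_config()].
#' @param placement `"wrist_L"` or `"wrist_R"`.
#' @return list with `recording` (an [imu_recording()]), `label`
#'   (= severity), and `cycles` (true per-cycle durations and
#'   amplitudes).
#' @export
simulate_upper_limb <- function(config, placement = "wrist_R") {
  stopifnot(inherits(config, "upper_limb_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  sev <- cfg$severity
  amp0 <- cfg$amplitude * (1 - 0.15 * sev)
  rate <- cfg$rate_hz * (1 - 0.08 * sev)
  jit_cv <- 0.02 + 0.045 * sev
  decr <- 0.015 * sev          # per-cycle amplitude decrement
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (seq_len(n) - 1) / cfg$fs
  main <- numeric(n)
  durs <- amps <- numeric(0)
  t0 <- 0; k <- 0
  while (t0 < cfg$duration_s) {
    d <- rnorm(1, 1 / rate, jit_cv / rate)
    d <- min(max(d, 0.4 / rate), 2.5 / rate)
    a <- amp0 * exp(-decr * k)
    ii <- which(tt >= t0 & tt < min(t0 + d, cfg$duration_s))
    if (length(ii)) {
      main[ii] <- a * sin(2 * pi * (tt[ii] - t0) / d)
    }
    durs <- c(durs, d); amps <- c(amps, a)
    t0 <- t0 + d; k <- k + 1
  }
  axis <- if (cfg$task == "pronation_supination") "gx" else "gz"
  gyro <- cbind(gx = numeric(n), gy = numeric(n), gz = numeric(n))
  gyro[, axis] <- main
  off <- setdiff(c("gx", "gy", "gz"), axis)
  gyro[, off[1]] <- 0.08 * main + rnorm(n, 0, 1)
  gyro[, off[2]] <- 0.05 * main
  if (cfg$dystonia_overlay > 0) {
    gyro[, off[1]] <- gyro[, off[1]] +
      cfg$dystonia_overlay * sin(2 * pi * runif(1, 0.3, 0.8) * tt +
                                   runif(1, 0, 2 * pi))
  }
  accel <- cbind(ax = 0.08 * sin(2 * pi * rate * tt),
                 ay = rep(0, n), az = rep(1, n))
  add_noise <- function(x) {
    s_rms <- sqrt(mean((x - mean(x))^2))
    x + rnorm(n, 0, cfg$noise_frac * max(s_rms, 0.01))
  }
  accel <- apply(accel, 2, add_noise)
  gyro <- apply(gyro, 2, add_noise)
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  rec <- imu_recording("sim", placement, cfg$fs, tt, accel, gyro)
  list(recording = rec, label = sev,
       cycles = data.frame(duration = durs, amplitude = amps))
}

# generating-parameter presets per cohort class; gait classes are
# separable by construction through stride length / timing / episodes
gait_class_params <- function(class) {
  base <- list(stride_length_norm_mean = 0.78, stride_time_mean = 1.05,
               stride_time_sd = 0.02, freezing_n = 0,
               dystonia_intrusion = 0, noise_frac = 0.05)
  sev <- function(s) {
    list(stride_length_norm_mean = 0.78 - 0.13 * s,
         stride_time_mean = min(2, 1.05 + 0.12 * s),
         stride_time_sd = 0.02 + 0.015 * s,
         freezing_n = 0, dystonia_intrusion = 0, noise_frac = 0.05)
  }
  switch(as.character(class),
         control = base,
         "0" = sev(0), "1" = sev(1), "2" = sev(2), "3" = sev(3),
         "fog-" = sev(1),
         "fog+" = modifyList(sev(1), list(freezing_n = 2)),
         "dystonia-" = sev(1),
         "dystonia+" = modifyList(sev(1), list(dystonia_intrusion = 35)),
         stop("unknown gait class: ", class))
}

default_cohort_classes <- function(scheme) {
  switch(scheme,
         gait_score = c("control", "1", "2"),
         fog_binary = c("control", "fog-", "fog+"),
         dystonia_presence = c("control", "dystonia-", "dystonia+"),
         fog_score = c("0", "1", "2", "3"),
         updrs_item_score = c("0", "1", "2", "3", "4"))
}

#' Simulate a labeled cohort, optionally written to disk
#'
#' Generates `n_per_class` participants per class with multiple trials
#' each.  Gait schemes produce two ankle recordings per participant in
#' which straight-walking trials alternate with turning spans; the
#' upper-limb scheme produces two wrist recordings with per-side task
#' trials.  When `dir` is given, the dataset is written in the exact
#' CSV dialects the loaders read (`<participant>_<placement>.csv`,
#' `annotations.csv`, `participants.csv`) plus a `manifest.json` of
#' all generating parameters.
#'
#' @param n_per_class participants per class (>= 2 for grouped CV).
#' @param scheme label scheme (decides the task and default classes).
#' @param classes override the class set.
#' @param n_trials trials per participant.
#' @param trial_duration_s duration of one trial (s).
#' @param fs sampling rate (Hz).
#' @param seed RNG seed; a fixed seed regenerates the identical
#'   cohort.
#' @param dir output directory, or `NULL` for in-memory only.
#' @return list with `recordings` (named list of [imu_recording()]s),
#'   `annotations`, `participants`, `ground_truth`, `manifest`.
#' @export
simulate_cohort <- function(n_per_class, scheme = "gait_score",
                            classes = NULL, n_trials = 3,
                            trial_duration_s = 20, fs = 512, seed = 1,
                            dir = NULL) {
  stopifnot(n_per_class >= 2)
  if (is.null(classes)) classes <- default_cohort_classes(scheme)
  upper <- scheme %in% c("updrs_item_score")
  set.seed(seed)
  recordings <- list()
  ground_truth <- list()
  ann <- list()
  parts <- list()
  manifest <- list(scheme = scheme, classes = classes, seed = seed,
                   n_per_class = n_per_class, n_trials = n_trials,
                   trial_duration_s = trial_duration_s, fs = fs,
                   participants = list())
  pid_n <- 0
  for (cl in classes) {
    for (r in seq_len(n_per_class)) {
      pid_n <- pid_n + 1
      pid <- sprintf("P%02d", pid_n)
      height <- min(1.9, max(1.5, rnorm(1, 1.70, 0.07)))
      pseed <- sample.int(.Machine$integer.max - 1, 1)
      group <- if (cl == "control") "control" else "patient"
      parts[[pid]] <- data.frame(participant_id = pid, group = group,
                                 height_m = height, label = cl)
      manifest$participants[[pid]] <- list(class = cl, height_m = height,
                                           seed = pseed)
      set.seed(pseed)
      if (upper) {
        res <- cohort_upper_participant(pid, cl, n_trials,
                                        trial_duration_s, fs)
      } else {
        res <- cohort_gait_participant(pid, cl, height, n_trials,
                                       trial_duration_s, fs)
      }
      recordings <- c(recordings, res$recordings)
      ground_truth[[pid]] <- res$ground_truth
      res$annotations$participant_id <- pid
      ann[[pid]] <- res$annotations
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  participants <- do.call(rbind, parts)
  rownames(participants) <- NULL
  out <- list(recordings = recordings, annotations = annotations,
              participants = participants, ground_truth = ground_truth,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(recordings)) {
      write_imu_csv(recordings[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
    write.csv(annotations, file.path(dir, "annotations.csv"),
              row.names = FALSE)
    write.csv(participants, file.path(dir, "participants.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# gait participant: per-ankle recording with trials separated by
# annotated turning spans (slow yaw, no usable gait signature)
cohort_gait_participant <- function(pid, class, height, n_trials,
                                    trial_duration_s, fs) {
  pars <- gait_class_params(class)
  # between-subject random effects on top of the class means
  pars$stride_length_norm_mean <- max(0.15, pars$stride_length_norm_mean +
                                        rnorm(1, 0, 0.03))
  pars$stride_time_mean <- min(2, max(0.8, pars$stride_time_mean +
                                        rnorm(1, 0, 0.04)))
  turn_s <- 3
  gap <- round(turn_s * fs)
  acc <- list(L = NULL, R = NULL)
  gyr <- list(L = NULL, R = NULL)
  truth <- list()
  ann <- list()
  t_cursor <- 0
  for (tr in seq_len(n_trials)) {
    cfg <- do.call(gait_sim_config, c(
      pars,
      list(fs = fs, duration_s = trial_duration_s, height_m = height,
           asymmetry = 0.02,
           seed = sample.int(.Machine$integer.max - 1, 1))))
    sim <- simulate_gait(cfg)
    for (leg in c("L", "R")) {
      rec <- sim[[paste0("ankle_", leg)]]
      acc[[leg]] <- rbind(acc[[leg]], rec$accel)
      gyr[[leg]] <- rbind(gyr[[leg]], rec$gyro)
    }
    ann[[length(ann) + 1]] <- data.frame(
      task = "straight_walking", side = "bilateral", trial_index = tr,
      t_start = t_cursor, t_end = t_cursor + trial_duration_s - 1 / fs,
      is_turning = FALSE)
    truth[[tr]] <- list(t_offset = t_cursor,
                        ground_truth = sim$ground_truth)
    t_cursor <- t_cursor + trial_duration_s
    if (tr < n_trials) {
      # turning span: slow rotation, annotated and discarded downstream
      ttg <- (seq_len(gap) - 1) / fs
      yaw <- 40 * sin(pi * ttg / turn_s)
      for (leg in c("L", "R")) {
        acc[[leg]] <- rbind(acc[[leg]],
                            cbind(ax = rnorm(gap, 0, 0.03),
                                  ay = rnorm(gap, 0, 0.03),
                                  az = 1 + rnorm(gap, 0, 0.03)))
        gyr[[leg]] <- rbind(gyr[[leg]],
                            cbind(gx = rnorm(gap, 0, 2),
                                  gy = yaw + rnorm(gap, 0, 2),
                                  gz = rnorm(gap, 0, 2)))
      }
      ann[[length(ann) + 1]] <- data.frame(
        task = "straight_walking", side = "bilateral", trial_index = tr,
        t_start = t_cursor, t_end = t_cursor + turn_s - 1 / fs, is_turning = TRUE)
      t_cursor <- t_cursor + turn_s
    }
  }
  recs <- list()
  for (leg in c("L", "R")) {
    nm <- sprintf("%s_ankle_%s", pid, leg)
    ntot <- nrow(acc[[leg]])
    recs[[nm]] <- imu_recording(pid, paste0("ankle_", leg), fs,
                                (seq_len(ntot) - 1) / fs,
                                acc[[leg]], gyr[[leg]], height_m = height)
  }
  list(recordings = recs, ground_truth = truth,
       annotations = do.call(rbind, ann))
}

# upper-limb participant: one recording per wrist, trials separated by
# short rests; per-side labels equal the participant's class
cohort_upper_participant <- function(pid, class, n_trials,
                                     trial_duration_s, fs) {
  sev <- as.integer(class)
  rest_s <- 2
  gapn <- round(rest_s * fs)
  recs <- list()
  ann <- list()
  truth <- list()
  for (leg in c("L", "R")) {
    acc <- NULL; gyr <- NULL
    t_cursor <- 0
    for (tr in seq_len(n_trials)) {
      cfg <- upper_limb_sim_config(
        task = "pronation_supination", severity = sev,
        duration_s = trial_duration_s, fs = fs,
        seed = sample.int(.Machine$integer.max - 1, 1))
      sim <- simulate_upper_limb(cfg, placement = paste0("wrist_", leg))
      acc <- rbind(acc, sim$recording$accel)
      gyr <- rbind(gyr, sim$recording$gyro)
      ann[[length(ann) + 1]] <- data.frame(
        task = "pronation_supination", side = leg, trial_index = tr,
        t_start = t_cursor, t_end = t_cursor + trial_duration_s - 1 / fs,
        is_turning = FALSE)
      truth[[paste(leg, tr)]] <- sim$cycles
      t_cursor <- t_cursor + trial_duration_s
      if (tr < n_trials) {
        acc <- rbind(acc, cbind(ax = rnorm(gapn, 0, 0.02),
                                ay = rnorm(gapn, 0, 0.02),
                                az = 1 + rnorm(gapn, 0, 0.02)))
        gyr <- rbind(gyr, cbind(gx = rnorm(gapn, 0, 1),
                                gy = rnorm(gapn, 0, 1),
                                gz = rnorm(gapn, 0, 1)))
        t_cursor <- t_cursor + rest_s
      }
    }
    nm <- sprintf("%s_wrist_%s", pid, leg)
    recs[[nm]] <- imu_recording(pid, paste0("wrist_", leg), fs,
                                (seq_len(nrow(acc)) - 1) / fs, acc, gyr)
  }
  ann <- do.call(rbind, ann)
  # annotations for both wrists are per-side; deduplicate by side+trial
  ann <- unique(ann)
  list(recordings = recs, ground_truth = truth, annotations = ann)
}
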