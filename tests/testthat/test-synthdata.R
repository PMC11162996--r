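test_that("default gait simulation produces the expected stride count", {
  sim <- simulate_gait(gait_sim_config(seed = 1))
  for (leg in c("L", "R")) {
    n_str <- nrow(sim$ground_truth[[leg]]$strides)
    expect_gte(n_str, 24)  # 30 s / 1.2 s per stride, minus edge margin
    expect_lte(n_str, 26)
    rec <- sim[[paste0("ankle_", leg)]]
    expect_s3_class(rec, "imu_recording")
    expect_equal(length(rec$t), 30 * 512)
  }
})

test_that("zero asymmetry with zero spread gives identical leg means", {
  cfg <- gait_sim_config(asymmetry = 0, stride_time_sd = 0,
                         stride_length_norm_sd = 0, seed = 2)
  sim <- simulate_gait(cfg)
  L <- sim$ground_truth$L$strides
  R <- sim$ground_truth$R$strides
  expect_equal(mean(L$stride_time), mean(R$stride_time))
  expect_equal(mean(L$stride_length_norm), mean(R$stride_length_norm))
})

test_that("asymmetry orders stride length and shifts the step phase", {
  cfg <- gait_sim_config(asymmetry = 0.2, stride_time_sd = 0,
                         stride_length_norm_sd = 0, seed = 2)
  sim <- simulate_gait(cfg)
  expect_gt(mean(sim$ground_truth$R$strides$stride_length_norm),
            mean(sim$ground_truth$L$strides$stride_length_norm))
  # both legs keep a common stride rate; the right step is delayed
  expect_equal(mean(sim$ground_truth$R$strides$stride_time),
               mean(sim$ground_truth$L$strides$stride_time),
               tolerance = 1e-9)
  offset <- sim$ground_truth$R$ic_times[1] - sim$ground_truth$L$ic_times[1]
  expect_equal(offset, 1.2 * (0.5 + 0.1), tolerance = 1e-6)
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_gait(gait_sim_config(seed = 77))
  b <- simulate_gait(gait_sim_config(seed = 77))
  expect_identical(a$ankle_L$gyro, b$ankle_L$gyro)
  expect_identical(a$ankle_R$accel, b$ankle_R$accel)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_gait(gait_sim_config(seed = 78))
  expect_false(identical(a$ankle_L$gyro, c$ankle_L$gyro))
})

test_that("config invariants are enforced", {
  expect_error(gait_sim_config(fs = 50))
  expect_error(gait_sim_config(stride_time_mean = 0.5))
  expect_error(gait_sim_config(stride_time_sd = -1))
  expect_error(upper_limb_sim_config(severity = 7))
})

test_that("severity strictly orders amplitude and cycle-time jitter", {
  cmp <- vapply(1:100, function(s) {
    s0 <- simulate_upper_limb(upper_limb_sim_config(severity = 0, seed = s,
                                                    fs = 128))
    s4 <- simulate_upper_limb(upper_limb_sim_config(severity = 4, seed = s,
                                                    fs = 128))
    rms <- function(r) sqrt(mean(r$recording$gyro[, "gx"]^2))
    cv <- function(r) sd(r$cycles$duration) / mean(r$cycles$duration)
    rms(s0) > rms(s4) && cv(s4) > cv(s0)
  }, logical(1))
  expect_true(all(cmp))
})

test_that("the task rate surfaces as the dominant frequency feature", {
  cfg <- upper_limb_sim_config(rate_hz = 1, duration_s = 10, fs = 128,
                               seed = 4)
  sim <- simulate_upper_limb(cfg)
  filt <- band_limit(sim$recording)
  seg <- filt
  seg$task <- "pronation_supination"; seg$side <- "R"; seg$trial_index <- 1L
  class(seg) <- c("imu_segment", "imu_recording")
  ws <- slide_windows(seg)
  dom <- vapply(ws, function(w) unname(window_features(w)["gx_dom_freq"]),
                numeric(1))
  expect_lt(abs(median(dom) - 1), 1 / 3 + 1e-9)
})

test_that("zero amplitude degenerates to noise but keeps its label", {
  sim <- simulate_upper_limb(upper_limb_sim_config(amplitude = 0,
                                                   severity = 3, fs = 128,
                                                   seed = 5))
  expect_equal(sim$label, 3)
  expect_lt(sqrt(mean(sim$recording$gyro[, "gx"]^2)), 1)
})

test_that("cohorts have the declared shape and are reproducible", {
  co <- gait_cohort_small()
  expect_equal(nrow(co$participants), 12)
  expect_setequal(unique(co$participants$label), c("control", "1", "2"))
  for (pid in co$participants$participant_id) {
    expect_length(grep(paste0("^", pid, "_"), names(co$recordings)), 2)
  }
  # regeneration with the same seed is identical
  co2 <- simulate_cohort(4, scheme = "gait_score", n_trials = 3,
                         trial_duration_s = 20, fs = 128, seed = 11)
  expect_identical(co$recordings[[1]]$gyro, co2$recordings[[1]]$gyro)
  expect_identical(co$annotations, co2$annotations)
})

test_that("freezing-class cohorts contain episodes per the manifest", {
  co <- simulate_cohort(2, scheme = "fog_binary", classes = c("fog-", "fog+"),
                        n_trials = 1, trial_duration_s = 20, fs = 128,
                        seed = 6)
  fogp <- co$participants$participant_id[co$participants$label == "fog+"]
  for (pid in fogp) {
    gt <- co$ground_truth[[pid]][[1]]$ground_truth
    expect_gte(nrow(gt$freezing), 1)
    # a gap at least as long as the episode shows in the event list
    expect_true(any(diff(gt$L$ic_times) >= 2))
  }
  fogm <- co$participants$participant_id[co$participants$label == "fog-"]
  for (pid in fogm) {
    expect_null(co$ground_truth[[pid]][[1]]$ground_truth$freezing)
  }
})

test_that("written cohorts round-trip through the text loaders", {
  dir <- file.path(tempdir(), "wearimu-cohort")
  on.exit(unlink(dir, recursive = TRUE))
  co <- simulate_cohort(2, scheme = "gait_score", classes = c("control", "2"),
                        n_trials = 2, trial_duration_s = 10, fs = 128,
                        seed = 12, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  parts <- read_participants_csv(file.path(dir, "participants.csv"))
  expect_equal(nrow(parts), 4)
  ann <- read.csv(file.path(dir, "annotations.csv"))
  pid <- parts$participant_id[1]
  rec <- read_imu_csv(file.path(dir, sprintf("%s_ankle_L.csv", pid)),
                      height_m = parts$height_m[1])
  expect_s3_class(rec, "imu_recording")
  expect_equal(rec$participant_id, pid)
  expect_equal(rec$placement, "ankle_L")
  expect_equal(rec$fs, 128, tolerance = 1e-6)
  expect_identical(round(rec$gyro, 6),
                   round(co$recordings[[sprintf("%s_ankle_L", pid)]]$gyro, 6))
  # annotations validate against the loaded recording
  a1 <- task_annotations(ann[ann$participant_id == pid, ], rec)
  expect_s3_class(a1, "task_annotations")
  mani <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mani$scheme, "gait_score")
  expect_length(mani$participants, 4)
})

test_that("running the full pipeline on simulator output recovers the truth", {
  # simulator/estimator consistency on a small seeded sweep
  set.seed(99)
  errs <- t(vapply(1:5, function(i) {
    cfg <- gait_sim_config(stride_time_mean = runif(1, 0.9, 1.6),
                           asymmetry = runif(1, 0, 0.2),
                           noise_frac = runif(1, 0, 0.3),
                           fs = 256, seed = 200 + i)
    sim <- simulate_gait(cfg)
    rec <- band_limit(sim$ankle_L)
    ev <- detect_gait_events(rec$accel[, "ax"], rec$gyro[, "gz"], rec$fs)
    gt <- sim$ground_truth$L$strides
    det <- diff(ev$ic_times)
    m <- vapply(ev$ic_times[-length(ev$ic_times)],
                function(x) which.min(abs(gt$ic_time - x)), 0L)
    sp <- spatial_parameters(rec$gyro[, "gz"], rec$fs, ev, cfg$height_m)
    c(st = mean(abs(det - gt$stride_time[m])),
      sl = abs(mean(sp$stride_length_norm[sp$valid]) -
                 mean(gt$stride_length_norm)) / mean(gt$stride_length_norm))
  }, numeric(2)))
  expect_lt(mean(errs[, "st"]), 1 / 256)
  expect_lt(mean(errs[, "sl"]), 0.05)
})
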