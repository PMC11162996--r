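test_that("events are recovered within 30 ms with no missed or extra cycles", {
  cfg <- gait_sim_config(stride_time_mean = 1.2, seed = 3)
  sim <- simulate_gait(cfg)
  for (leg in c("L", "R")) {
    rec <- band_limit(sim[[paste0("ankle_", leg)]])
    ev <- detect_gait_events(rec$accel[, "ax"], rec$gyro[, "gz"], rec$fs)
    gt <- sim$ground_truth[[leg]]
    # first/last incomplete cycles are dropped, so detection spans the
    # interior IC instants one-for-one
    expect_equal(length(ev$ic_times), length(gt$ic_times) - 2)
    err <- vapply(ev$ic_times,
                  function(x) min(abs(gt$ic_times - x)), numeric(1))
    expect_lt(max(err), 0.030)
    errf <- vapply(ev$fc_times,
                   function(x) min(abs(gt$fc_times - x)), numeric(1))
    expect_lt(max(errf), 0.030)
  }
})

test_that("flat and too-quiet signals raise a no-gait error", {
  expect_error(detect_gait_events(numeric(2000), numeric(2000), 100),
               "no gait")
})

test_that("freezing pauses contain no events and gait resumes around them", {
  cfg <- gait_sim_config(duration_s = 40, freezing_n = 2,
                         freezing_duration_s = c(3, 3.5), seed = 8)
  sim <- simulate_gait(cfg)
  fz <- sim$ground_truth$freezing
  expect_equal(nrow(fz), 2)
  rec <- band_limit(sim$ankle_L)
  ev <- detect_gait_events(rec$accel[, "ax"], rec$gyro[, "gz"], rec$fs)
  all_ev <- c(ev$ic_times, ev$fc_times)
  for (w in seq_len(nrow(fz))) {
    expect_false(any(all_ev > fz$start[w] + 0.3 & all_ev < fz$end[w] - 0.3))
    expect_true(any(all_ev < fz$start[w]))
    expect_true(any(all_ev > fz$end[w]))
  }
  # ground truth carries the carved-out gaps
  expect_equal(sum(diff(sim$ground_truth$L$ic_times) >= 3), 2)
})

test_that("temporal parameters follow the event arithmetic", {
  mk_ev <- function(ic, fc) {
    structure(list(ic_times = ic, fc_times = fc, fs = 512,
                   cadence_implausible = FALSE),
              class = "gait_event_series")
  }
  ic_L <- seq(0, 12, by = 1.2)
  ev_L <- mk_ev(ic_L, head(ic_L, -1) + 0.72)
  ic_R <- ic_L + 0.6
  ev_R <- mk_ev(ic_R, head(ic_R, -1) + 0.72)
  tp <- temporal_parameters(ev_L, ev_R)
  st <- tp$strides
  expect_true(all(abs(st$stride_time - 1.2) < 1e-9))
  expect_true(all(abs(st$stance_time - 0.72) < 1e-9))
  expect_true(all(abs(st$swing_time - 0.48) < 1e-9))
  # symmetric gait: every step is half a stride
  expect_true(all(abs(tp$steps$step_time - 0.6) < 1e-9))

  bad <- mk_ev(ic_L, head(ic_L, -1) + 1.5)  # FC after next IC
  expect_error(temporal_parameters(bad, ev_R), "alternation")
})

test_that("stride-time variability is recovered from the simulator", {
  cfg <- gait_sim_config(stride_time_sd = 0.04, duration_s = 30, seed = 5)
  sim <- simulate_gait(cfg)
  rec <- band_limit(sim$ankle_L)
  ev <- detect_gait_events(rec$accel[, "ax"], rec$gyro[, "gz"], rec$fs)
  got_sd <- sd(diff(ev$ic_times))
  true_sd <- sd(sim$ground_truth$L$strides$stride_time)
  expect_lt(abs(got_sd - true_sd), 0.010)
})

test_that("spatial parameters invert the shared pendulum geometry", {
  cfg <- gait_sim_config(stride_length_norm_mean = 0.60,
                         stride_length_norm_sd = 0.02, seed = 9)
  sim <- simulate_gait(cfg)
  rec <- band_limit(sim$ankle_L)
  ev <- detect_gait_events(rec$accel[, "ax"], rec$gyro[, "gz"], rec$fs)
  sp <- spatial_parameters(rec$gyro[, "gz"], rec$fs, ev, cfg$height_m)
  truth <- mean(sim$ground_truth$L$strides$stride_length_norm)
  expect_lt(abs(mean(sp$stride_length_norm[sp$valid]) - truth) / truth, 0.05)
  expect_equal(sp$stride_velocity_norm,
               sp$stride_length_norm / diff(ev$ic_times))

  # normalization: same normalized gait at a different stature
  cfg2 <- gait_sim_config(stride_length_norm_mean = 0.60,
                          stride_length_norm_sd = 0.02,
                          height_m = 2.0, seed = 9)
  sim2 <- simulate_gait(cfg2)
  rec2 <- band_limit(sim2$ankle_L)
  ev2 <- detect_gait_events(rec2$accel[, "ax"], rec2$gyro[, "gz"], rec2$fs)
  sp2 <- spatial_parameters(rec2$gyro[, "gz"], rec2$fs, ev2, 2.0)
  expect_lt(abs(mean(sp2$stride_length_norm[sp2$valid]) -
                  mean(sp$stride_length_norm[sp$valid])), 0.03)

  expect_error(spatial_parameters(rec$gyro[, "gz"], rec$fs, ev, NA),
               "height")
})

test_that("zero angular excursion yields zero stride length", {
  ev <- structure(list(ic_times = c(0, 1.2, 2.4), fc_times = c(0.7, 1.9),
                       fs = 100, cadence_implausible = FALSE),
                  class = "gait_event_series")
  sp <- spatial_parameters(numeric(300), 100, ev, 1.7)
  expect_equal(sp$stride_length_norm, c(0, 0))
})

test_that("regularity matches a brute-force autocovariance oracle", {
  fs <- 100
  t <- (0:2999) / fs
  stride <- 1.2
  # half-period symmetric waveform: perfect step and stride periodicity
  x <- sin(2 * pi * 2 * t / stride)
  r <- regularity_symmetry(x, fs, stride / 2, stride)
  expect_equal(r$step_regularity, 1, tolerance = 0.02)
  expect_equal(r$stride_regularity, 1, tolerance = 0.02)
  expect_equal(r$step_symmetry, 1, tolerance = 0.03)

  # alternating strong/weak steps: step regularity must fall below
  # stride regularity
  amp <- rep_len(c(1, 0.5), 100)
  y <- numeric(length(t))
  ic <- seq(0.3, 28, by = stride / 2)
  for (i in seq_along(ic)) {
    y <- y + amp[i] * exp(-((t - ic[i]) / 0.05)^2)
  }
  ry <- regularity_symmetry(y, fs, stride / 2, stride)
  expect_lt(ry$step_regularity, ry$stride_regularity)
  expect_lt(ry$step_symmetry, 1)

  # independent oracle: unbiased normalized autocovariance by direct
  # summation at the step lag
  lag <- round(stride / 2 * fs)
  xc <- y - mean(y)
  n <- length(xc)
  oracle <- (sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / (n - lag)) /
    (sum(xc^2) / n)
  expect_equal(ry$step_regularity, oracle, tolerance = 1e-12)

  expect_error(regularity_symmetry(rep(1, 500), fs, 0.6, 1.2), "variance")
})

test_that("white-noise regularity stays near zero", {
  vals <- vapply(1:100, function(s) {
    set.seed(s)
    r <- regularity_symmetry(rnorm(3000), 100, 0.6, 1.2)
    max(abs(c(r$step_regularity, r$stride_regularity)))
  }, numeric(1))
  expect_lt(max(vals), 0.2)
})

test_that("trial aggregation produces the documented statistics", {
  strides <- data.frame(
    leg = rep(c("L", "R"), each = 5),
    ic_time = c(seq(0, 4.8, 1.2), seq(0.6, 5.4, 1.2)),
    stride_time = rep(1.2, 10),
    stance_time = rep(0.72, 10),
    swing_time = rep(0.48, 10),
    stride_length_norm = rep(c(0.60, 0.66), each = 5),
    stride_velocity_norm = rep(c(0.5, 0.55), each = 5),
    valid = TRUE)
  steps <- data.frame(t = seq(0.6, 5.4, 0.6), step_time = 0.6,
                      leg_to = rep_len(c("R", "L"), 9), valid = TRUE)
  sp <- structure(list(strides = strides, steps = steps),
                  class = "stride_parameters")
  agg <- aggregate_trial(sp)
  expect_equal(agg$stride_time_cv, 0)
  expect_equal(agg$stride_time_rl_ratio, 1)
  expect_equal(agg$stride_length_norm_rl_ratio, 1.1, tolerance = 1e-9)
  expect_equal(agg$cadence, 100)

  # permutation invariance to stride order
  sp2 <- sp
  set.seed(1)
  sp2$strides <- sp2$strides[sample(nrow(sp2$strides)), ]
  expect_equal(aggregate_trial(sp2), agg)

  few <- sp
  few$strides <- few$strides[c(1:2, 6:7), ]
  expect_error(aggregate_trial(few), "too few")
})

test_that("degenerate designs fall back to ordinary regression", {
  set.seed(2)
  d <- data.frame(y = rnorm(8), g = rep(c("A", "B"), each = 4), pid = 1:8)
  expect_warning(ct <- compare_groups_mixed(d["y"], d$g, d$pid),
                 "falling back")
  expect_equal(ct$model, "ols")
  expect_true(all(c("estimate", "se", "p_value") %in% names(ct)))
})
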