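# shared fixtures, built in code and cached across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a bare 6-channel window matrix
make_window_matrix <- function(n = 1536, fill = 0) {
  matrix(fill, n, 6, dimnames = list(NULL, c("ax", "ay", "az",
                                             "gx", "gy", "gz")))
}

# recording with a single sinusoid on every channel
make_sine_recording <- function(freq = 5, fs = 512, duration = 30,
                                offset = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t) + offset
  imu_recording("T01", "ankle_L", fs, t,
                cbind(x, x, x), cbind(x, x, x))
}

# small separable 3-class gait cohort used by several tests
gait_cohort_small <- function() {
  cached("gait_cohort", function() {
    co <- simulate_cohort(4, scheme = "gait_score", n_trials = 3,
                          trial_duration_s = 20, fs = 128, seed = 11)
    co$features <- suppressWarnings(cohort_gait_features(co))
    co
  })
}

# 10-subject two-sided upper-limb cohort for side-out CV structure
upper_cohort_small <- function() {
  cached("upper_cohort", function() {
    co <- simulate_cohort(5, scheme = "updrs_item_score",
                          classes = c("0", "3"), n_trials = 2,
                          trial_duration_s = 10, fs = 128, seed = 21)
    co$features <- cohort_window_features(co)
    co
  })
}
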