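#' Window feature extraction
#'
#' Time- and frequency-domain features are computed per channel on the
#' six raw channels (`ax..gz`) plus the two magnitude channels (`amag`,
#' `gmag`, Euclidean norms of the filtered axes).  The registry of
#' feature names is fixed for a given registry version so feature
#' tables are column-stable across windows and cohorts.
#'
#' @name features
NULL

FEATURE_REGISTRY_VERSION <- "1.0"

window_channels <- function(samples) {
  a <- samples[, c("ax", "ay", "az"), drop = FALSE]
  g <- samples[, c("gx", "gy", "gz"), drop = FALSE]
  cbind(samples,
        amag = sqrt(rowSums(a^2)),
        gmag = sqrt(rowSums(g^2)))
}

#' Time-domain features of one window
#'
#' Per channel (6 axes + 2 magnitudes): mean, SD, RMS, range, IQR,
#' skewness, kurtosis, zero-crossing rate (sign changes about the
#' channel mean per sample) and RMS of the first difference (jerk
#' proxy); plus the three pairwise inter-axis Pearson correlations for
#' each sensor modality.  Correlations involving a zero-variance
#' channel are reported as 0 by convention.
#'
#' @param window a `signal_window` from [slide_windows()], or a plain
#'   numeric matrix with columns `ax,ay,az,gx,gy,gz`.
#' @return named numeric vector (all values finite).
#' @export
time_features <- function(window) {
  samples <- if (inherits(window, "signal_window")) window$samples else window
  if (!all(is.finite(samples))) stop("window contains non-finite samples")
  ch <- window_channels(samples)
  out <- numeric(0)
  for (nm in colnames(ch)) {
    x <- ch[, nm]
    m <- mean(x)
    s <- sd(x)
    xc <- x - m
    zc <- if (s > 0) mean(diff(sign(xc)[sign(xc) != 0]) != 0) else 0
    f <- c(mean = m, sd = s, rms = sqrt(mean(x^2)),
           range = diff(range(x)), iqr = unname(diff(quantile(x, c(.25, .75)))),
           skew = if (s > 0) e1071::skewness(x, type = 2) else 0,
           kurt = if (s > 0) e1071::kurtosis(x, type = 2) else 0,
           zcr = zc,
           jerk_rms = sqrt(mean(diff(x)^2)))
    names(f) <- paste(nm, names(f), sep = "_")
    out <- c(out, f)
  }
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
  }
  pairs <- list(c("ax", "ay"), c("ax", "az"), c("ay", "az"),
                c("gx", "gy"), c("gx", "gz"), c("gy", "gz"))
  for (p in pairs) {
    out[paste0("cor_", p[1], "_", p[2])] <- safe_cor(ch[, p[1]], ch[, p[2]])
  }
  out
}

# Hann-windowed periodogram of one channel; single taper on the full
# window (Welch segmentation at 3 s would destroy sub-1 Hz resolution)
hann_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- (x - mean(x)) * w
  X <- fft(xw)
  nf <- floor(n / 2) + 1
  p <- Mod(X[seq_len(nf)])^2 / (fs * sum(w^2))
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * fs / n, power = p)
}

#' Frequency-domain features of one window
#'
#' Per channel: dominant frequency in the 0.3-20 Hz analysis band,
#' power at the dominant frequency, total band power, relative powers
#' in 0.3-3, 3-8, 8-12 and 12-20 Hz, spectral centroid, and spectral
#' entropy normalized to `[0, 1]`.  Spectra come from one
#' Hann-windowed periodogram of the full window.  Channels with zero
#' band power report 0 for all spectral features by convention.
#'
#' @param window a `signal_window` or numeric matrix (see
#'   [time_features()]).
#' @param fs sampling rate in Hz; taken from the window when absent.
#' @return named numeric vector.
#' @export
frequency_features <- function(window, fs = NULL) {
  if (inherits(window, "signal_window")) {
    samples <- window$samples
    if (is.null(fs)) fs <- window$fs
  } else samples <- window
  if (is.null(fs)) stop("fs required for a bare matrix")
  if (fs <= 2 * 20) stop("fs too low for the 20 Hz band edge")
  if (!all(is.finite(samples))) stop("window contains non-finite samples")
  if (nrow(samples) < fs) stop("window shorter than 1 s")
  ch <- window_channels(samples)
  bands <- rbind(c(0.3, 3), c(3, 8), c(8, 12), c(12, 20))
  out <- numeric(0)
  for (nm in colnames(ch)) {
    pg <- hann_periodogram(ch[, nm], fs)
    inband <- pg$freq >= 0.3 & pg$freq <= 20
    fr <- pg$freq[inband]
    pw <- pg$power[inband]
    tot <- sum(pw)
    if (tot <= 0) {
      f <- c(dom_freq = 0, dom_power = 0, band_power = 0,
             relpow_0.3_3 = 0, relpow_3_8 = 0, relpow_8_12 = 0,
             relpow_12_20 = 0, centroid = 0, entropy = 0)
    } else {
      i <- which.max(pw)
      rel <- apply(bands, 1, function(b) sum(pw[fr >= b[1] & fr < b[2]]) / tot)
      pn <- pw / tot
      pn <- pn[pn > 0]
      ent <- if (length(pn) > 1) -sum(pn * log(pn)) / log(length(pw)) else 0
      f <- c(dom_freq = fr[i], dom_power = pw[i], band_power = tot,
             relpow_0.3_3 = rel[1], relpow_3_8 = rel[2],
             relpow_8_12 = rel[3], relpow_12_20 = rel[4],
             centroid = sum(fr * pw) / tot, entropy = ent)
    }
    names(f) <- paste(nm, names(f), sep = "_")
    out <- c(out, f)
  }
  out
}

#' Full feature vector of one window
#'
#' Concatenates [time_features()] and [frequency_features()].
#'
#' @inheritParams frequency_features
#' @return named numeric vector (150 features for registry 1.0).
#' @export
window_features <- function(window, fs = NULL) {
  c(time_features(window), frequency_features(window, fs))
}

#' Names and layout of the feature registry
#'
#' @return list with `version` and the ordered `feature_names`
#'   character vector, as produced by [window_features()].
#' @export
feature_registry <- function() {
  dummy <- matrix(rnorm(512 * 6), ncol = 6,
                  dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  list(version = FEATURE_REGISTRY_VERSION,
       feature_names = names(window_features(dummy, fs = 512)))
}

#' Assemble a labeled feature table from windows
#'
#' One row per window: metadata columns, the feature registry columns,
#' and the clinical label resolved from the label table for the
#' window's participant (and side, when the label table has a `side`
#' column with non-`NA` entries for that participant).  Control
#' participants must carry the literal label `"control"` in the label
#' table; it is never merged with a patient score.
#'
#' @param windows list of `signal_window` objects.
#' @param labels data frame with `participant_id`, optional `side`,
#'   and a `value` column holding the clinical label.
#' @param scheme label scheme name, one of `"updrs_item_score"`,
#'   `"dystonia_presence"`, `"fog_binary"`, `"fog_score"`,
#'   `"gait_score"`; recorded as an attribute.
#' @return data frame of class `feature_table` with attributes
#'   `scheme` and `registry_version`.
#' @export
build_feature_table <- function(windows, labels,
                                scheme = c("updrs_item_score",
                                           "dystonia_presence", "fog_binary",
                                           "fog_score", "gait_score")) {
  scheme <- match.arg(scheme)
  stopifnot(length(windows) > 0)
  feats <- t(vapply(windows, window_features,
                    numeric(length(window_features(windows[[1]])))))
  meta <- data.frame(
    participant_id = vapply(windows, `[[`, "", "participant_id"),
    placement = vapply(windows, `[[`, "", "placement"),
    task = vapply(windows, function(w) as.character(w$task %||% NA), ""),
    side = vapply(windows, function(w) as.character(w$side %||% NA), ""),
    trial_index = vapply(windows, function(w) as.integer(w$trial_index %||% NA),
                         integer(1)),
    window_start_s = vapply(windows, `[[`, 0, "window_start_s"))
  lab <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cand <- labels[labels$participant_id == meta$participant_id[i], ,
                   drop = FALSE]
    if ("side" %in% names(cand) && any(!is.na(cand$side))) {
      cand <- cand[is.na(cand$side) | cand$side == meta$side[i], ,
                   drop = FALSE]
    }
    if (nrow(cand) < 1) {
      stop("no label for sample (participant ", meta$participant_id[i],
           ", side ", meta$side[i], ", task ", meta$task[i], ")")
    }
    lab[i] <- as.character(cand$value[1])
  }
  out <- cbind(meta, label = lab, as.data.frame(feats))
  if (anyNA(out[, -seq_len(ncol(meta))])) stop("NA in emitted feature table")
  attr(out, "scheme") <- scheme
  attr(out, "registry_version") <- FEATURE_REGISTRY_VERSION
  class(out) <- c("feature_table", class(out))
  out
}

#' Feature columns of a feature table
#'
#' @param table a `feature_table` (or any data frame).
#' @return character vector of feature column names (numeric columns
#'   that are not metadata).
#' @export
feature_columns <- function(table) {
  meta <- c("participant_id", "placement", "task", "side", "trial_index",
            "window_start_s", "label", "group", "trial")
  setdiff(names(table)[vapply(table, is.numeric, TRUE)], meta)
}
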