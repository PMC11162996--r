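#' Gait event detection and stride-level parameters
#'
#' Shank-mounted inertial sensors show a characteristic sagittal-plane
#' angular-rate signature in walking: a tall positive lobe at
#' mid-swing flanked by negative troughs at initial contact (IC, heel
#' strike) and final contact (FC, foot off).  Detection anchors on the
#' mid-swing peaks and localizes IC/FC at the trough pattern between
#' consecutive swings, refining each event towards the impact
#' transient visible in anteroposterior (AP) acceleration.
#'
#' @name gait
NULL

# indices of interior local maxima (strict on the left, >= on the right
# so plateaus keep their first sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# topographic prominence of peaks at index `pk` of x: drop to the
# lowest saddle separating the peak from higher ground on each side
peak_prominence <- function(x, pk) {
  vapply(pk, function(i) {
    hl <- which(x[seq_len(i - 1)] > x[i])
    lo_l <- if (length(hl)) min(x[max(hl):i]) else min(x[seq_len(i)])
    hr <- which(x[(i + 1):length(x)] > x[i])
    lo_r <- if (length(hr)) min(x[i:(i + min(hr))]) else min(x[i:length(x)])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
}

# greedy minimum-separation enforcement, keeping taller peaks
enforce_separation <- function(pk, height, min_gap) {
  keep <- logical(length(pk))
  for (i in order(-height)) {
    if (!any(keep & abs(pk - pk[i]) < min_gap)) keep[i] <- TRUE
  }
  sort(pk[keep])
}

trapz_ <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

#' Detect initial and final foot contacts from one shank sensor
#'
#' Mid-swing peaks are located on the sagittal angular rate
#' (prominence-thresholded local maxima with a minimum separation,
#' default 0.4 s).  Within each inter-swing interval the first
#' sufficiently deep angular-rate minimum after the swing peak is the
#' IC and the minimum immediately preceding the next swing peak is the
#' FC; each is refined to the nearest salient AP-acceleration peak
#' within +/- 100 ms.  First and last incomplete cycles are dropped by
#' construction (events only come from complete inter-swing intervals).
#'
#' @param ap_accel anteroposterior shank acceleration (g), filtered.
#' @param sagittal_gyro sagittal-plane angular rate (deg/s), filtered;
#'   mid-swing must be the positive direction.
#' @param fs sampling rate in Hz.
#' @param min_separation_s minimum spacing between swing peaks (s).
#' @param prominence_frac swing peaks must exceed this fraction of the
#'   largest peak prominence.
#' @param depth_frac a trough qualifies as an event candidate when at
#'   least this fraction as deep as the deepest trough of its interval.
#' @param refine_s half-width of the AP-acceleration refinement window.
#' @return `gait_event_series`: list with `ic_times`, `fc_times` (s, on
#'   the sample grid of the inputs), `fs` and a `cadence_implausible`
#'   flag set when the implied cadence leaves 30-180 steps/min.
#' @export
detect_gait_events <- function(ap_accel, sagittal_gyro, fs,
                               min_separation_s = 0.4,
                               prominence_frac = 0.3,
                               depth_frac = 0.25,
                               refine_s = 0.1) {
  stopifnot(length(ap_accel) == length(sagittal_gyro), fs > 0)
  g <- sagittal_gyro
  pk <- local_maxima(g)
  pk <- pk[g[pk] > 0]
  if (length(pk) >= 2) {
    prom <- peak_prominence(g, pk)
    pk <- pk[prom >= prominence_frac * max(prom)]
    pk <- enforce_separation(pk, g[pk], min_separation_s * fs)
  }
  if (length(pk) < 2) stop("no gait detected: fewer than 2 swing peaks")

  refine <- function(i0) {
    w <- max(1L, i0 - round(refine_s * fs)):min(length(ap_accel),
                                                i0 + round(refine_s * fs))
    cand <- local_maxima(ap_accel[w])
    if (!length(cand)) return(i0)
    cand <- w[cand]
    # salient = within 50% of the tallest peak height above the local
    # floor (offset-independent)
    h <- ap_accel[cand] - min(ap_accel[w])
    sal <- cand[h >= 0.5 * max(h)]
    sal[which.min(abs(sal - i0))]
  }

  ic <- fc <- integer(0)
  for (k in seq_len(length(pk) - 1)) {
    seg <- g[pk[k]:pk[k + 1]]
    mins <- local_maxima(-seg)
    if (!length(mins)) next
    vals <- seg[mins]
    deep <- mins[vals < 0 & vals <= depth_frac * min(vals)]
    if (length(deep) < 2) next
    ic_k <- refine(pk[k] + deep[1] - 1L)
    fc_k <- refine(pk[k] + deep[length(deep)] - 1L)
    if (fc_k <= ic_k) next
    ic <- c(ic, ic_k)
    fc <- c(fc, fc_k)
  }
  if (length(ic) < 1) stop("no gait detected: no contact events localized")
  res <- list(ic_times = (ic - 1) / fs, fc_times = (fc - 1) / fs, fs = fs,
              cadence_implausible = FALSE)
  if (length(ic) >= 2) {
    cad <- 120 / median(diff(res$ic_times))
    if (cad > 180 || cad < 30) {
      res$cadence_implausible <- TRUE
      warning("implausible cadence: ", round(cad), " steps/min")
    }
  }
  class(res) <- "gait_event_series"
  res
}

#' @export
print.gait_event_series <- function(x, ...) {
  cat(sprintf("<gait_event_series> %d IC / %d FC events over %.1f s%s\n",
              length(x$ic_times), length(x$fc_times),
              diff(range(c(x$ic_times, x$fc_times))),
              if (x$cadence_implausible) " [implausible cadence]" else ""))
  invisible(x)
}

check_alternation <- function(ev) {
  nI <- length(ev$ic_times)
  for (k in seq_len(min(nI - 1, length(ev$fc_times)))) {
    if (!(ev$ic_times[k] < ev$fc_times[k] &&
          ev$fc_times[k] < ev$ic_times[k + 1])) {
      stop("IC/FC alternation violated at event index ", k)
    }
  }
  invisible(TRUE)
}

#' Temporal gait parameters from both legs' event series
#'
#' Stride time is same-leg IC-to-IC, stance is IC to the next same-leg
#' FC, swing is FC to the next same-leg IC, and step time is IC of one
#' leg to the next contralateral IC.  Strides whose duration exceeds
#' `gap_factor` times the leg's median stride time (e.g. those
#' spanning a freezing pause) are flagged invalid and excluded from
#' aggregates.
#'
#' @param events_L,events_R `gait_event_series` for the left and right
#'   leg.
#' @param gap_factor no-gait gap threshold as a multiple of the median
#'   stride time.
#' @return `stride_parameters`: list with a per-stride data frame
#'   (`strides`) and a per-step data frame (`steps`).
#' @export
temporal_parameters <- function(events_L, events_R, gap_factor = 1.8) {
  one_leg <- function(ev, leg) {
    check_alternation(ev)
    nstr <- length(ev$ic_times) - 1L
    if (nstr < 1) return(NULL)
    k <- seq_len(nstr)
    d <- data.frame(
      leg = leg,
      ic_time = ev$ic_times[k],
      stride_time = diff(ev$ic_times),
      stance_time = ev$fc_times[k] - ev$ic_times[k],
      swing_time = ev$ic_times[k + 1] - ev$fc_times[k])
    d$valid <- d$stride_time <= gap_factor * median(d$stride_time)
    d
  }
  strides <- rbind(one_leg(events_L, "L"), one_leg(events_R, "R"))
  ics <- rbind(data.frame(t = events_L$ic_times, leg = "L"),
               data.frame(t = events_R$ic_times, leg = "R"))
  ics <- ics[order(ics$t), ]
  steps <- NULL
  if (nrow(ics) >= 2) {
    alt <- which(ics$leg[-1] != ics$leg[-nrow(ics)])
    if (length(alt)) {
      steps <- data.frame(t = ics$t[alt], step_time = diff(ics$t)[alt],
                          leg_to = ics$leg[alt + 1])
      steps$valid <- steps$step_time <= gap_factor * median(steps$step_time)
    }
  }
  structure(list(strides = strides, steps = steps),
            class = "stride_parameters")
}

#' Spatial gait parameters from the sagittal angular rate
#'
#' Models the shank as an inverted pendulum of length
#' `0.53 * height_m`.  Per stride, angular rate is drift-corrected by
#' subtracting the constant forcing zero net rotation over the full
#' stride (the shank returns to the same orientation each cycle), then
#' integrated (trapezoid rule) over stance (IC to FC) and swing (FC to
#' next IC) to give the segment excursions `theta`.  Stride length is
#' `2 l sin(theta_swing/2) + 2 l sin(theta_stance/2)`, normalized by
#' stature; stride velocity is normalized length over stride time.
#' Excursions beyond pi/2 flag the stride implausible (excluded from
#' aggregates).
#'
#' @param sagittal_gyro sagittal angular rate (deg/s) for this leg,
#'   sample k at time `(k - 1) / fs`.
#' @param fs sampling rate in Hz.
#' @param events `gait_event_series` for the same leg.
#' @param height_m participant stature (m); required.
#' @return data frame, one row per stride: `ic_time`,
#'   `stride_length_norm`, `stride_velocity_norm`, `theta_swing`,
#'   `theta_stance`, `valid`.
#' @export
spatial_parameters <- function(sagittal_gyro, fs, events, height_m) {
  if (is.na(height_m) || height_m <= 0) {
    stop("participant height required for spatial parameters")
  }
  check_alternation(events)
  l_leg <- 0.53 * height_m
  dx <- 1 / fs
  idx <- function(tt) pmin(length(sagittal_gyro), pmax(1L, round(tt * fs) + 1L))
  nstr <- length(events$ic_times) - 1L
  out <- vector("list", nstr)
  for (k in seq_len(nstr)) {
    i1 <- idx(events$ic_times[k])
    i2 <- idx(events$ic_times[k + 1])
    ifc <- idx(events$fc_times[k])
    stride_time <- events$ic_times[k + 1] - events$ic_times[k]
    seg <- sagittal_gyro[i1:i2]
    bias <- trapz_(seg, dx) / ((i2 - i1) * dx)
    g2 <- sagittal_gyro - bias
    th_st <- abs(trapz_(g2[i1:ifc], dx)) * pi / 180
    th_sw <- abs(trapz_(g2[ifc:i2], dx)) * pi / 180
    sl <- 2 * l_leg * (sin(th_sw / 2) + sin(th_st / 2))
    out[[k]] <- data.frame(
      ic_time = events$ic_times[k],
      stride_length_norm = sl / height_m,
      stride_velocity_norm = (sl / height_m) / stride_time,
      theta_swing = th_sw, theta_stance = th_st,
      valid = th_sw <= pi / 2 && th_st <= pi / 2)
  }
  do.call(rbind, out)
}

#' Step/stride regularity and step symmetry
#'
#' Computes the unbiased, normalized autocovariance of the AP
#' acceleration; step regularity is its value at the lag nearest the
#' mean step time, stride regularity at the lag nearest the mean
#' stride time, and step symmetry their ratio (clipped to `[0, 2]`,
#' flagged when clipping occurs).
#'
#' @param ap_accel AP acceleration of the trial (filtered).
#' @param fs sampling rate in Hz.
#' @param mean_step_time,mean_stride_time trial means in s.
#' @return named list `step_regularity`, `stride_regularity`,
#'   `step_symmetry`, `clipped`.
#' @export
regularity_symmetry <- function(ap_accel, fs, mean_step_time,
                                mean_stride_time) {
  x <- ap_accel - mean(ap_accel)
  n <- length(x)
  if (var(x) == 0) stop("zero-variance signal: regularity undefined")
  lag_step <- round(mean_step_time * fs)
  lag_stride <- round(mean_stride_time * fs)
  if (n <= lag_stride + 1) stop("trial too short for the stride lag")
  rho <- function(l) {
    (sum(x[1:(n - l)] * x[(l + 1):n]) / (n - l)) / (sum(x^2) / n)
  }
  sr <- rho(lag_step)
  lr <- rho(lag_stride)
  sym_raw <- if (lr != 0) sr / lr else Inf
  sym <- min(max(sym_raw, 0), 2)
  list(step_regularity = sr, stride_regularity = lr,
       step_symmetry = sym, clipped = !identical(sym, sym_raw))
}

#' Trial-level aggregation of gait parameters
#'
#' For each spatio-temporal parameter: mean, SD, coefficient of
#' variation and right/left ratio of leg means, over valid strides;
#' cadence is `60 / mean(step_time)` steps/min; regularity and
#' symmetry are passed through.  The result is one feature row per
#' trial.
#'
#' @param stride_params a `stride_parameters` from
#'   [temporal_parameters()], optionally with spatial columns merged
#'   in via [add_spatial_parameters()].
#' @param regularity optional result of [regularity_symmetry()].
#' @param min_strides minimum valid strides required per leg.
#' @return one-row data frame with columns `<param>_<stat>` plus
#'   `cadence` and any regularity fields.
#' @export
aggregate_trial <- function(stride_params, regularity = NULL,
                            min_strides = 3) {
  st <- stride_params$strides
  st <- st[st$valid, , drop = FALSE]
  if (is.null(st) || min(table(factor(st$leg, c("L", "R")))) < min_strides) {
    stop("too few valid strides per leg (need >= ", min_strides, ")")
  }
  params <- intersect(c("stride_time", "stance_time", "swing_time",
                        "stride_length_norm", "stride_velocity_norm"),
                      names(st))
  out <- list()
  for (p in params) {
    v <- st[[p]]
    m <- mean(v)
    out[[paste0(p, "_mean")]] <- m
    out[[paste0(p, "_sd")]] <- sd(v)
    out[[paste0(p, "_cv")]] <- if (m != 0) sd(v) / m else NA_real_
    mr <- mean(st[[p]][st$leg == "R"])
    ml <- mean(st[[p]][st$leg == "L"])
    out[[paste0(p, "_rl_ratio")]] <- mr / ml
  }
  steps <- stride_params$steps
  if (!is.null(steps)) {
    if (min(table(factor(steps$leg_to[steps$valid], c("L", "R")))) < 2) {
      stop("too few valid steps towards each side for a right/left ratio")
    }
    sv <- steps$step_time[steps$valid]
    out$step_time_mean <- mean(sv)
    out$step_time_sd <- sd(sv)
    out$step_time_cv <- sd(sv) / mean(sv)
    mr <- mean(steps$step_time[steps$valid & steps$leg_to == "R"])
    ml <- mean(steps$step_time[steps$valid & steps$leg_to == "L"])
    out$step_time_rl_ratio <- mr / ml
    out$cadence <- 60 / mean(sv)
  }
  if (!is.null(regularity)) {
    out$step_regularity <- regularity$step_regularity
    out$stride_regularity <- regularity$stride_regularity
    out$step_symmetry <- regularity$step_symmetry
  }
  as.data.frame(out)
}

#' Merge spatial parameters into a stride-parameter set
#'
#' @param stride_params result of [temporal_parameters()].
#' @param spatial_L,spatial_R results of [spatial_parameters()] for
#'   each leg.
#' @return the `stride_parameters` with spatial columns joined by leg
#'   and IC time; strides flagged implausible by the spatial stage are
#'   marked invalid.
#' @export
add_spatial_parameters <- function(stride_params, spatial_L, spatial_R) {
  st <- stride_params$strides
  join <- function(st, sp, leg) {
    sel <- st$leg == leg
    i <- match(round(st$ic_time[sel], 6), round(sp$ic_time, 6))
    for (col in c("stride_length_norm", "stride_velocity_norm")) {
      st[[col]][sel] <- sp[[col]][i]
    }
    st$valid[sel] <- st$valid[sel] & (sp$valid[i] %in% TRUE)
    st
  }
  st$stride_length_norm <- NA_real_
  st$stride_velocity_norm <- NA_real_
  st <- join(st, spatial_L, "L")
  st <- join(st, spatial_R, "R")
  st <- st[complete.cases(st[, c("stride_length_norm")]), ]
  stride_params$strides <- st
  stride_params
}

#' Mixed-effects group contrasts of trial-level gait parameters
#'
#' For each gait parameter, fits a mixed-effects model with group as a
#' fixed effect and a per-participant random intercept (repeated
#' trials per participant), and reports all pairwise group contrasts
#' with estimates, standard errors and p-values, flagged at p < 0.01
#' and p < 0.001.  Designs that cannot support a random intercept
#' (singular fit, e.g. one trial per participant everywhere) fall back
#' to ordinary least squares with a logged flag.
#'
#' @param trial_features data frame of one row per trial with numeric
#'   parameter columns.
#' @param group_labels factor/character of group membership per trial.
#' @param participant_ids participant identifier per trial.
#' @param params which columns to analyze (default: all numeric).
#' @return data frame: `parameter`, `contrast`, `estimate`, `se`,
#'   `p_value`, `sig_0.01`, `sig_0.001`, `model` ("mixed" or "ols").
#' @export
compare_groups_mixed <- function(trial_features, group_labels,
                                 participant_ids, params = NULL) {
  group_labels <- factor(group_labels)
  if (nlevels(group_labels) < 2) stop("need >= 2 groups")
  if (is.null(params)) {
    params <- names(trial_features)[vapply(trial_features, is.numeric, TRUE)]
  }
  res <- list()
  for (p in params) {
    d <- data.frame(y = trial_features[[p]], group = group_labels,
                    pid = factor(participant_ids))
    d <- d[is.finite(d$y), ]
    fit <- NULL
    model <- "mixed"
    fit <- tryCatch({
      m <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ group + (1 | pid), data = d)))
      if (lme4::isSingular(m, tol = 1e-5)) stop("singular fit")
      m
    }, error = function(e) NULL)
    if (is.null(fit)) {
      model <- "ols"
      warning("parameter '", p, "': random-intercept fit singular or ",
              "failed; falling back to ordinary regression")
      fit <- lm(y ~ group, data = d)
    }
    em <- suppressMessages(
      emmeans::emmeans(fit, pairwise ~ group, lmer.df = "satterthwaite"))
    ct <- as.data.frame(em$contrasts)
    res[[p]] <- data.frame(parameter = p, contrast = as.character(ct$contrast),
                           estimate = ct$estimate, se = ct$SE,
                           p_value = ct$p.value,
                           sig_0.01 = ct$p.value < 0.01,
                           sig_0.001 = ct$p.value < 0.001,
                           model = model)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
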