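# Actigraphy from the wrist-worn accelerometer: acceleration magnitude,
# 1-minute epoch activity with imputation of out-of-range gaps, and the
# non-parametric circadian metrics L5, M10, IS, IV and relative amplitude.
#
# Rhythm metrics are computed on per-minute movement intensity (the mean of
# per-second standard deviations of magnitude): mean magnitude itself hovers
# near 1 g for every posture, so intensity, not level, carries the rhythm.

#' Acceleration magnitude
#'
#' Per-sample Euclidean norm `A = sqrt(x^2 + y^2 + z^2)` of the tri-axial
#' acceleration, an orientation-independent measure of movement force
#' (about 1 g at rest).
#'
#' @param stream a `sensor_stream`, or a data.frame with columns x, y, z and
#'   optionally time.
#' @return data.table `time`, `A` (g).
#' @export
magnitude <- function(stream) {
  acc <- if (inherits(stream, "sensor_stream")) stream$accel else as.data.table(stream)
  if (nrow(acc) == 0) stop("no acceleration records")
  tm <- if ("time" %in% names(acc)) acc$time else seq_len(nrow(acc)) - 1
  data.table(time = tm, A = sqrt(acc$x^2 + acc$y^2 + acc$z^2))
}

#' One-minute epoch activity
#'
#' Aligns the magnitude series to clock minutes. Within each minute the mean
#' magnitude (`mean_g`) and the per-second sub-window statistics (minimum and
#' maximum of per-second means, and the mean of per-second standard
#' deviations, `std_g`) are computed. Minutes without samples (out-of-home
#' gaps, outages) are filled per the imputation strategy and flagged:
#' `"zero"` (default, the simplest method) sets them to 0, `"interpolate"`
#' fills linearly between observed epochs.
#'
#' @param mag output of [magnitude()].
#' @param impute `"zero"` or `"interpolate"`.
#' @return object of class `epoch_activity`: data.table `epoch` (start, s),
#'   `mean_g`, `min_g`, `max_g`, `std_g`, `imputed`.
#' @export
epochise <- function(mag, impute = c("zero", "interpolate")) {
  impute <- match.arg(impute)
  dt <- copy(as.data.table(mag))
  dt[, sec := floor(time)]
  per_sec <- dt[, .(m = mean(A), s = if (.N > 1) sd(A) else 0), by = sec]
  per_sec[, minute := sec %/% 60L]
  per_min <- per_sec[, .(mean_g = mean(m), min_g = min(m), max_g = max(m),
                         std_g = mean(s)), by = minute]
  grid <- data.table(minute = seq(min(per_min$minute), max(per_min$minute)))
  out <- per_min[grid, on = "minute"]
  out[, imputed := is.na(mean_g)]
  cols <- c("mean_g", "min_g", "max_g", "std_g")
  if (impute == "zero") {
    for (cl in cols) set(out, which(out$imputed), cl, 0)
  } else {
    obs <- which(!out$imputed)
    for (cl in cols) {
      set(out, j = cl,
          value = approx(obs, out[[cl]][obs], xout = seq_len(nrow(out)),
                         rule = 2)$y)
    }
  }
  out[, epoch := minute * 60]
  setcolorder(out, c("epoch", "minute", cols, "imputed"))
  setattr(out, "class", c("epoch_activity", class(out)))
  setattr(out, "impute", impute)
  out[]
}

# epochs restricted to complete midnight-to-midnight days
full_day_epochs <- function(epochs) {
  ep <- copy(as.data.table(epochs))
  ep[, day := minute %/% MINS_DAY]
  complete <- ep[, .N, by = day][N == MINS_DAY, day]
  ep[day %in% complete]
}

#' Least-active 5-h and most-active 10-h windows (L5/M10)
#'
#' Computed on the average 24-h profile: the activity column is averaged per
#' clock minute across complete days, then L5 is the contiguous 5-h window
#' (wrapping midnight) minimising the mean and M10 the 10-h window maximising
#' it. Onsets are window-start clock times; ties are broken towards the
#' earliest clock time.
#'
#' @param epochs an `epoch_activity` (span must include a complete day).
#' @param act_col activity column, default `"std_g"` (movement intensity).
#' @return list `l5_onset`, `l5_mean`, `m10_onset`, `m10_mean`; onsets in
#'   clock minutes.
#' @export
l5_m10 <- function(epochs, act_col = "std_g") {
  ep <- full_day_epochs(epochs)
  if (nrow(ep) == 0) stop("span < 24 h: need at least one complete day")
  ep[, tod := minute %% MINS_DAY]
  prof <- ep[, .(value = mean(get(act_col))), by = tod]
  setorder(prof, tod)
  p <- prof$value
  cs <- cumsum(c(0, rep(p, 2)))
  wmean <- function(len) {
    i <- seq_len(MINS_DAY)
    (cs[i + len] - cs[i]) / len
  }
  # round away floating noise so exact ties resolve to the earliest clock time
  m5 <- round(wmean(300L), 9); m10 <- round(wmean(600L), 9)
  list(l5_onset = which.min(m5) - 1L, l5_mean = min(m5),
       m10_onset = which.max(m10) - 1L, m10_mean = max(m10))
}

#' Interdaily stability (IS)
#'
#' `IS = (n * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)` over the
#' hourly series, with `p = 24` clock-hour bins and `n` the total number of
#' hourly values. 1 for a perfectly repeating 24-h profile, near 0 for noise.
#'
#' @param x an `epoch_activity` (hourly means of movement intensity over
#'   complete days are derived) or a numeric vector of hourly values.
#' @param p number of bins per day (24 for hourly data).
#' @return IS in `[0, 1]`.
#' @export
interdaily_stability <- function(x, p = 24L) {
  xv <- if (inherits(x, "epoch_activity")) hourly_values(x) else as.numeric(x)
  n <- length(xv)
  xbar <- mean(xv)
  denom <- sum((xv - xbar)^2)
  if (denom == 0) stop("zero-variance series: IS undefined")
  bin <- ((seq_len(n) - 1L) %% p)
  hb <- tapply(xv, bin, mean)
  (n * sum((hb - xbar)^2)) / (p * denom)
}

# hourly values across complete days (per-hour means within each day)
hourly_values <- function(epochs, act_col = "std_g") {
  ep <- full_day_epochs(epochs)
  if (nrow(ep) == 0) stop("no complete day in epoch series")
  ep[, hour := minute %/% 60L]
  hv <- ep[, .(value = mean(get(act_col))), by = hour]
  setorder(hv, hour)
  hv$value
}

#' Intradaily variability (IV)
#'
#' `IV = (n * sum_{i>=2} (x_i - x_{i-1})^2) / ((n - 1) * sum_i (x_i - xbar)^2)`
#' on the hourly series: the normalised mean-squared first difference. About 2
#' for white noise, 4 for a perfectly alternating series, small for a smooth
#' rhythm; high values mark fragmented rest-activity cycles.
#'
#' @param x an `epoch_activity` or a numeric vector of hourly values.
#' @return IV (>= 0), or `NA` with a warning for a constant series.
#' @export
intradaily_variability <- function(x) {
  xv <- if (inherits(x, "epoch_activity")) hourly_values(x) else as.numeric(x)
  n <- length(xv)
  denom <- sum((xv - mean(xv))^2)
  if (denom == 0) {
    warning("constant series: IV undefined")
    return(NA_real_)
  }
  (n * sum(diff(xv)^2)) / ((n - 1) * denom)
}

#' Relative amplitude (RA)
#'
#' `RA = (M10 - L5) / (M10 + L5)` over the mean activity levels of the
#' most-active 10-h and least-active 5-h windows; in `[0, 1]` for non-negative
#' activity, 1 when the least-active window is completely still.
#'
#' @param l5_mean mean activity of the L5 window (>= 0).
#' @param m10_mean mean activity of the M10 window (>= 0).
#' @return RA.
#' @export
relative_amplitude <- function(l5_mean, m10_mean) {
  if (l5_mean < 0 || m10_mean < 0) stop("activity levels must be >= 0")
  if (l5_mean + m10_mean == 0) stop("both levels zero: RA undefined")
  (m10_mean - l5_mean) / (m10_mean + l5_mean)
}

#' Non-parametric rest-activity profile
#'
#' Bundles L5/M10 onsets and means, IS, IV and RA for an observation span,
#' computed on per-minute movement intensity over complete
#' midnight-to-midnight days.
#'
#' @param epochs an `epoch_activity`.
#' @param act_col activity column, default `"std_g"`.
#' @return object of class `actigraphy_profile` (a list).
#' @export
actigraphy_profile <- function(epochs, act_col = "std_g") {
  lm10 <- l5_m10(epochs, act_col)
  hv <- hourly_values(epochs, act_col)
  n_days <- length(hv) / 24
  structure(c(lm10, list(
    is = interdaily_stability(hv),
    iv = intradaily_variability(hv),
    ra = relative_amplitude(lm10$l5_mean, lm10$m10_mean),
    n_days = n_days, epochs_per_day = MINS_DAY,
    n_epochs = n_days * MINS_DAY
  )), class = "actigraphy_profile")
}

#' @export
print.actigraphy_profile <- function(x, ...) {
  cat(sprintf(
    "<actigraphy_profile> L5 %s (%.4f g)  M10 %s (%.4f g)\n  IS %.3f  IV %.3f  RA %.3f  over %g day(s)\n",
    format_clock(x$l5_onset), x$l5_mean, format_clock(x$m10_onset), x$m10_mean,
    x$is, x$iv, x$ra, x$n_days))
  invisible(x)
}

#' Offset between L5 onset and self-reported sleep onset
#'
#' Signed circular difference in minutes, positive when the least-active
#' window starts after the participant's predicted sleep time; range
#' `(-720, 720]`.
#'
#' @param profile an `actigraphy_profile`, or an L5 onset as clock minutes or
#'   `"HH:MM"`.
#' @param reported_onset self-reported sleep onset (`"HH:MM"` or minutes).
#' @return signed difference in minutes.
#' @export
delta_t <- function(profile, reported_onset) {
  l5 <- if (inherits(profile, "actigraphy_profile")) profile$l5_onset
        else parse_clock(profile)
  clock_diff(l5, parse_clock(reported_onset))
}

#' Daily movement trend
#'
#' Mean per-minute movement intensity (mean of per-second standard deviations
#' of magnitude) per day; imputed epochs are excluded so out-of-home gaps do
#' not drag the trend towards zero.
#'
#' @param epochs an `epoch_activity`.
#' @return data.table `day` (1-based), `movement` (g).
#' @export
movement_trend <- function(epochs) {
  ep <- copy(as.data.table(epochs)[imputed == FALSE])
  ep[, day := minute %/% MINS_DAY + 1L]
  out <- ep[, .(movement = mean(std_g)), by = day]
  setorder(out, day)
  out[]
}
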