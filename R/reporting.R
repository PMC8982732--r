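# Clinician-facing surfaces: hourly modal location/activity grid with L5/M10
# highlighting, the 75th-percentile movement spiral series, and the PROM
# comparison table.

#' Hourly modal location and dominant activity grid
#'
#' For every day x hour cell: the modal predicted location (ties broken
#' towards the label more frequent overall, then lexicographically), the
#' dominant (plurality) activity of the hour's classified windows, and an
#' activity flag (`"active"` when walk or stair dominate, `"stand"` when
#' standing dominates). Hours without data are `"unknown"`. L5/M10 onsets are
#' attached as attributes when a profile is supplied.
#'
#' @param timeline location timeline from [predict_timeline()].
#' @param activity_timeline optional data.table window/label (attribute
#'   `timeline` of [predict_daily_activity()]).
#' @param profile optional `actigraphy_profile` for the highlight bands.
#' @return object of class `hourly_modal`: data.table `day`, `hour`,
#'   `modal_location`, `dominant_activity`, `flag`; attributes `l5_onset`,
#'   `m10_onset` (clock minutes) when a profile is given.
#' @export
hourly_modal <- function(timeline, activity_timeline = NULL, profile = NULL) {
  tl <- copy(as.data.table(timeline))
  tl[, `:=`(day = floor(time / SECS_DAY) + 1L,
            hour = (floor(time) %% SECS_DAY) %/% 3600L)]
  overall <- tl[, .N, by = label]
  counts <- tl[, .N, by = .(day, hour, label)]
  counts <- counts[overall, on = "label", overall := i.N]
  setorder(counts, day, hour, -N, -overall, label)
  modal <- counts[, .SD[1], by = .(day, hour)][, .(day, hour, modal_location = as.character(label))]

  grid <- CJ(day = seq(min(tl$day), max(tl$day)), hour = 0:23)
  out <- modal[grid, on = c("day", "hour")]
  out[is.na(modal_location), modal_location := "unknown"]

  out[, dominant_activity := NA_character_]
  if (!is.null(activity_timeline) && nrow(activity_timeline) > 0) {
    at <- copy(as.data.table(activity_timeline))
    at[, `:=`(day = floor(window / SECS_DAY) + 1L,
              hour = (floor(window) %% SECS_DAY) %/% 3600L)]
    ac <- at[, .N, by = .(day, hour, label)]
    setorder(ac, day, hour, -N, label)
    dom <- ac[, .SD[1], by = .(day, hour)][, .(day, hour, dom = as.character(label))]
    out[dom, on = c("day", "hour"), dominant_activity := i.dom]
  }
  out[, flag := fifelse(dominant_activity %in% c("walk", "stair"), "active",
                 fifelse(dominant_activity == "stand", "stand", NA_character_))]
  setorder(out, day, hour)
  if (!is.null(profile)) {
    setattr(out, "l5_onset", profile$l5_onset)
    setattr(out, "m10_onset", profile$m10_onset)
  }
  structure(out[], class = c("hourly_modal", class(out)))
}

#' Movement spiral series (75th-percentile filter)
#'
#' Retains per-minute movement values at or above the 75th percentile
#' (linear-interpolation quantile; ties retained) of all epochs, blanking the
#' rest, for the clockwise study spiral (angle = time of day, radius = study
#' day, inner = study start).
#'
#' @param epochs an `epoch_activity`.
#' @param value_col column to filter on, default `"std_g"`.
#' @return data.table `day`, `tod_min` (clock minutes), `value` (NA when
#'   filtered out), `retained`; attribute `threshold`.
#' @export
spiral_filter <- function(epochs, value_col = "std_g") {
  ep <- as.data.table(epochs)
  if (nrow(ep) == 0) stop("empty epoch series")
  v <- ep[[value_col]]
  thr <- quantile(v, 0.75, type = 7, names = FALSE)
  out <- data.table(day = ep$minute %/% MINS_DAY + 1L,
                    tod_min = ep$minute %% MINS_DAY,
                    value = ifelse(v >= thr, v, NA_real_),
                    retained = v >= thr)
  setattr(out, "threshold", thr)
  out[]
}

#' PROM comparison table
#'
#' Renders baseline and follow-up scores per instrument and participant beside
#' optional sensor-derived trend summaries (movement slope, bedroom-share
#' slope, intradaily variability). Missing timepoints stay blank; an empty
#' fixture list yields an empty table.
#'
#' @param fixtures data.frame from [load_prom_fixture()] (participant,
#'   instrument, timepoint, score).
#' @param trends optional data.frame keyed by `participant` with trend
#'   columns to append.
#' @return data.frame with one row per instrument x participant and columns
#'   BL, FU1, FU2, FU3 plus any trend columns.
#' @export
prom_report <- function(fixtures, trends = NULL) {
  tps <- c("BL", "FU1", "FU2", "FU3")
  if (is.null(fixtures) || nrow(fixtures) == 0) {
    out <- data.frame(instrument = character(0), participant = character(0))
    for (tp in tps) out[[tp]] <- numeric(0)
    return(out)
  }
  fx <- copy(as.data.table(fixtures))
  fx[, timepoint := factor(as.character(timepoint), levels = tps)]
  wide <- dcast(fx, instrument + participant ~ timepoint, value.var = "score",
                drop = c(TRUE, FALSE))
  for (tp in setdiff(tps, names(wide))) wide[, (tp) := NA_real_]
  setcolorder(wide, c("instrument", "participant", tps))
  out <- as.data.frame(wide)
  if (!is.null(trends) && nrow(trends) > 0) {
    out <- merge(out, as.data.frame(trends), by = "participant",
                 all.x = TRUE, sort = FALSE)
    out <- out[, c("instrument", setdiff(names(out), "instrument"))]
  }
  out[order(out$instrument, out$participant), , drop = FALSE]
}

# ---- figures -----------------------------------------------------------

#' Stacked-area daily distribution figure
#' @param dist data.table day/label/percent (location or activity).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_daily_distribution <- function(dist, title = "Daily distribution") {
  dd <- as.data.table(dist)
  full <- CJ(day = seq(min(dd$day), max(dd$day)), label = unique(dd$label))
  dd <- dd[full, on = c("day", "label")]
  dd[is.na(percent), percent := 0]
  ggplot(dd, aes(x = day, y = percent, fill = label)) +
    geom_area(position = "stack") +
    labs(title = title, x = "study day", y = "% of day", fill = NULL) +
    theme_minimal()
}

#' Gateway message-count figure
#' @param health a `gateway_health`.
#' @return a ggplot object.
#' @export
plot_gateway_health <- function(health) {
  ggplot(as.data.table(health$counts), aes(x = day, y = n, fill = gateway)) +
    geom_area(position = "stack") +
    labs(title = "BLE gateway messages per day", x = "study day",
         y = "messages", fill = NULL) +
    theme_minimal()
}

#' Hourly modal grid figure
#' @param grid an `hourly_modal`.
#' @return a ggplot object.
#' @export
plot_hourly_modal <- function(grid) {
  g <- ggplot(as.data.table(grid),
              aes(x = hour, y = day, fill = modal_location)) +
    geom_tile(colour = "white", linewidth = 0.1) +
    scale_y_reverse() +
    labs(title = "Hourly modal location", x = "hour of day", y = "study day",
         fill = NULL) +
    theme_minimal()
  l5 <- attr(grid, "l5_onset"); m10 <- attr(grid, "m10_onset")
  if (!is.null(l5)) {
    g <- g + geom_vline(xintercept = c(l5 / 60, (l5 / 60 + 5) %% 24),
                        colour = "grey40", linetype = 2) +
      geom_vline(xintercept = c(m10 / 60, (m10 / 60 + 10) %% 24),
                 colour = "goldenrod", linetype = 2)
  }
  g
}

#' Movement spiral figure
#' @param spiral output of [spiral_filter()].
#' @return a ggplot object (polar coordinates, clockwise, inner = start).
#' @export
plot_spiral <- function(spiral) {
  sp <- as.data.table(spiral)[retained == TRUE]
  ggplot(sp, aes(x = tod_min, y = day, colour = value)) +
    geom_point(size = 0.4) +
    coord_polar(direction = 1) +
    scale_x_continuous(limits = c(0, 1440), breaks = seq(0, 1380, 180),
                       labels = format_clock(seq(0, 1380, 180))) +
    labs(title = "Movement >= 75th percentile", x = NULL, y = "study day",
         colour = "std (g)") +
    theme_minimal()
}
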