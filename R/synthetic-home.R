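# Synthetic smart-home generator: homes, circadian routines, multimodal sensor
# streams, annotation protocols, failure injection and PROM fixtures. The
# generator reproduces the statistical structure the downstream analyses assume
# (log-distance RSSI decay, activity-conditioned acceleration, circadian
# routine with out-of-home gaps) without any claim to radio realism.

ROOM_POOL <- c(
  "bedroom", "kitchen", "bathroom", "living room", "hall", "study",
  "dining room", "stairs", "laundry", "porch", "bedroom 2", "hall 2",
  "bathroom 2", "bedroom 3", "conservatory", "utility", "office", "landing",
  "garage", "box room"
)

# jitter multipliers applied to cfg$accel_noise_sd per activity; chosen so the
# gravity-free std ordering lay down < sit < stand < walk holds at defaults
ACT_NOISE_MULT <- c("lay down" = 0.3, "sit" = 1.5, "stair" = 4, "stand" = 2, "walk" = 3)

# base wrist orientation (unit gravity direction) per activity
ACT_GRAVITY <- list(
  "lay down" = c(1, 0, 0),
  "sit"      = c(0.30, 0.30, 0.906),
  "stair"    = c(0, 0.60, 0.80),
  "stand"    = c(0, 0.45, 0.893),
  "walk"     = c(0, 0.45, 0.893)
)

#' Simulation configuration
#'
#' Parameters of the synthetic sensor channel: log-distance RSSI decay with
#' Gaussian shadowing, emission cadence, accelerometer noise and gait
#' frequency, plus gateway failure windows.
#'
#' @param seed RNG seed used by the simulators.
#' @param ref_power_db received power (dBm) at 1 m.
#' @param path_exp path-loss exponent of the log-distance decay.
#' @param shadow_sd shadowing standard deviation in dB (>= 0).
#' @param oor_threshold out-of-range threshold in dB; readings below are dropped
#'   and silent gateways are substituted with this constant during
#'   featurisation. Default -100 dB.
#' @param accel_noise_sd base accelerometer jitter std in g; per-activity
#'   multipliers are applied on top.
#' @param gait_hz walking cadence in Hz.
#' @param accel_hz accelerometer sampling rate in Hz (wearable nominal 25).
#' @param rssi_drop probability that a nominal once-per-second gateway reading
#'   is not received.
#' @param failure_windows `data.frame(gateway, start_day, end_day)` of
#'   whole-day gateway outages (1-based inclusive day indices), or `NULL`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ref_power_db = -45, path_exp = 3,
                       shadow_sd = 3, oor_threshold = -100,
                       accel_noise_sd = 0.01, gait_hz = 1.8, accel_hz = 25,
                       rssi_drop = 0.1, failure_windows = NULL) {
  stopifnot(shadow_sd >= 0, accel_hz > 0, rssi_drop >= 0, rssi_drop < 1)
  structure(list(
    seed = seed, ref_power_db = ref_power_db, path_exp = path_exp,
    shadow_sd = shadow_sd, oor_threshold = oor_threshold,
    accel_noise_sd = accel_noise_sd, gait_hz = gait_hz, accel_hz = accel_hz,
    rssi_drop = rssi_drop, failure_windows = failure_windows
  ), class = "sim_config")
}

#' Generate a multi-room home layout with BLE gateways
#'
#' Rooms are placed on a jittered 3 m grid. When at least eight rooms are
#' requested the `stairs` and `laundry` rooms are placed about 1 m from `hall`
#' and `kitchen` respectively, producing the adjoining, hard-to-fingerprint
#' room pairs seen in larger homes. Gateways sit near a spread-out subset of
#' room centroids.
#'
#' @param room_count number of rooms (>= 1). The first four labels are always
#'   bedroom, kitchen, bathroom, living room.
#' @param gateway_count number of BLE gateways (>= 1).
#' @param seed RNG seed; the layout is deterministic given the seed.
#' @return object of class `home_layout`: `rooms` (label, x, y, floor),
#'   `gateways` (gateway, x, y), `adjacency` (room label pairs).
#' @export
generate_home <- function(room_count, gateway_count, seed = 1) {
  if (!is.numeric(room_count) || room_count < 1) stop("room_count must be >= 1")
  if (!is.numeric(gateway_count) || gateway_count < 1) stop("gateway_count must be >= 1")
  room_count <- as.integer(room_count)
  gateway_count <- as.integer(gateway_count)
  set.seed(seed)

  labels <- if (room_count <= length(ROOM_POOL)) {
    ROOM_POOL[seq_len(room_count)]
  } else {
    c(ROOM_POOL, paste("room", seq_len(room_count - length(ROOM_POOL))))
  }
  ncol_ <- ceiling(sqrt(room_count))
  gx <- ((seq_len(room_count) - 1L) %% ncol_) * 3
  gy <- ((seq_len(room_count) - 1L) %/% ncol_) * 3
  x <- gx + runif(room_count, -0.5, 0.5)
  y <- gy + runif(room_count, -0.5, 0.5)
  floor_idx <- as.integer(gy >= 6)

  adjoin <- list(c("stairs", "hall"), c("laundry", "kitchen"))
  pairs <- list()
  if (room_count >= 8) {
    for (pr in adjoin) {
      if (all(pr %in% labels)) {
        i <- match(pr[1], labels); j <- match(pr[2], labels)
        ang <- runif(1, 0, 2 * pi)
        x[i] <- x[j] + cos(ang) * 1.0
        y[i] <- y[j] + sin(ang) * 1.0
        floor_idx[i] <- floor_idx[j]
        pairs <- c(pairs, list(pr))
      }
    }
  }
  rooms <- data.table(label = labels, x = x, y = y, floor = floor_idx)

  # chain adjacency keeps every room reachable; adjoining pairs added on top
  adjacency <- if (room_count > 1) {
    data.table(a = labels[-room_count], b = labels[-1])
  } else data.table(a = character(0), b = character(0))
  for (pr in pairs) adjacency <- rbind(adjacency, data.table(a = pr[1], b = pr[2]))

  host <- if (gateway_count <= room_count) {
    round(seq(1, room_count, length.out = gateway_count))
  } else {
    c(seq_len(room_count), sample.int(room_count, gateway_count - room_count, replace = TRUE))
  }
  gateways <- data.table(
    gateway = paste0("gw", seq_len(gateway_count)),
    x = x[host] + runif(gateway_count, -0.7, 0.7),
    y = y[host] + runif(gateway_count, -0.7, 0.7)
  )
  structure(list(rooms = rooms, gateways = gateways, adjacency = adjacency),
            class = "home_layout")
}

#' @export
print.home_layout <- function(x, ...) {
  cat("<home_layout> ", nrow(x$rooms), " rooms, ", nrow(x$gateways), " gateways\n", sep = "")
  invisible(x)
}

# per-day behavioural parameters for the three participant profiles
profile_params <- function(profile, frac) {
  switch(profile,
    control = list(
      p_bed = 0.08, p_out = 0, intensity = 1,
      acts = c("lay down" = 0.05, "sit" = 0.45, "stair" = 0.05,
               "stand" = 0.2, "walk" = 0.25)
    ),
    recovering = list(
      p_bed = 0.60 - 0.45 * frac, p_out = 0.30 * frac,
      intensity = 0.5 + 1.0 * frac,
      acts = c("lay down" = 0.13 - 0.10 * frac, "sit" = 0.60 - 0.25 * frac,
               "stair" = 0.02 + 0.05 * frac, "stand" = 0.15,
               "walk" = 0.10 + 0.30 * frac)
    ),
    withdrawing = list(
      p_bed = 0.25 + 0.50 * frac, p_out = 0.10 * (1 - frac),
      intensity = 1.1 - 0.7 * frac,
      acts = c("lay down" = 0.08 + 0.05 * frac, "sit" = 0.55 + 0.25 * frac,
               "stair" = 0.02, "stand" = 0.15 - 0.05 * frac,
               "walk" = 0.20 - 0.15 * frac)
    ),
    stop("unknown profile: ", profile)
  )
}

#' Generate a multi-day participant routine
#'
#' Produces an ordered, non-overlapping segment schedule covering the whole
#' span, one activity-labelled segment at a time, with a nightly sleep window
#' around 23:00-07:00 recorded per day. Profiles encode the three study
#' archetypes: `control` leaves the home 09:00-17:00 on weekdays only;
#' `recovering` increases outings, walking and movement intensity linearly over
#' the span while bedroom share falls; `withdrawing` does the opposite, with
#' sitting dominating.
#'
#' @param profile one of `"recovering"`, `"withdrawing"`, `"control"`.
#' @param days number of days (>= 1); day 1 is a Monday.
#' @param seed RNG seed.
#' @param rooms room labels the routine may visit (first entry must be the
#'   bedroom used for sleep).
#' @return object of class `routine`: a `data.table` with columns
#'   `start`, `end` (seconds from study start), `room` (`"OUT"` when away),
#'   `activity`, `intensity`; attributes `profile`, `days`,
#'   `sleep_onset` (clock minutes per day).
#' @export
generate_routine <- function(profile = c("recovering", "withdrawing", "control"),
                             days, seed = 1,
                             rooms = c("bedroom", "kitchen", "bathroom",
                                       "living room", "hall")) {
  profile <- match.arg(profile)
  if (!is.numeric(days) || days < 1) stop("days must be >= 1")
  days <- as.integer(days)
  set.seed(seed)

  segs <- vector("list", days)
  sleep_onset <- numeric(days)
  day_rooms <- setdiff(rooms, "OUT")
  other_rooms <- setdiff(day_rooms, "bedroom")
  if (length(other_rooms) == 0) other_rooms <- day_rooms

  for (d in seq_len(days)) {
    frac <- if (days > 1) (d - 1) / (days - 1) else 0
    pp <- profile_params(profile, frac)
    base <- (d - 1L) * SECS_DAY
    weekday <- ((d - 1L) %% 7L) < 5L
    wake <- 7 * 3600 + round(rnorm(1, 0, 600))
    wake <- min(max(wake, 6 * 3600), 8 * 3600)
    onset <- 23 * 3600 + round(rnorm(1, 0, 600))
    onset <- min(max(onset, 22 * 3600), 23.9 * 3600)
    sleep_onset[d] <- onset / 60

    out <- list(data.table(start = base, end = base + wake, room = "bedroom",
                           activity = "lay down", intensity = 0.3))
    t <- wake
    repeat {
      if (t >= onset) break
      if (profile == "control" && weekday && t >= 9 * 3600 && t < 17 * 3600) {
        # workday outing: wearable out of range, no segments emitted by sensors
        out <- c(out, list(data.table(start = base + t, end = base + 17 * 3600,
                                      room = "OUT", activity = NA_character_,
                                      intensity = NA_real_)))
        t <- 17 * 3600
        next
      }
      dur <- round(runif(1, 1200, 4500))
      end_t <- min(t + dur, onset)
      if (profile == "control" && weekday && t < 9 * 3600) {
        end_t <- min(end_t, 9 * 3600)
      }
      u <- runif(1)
      if (u < pp$p_out && profile != "control") {
        out <- c(out, list(data.table(start = base + t, end = base + end_t,
                                      room = "OUT", activity = NA_character_,
                                      intensity = NA_real_)))
      } else {
        room <- if (runif(1) < pp$p_bed) "bedroom" else sample(other_rooms, 1)
        act <- sample(names(pp$acts), 1, prob = pmax(pp$acts, 0))
        out <- c(out, list(data.table(start = base + t, end = base + end_t,
                                      room = room, activity = act,
                                      intensity = pp$intensity)))
      }
      t <- end_t
    }
    out <- c(out, list(data.table(start = base + onset, end = base + SECS_DAY,
                                  room = "bedroom", activity = "lay down",
                                  intensity = 0.3)))
    segs[[d]] <- rbindlist(out)
  }
  segs <- rbindlist(segs)
  structure(segs, class = c("routine", class(segs)),
            profile = profile, days = days, sleep_onset = sleep_onset)
}

# unit-normalise a 3-vector
unit3 <- function(v) v / sqrt(sum(v^2))

# synthesise tri-axial acceleration for one segment; returns data.table
synth_accel_segment <- function(start, end, activity, intensity, cfg) {
  hz <- cfg$accel_hz
  n <- round((end - start) * hz)
  if (n <= 0) return(NULL)
  t <- start + (seq_len(n) - 1) / hz
  gvec <- unit3(ACT_GRAVITY[[activity]] + rnorm(3, 0, 0.05))
  perp <- unit3(c(-gvec[2], gvec[1], 0) + c(0, 0, 1e-6))
  amp_t <- rep(0, n)
  freq <- cfg$gait_hz
  if (activity == "walk") {
    amp_t[] <- (0.15 + 0.2 * runif(1)) * intensity
  } else if (activity == "stair") {
    amp_t[] <- (0.30 + 0.25 * runif(1)) * intensity
    freq <- 0.8 * cfg$gait_hz
  } else if (activity == "stand") {
    # intermittent arm-movement bouts: 10-s blocks, half of them active with a
    # low periodic amplitude that overlaps slow walking
    nb <- ceiling(n / (10 * hz))
    bamp <- ifelse(runif(nb) < 0.5, runif(nb, 0.03, 0.22), 0) * intensity
    amp_t <- rep(bamp, each = 10 * hz)[seq_len(n)]
    freq <- 1.05 * cfg$gait_hz
  }
  phase <- runif(2, 0, 2 * pi)
  p <- amp_t * sin(2 * pi * freq * (t - start) + phase[1])
  p2 <- 0.4 * amp_t * sin(4 * pi * freq * (t - start) + phase[2])
  sd_n <- ACT_NOISE_MULT[[activity]] * cfg$accel_noise_sd
  noise <- if (sd_n > 0) matrix(rnorm(3 * n, 0, sd_n), ncol = 3) else matrix(0, n, 3)
  a <- outer(1 + p, gvec) + outer(p2, perp) + noise
  data.table(time = t, x = a[, 1], y = a[, 2], z = a[, 3])
}

# core simulator over a plain segment table (no seed handling, no coverage check)
simulate_segments <- function(layout, segs, cfg) {
  rooms <- layout$rooms
  gws <- layout$gateways
  d_mat <- outer(seq_len(nrow(rooms)), seq_len(nrow(gws)), function(i, j) {
    pmax(sqrt((rooms$x[i] - gws$x[j])^2 + (rooms$y[i] - gws$y[j])^2), 0.5)
  })
  rownames(d_mat) <- rooms$label

  rssi_out <- list(); accel_out <- list()
  for (k in seq_len(nrow(segs))) {
    room <- segs$room[k]
    if (is.na(room) || room == "OUT") next
    s0 <- segs$start[k]; s1 <- segs$end[k]
    secs <- seq(s0, s1 - 1)
    ns <- length(secs)
    for (j in seq_len(nrow(gws))) {
      keep <- runif(ns) >= cfg$rssi_drop
      if (!any(keep)) next
      tt <- secs[keep] + runif(sum(keep))
      mu <- cfg$ref_power_db - 10 * cfg$path_exp * log10(d_mat[room, j])
      val <- mu + rnorm(sum(keep), 0, cfg$shadow_sd)
      ok <- val >= cfg$oor_threshold
      if (any(ok)) {
        rssi_out[[length(rssi_out) + 1L]] <- data.table(
          time = tt[ok], gateway = gws$gateway[j], rssi = val[ok])
      }
    }
    accel_out[[length(accel_out) + 1L]] <-
      synth_accel_segment(s0, s1, segs$activity[k], segs$intensity[k], cfg)
  }
  rssi <- if (length(rssi_out)) rbindlist(rssi_out) else
    data.table(time = numeric(0), gateway = character(0), rssi = numeric(0))
  accel <- if (length(accel_out)) rbindlist(accel_out) else
    data.table(time = numeric(0), x = numeric(0), y = numeric(0), z = numeric(0))
  setorder(rssi, time, gateway)
  setorder(accel, time)
  structure(list(rssi = rssi, accel = accel), class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat("<sensor_stream> ", nrow(x$rssi), " RSSI readings, ",
      nrow(x$accel), " accel samples\n", sep = "")
  invisible(x)
}

#' Simulate wearable RSSI and acceleration streams for a routine
#'
#' RSSI follows a log-distance decay from the occupied room's centroid to each
#' gateway with Gaussian shadowing, emitted nominally once per gateway per
#' second with a random drop; readings below the out-of-range threshold are
#' discarded. Acceleration is a gravity-oriented baseline per activity plus
#' class-specific dynamics (periodic gait for walk/stair, intermittent bouts
#' for stand, jitter for sit, near-stillness for lay down) and Gaussian noise.
#' `OUT` segments emit nothing on either channel (wearable out of range).
#'
#' @param layout a `home_layout`.
#' @param routine a `routine` (rooms must be a subset of the layout's rooms).
#' @param cfg a [sim_config()].
#' @param days optional integer vector of 1-based day indices to simulate
#'   (defaults to all days); used to scale long observation spans.
#' @return a `sensor_stream`: list of `rssi` (time, gateway, rssi) and
#'   `accel` (time, x, y, z) data.tables.
#' @export
simulate_stream <- function(layout, routine, cfg = sim_config(), days = NULL) {
  if (nrow(routine) == 0) stop("empty routine")
  used <- setdiff(unique(routine$room), "OUT")
  if (!all(used %in% layout$rooms$label)) {
    stop("routine rooms not in layout: ",
         paste(setdiff(used, layout$rooms$label), collapse = ", "))
  }
  segs <- as.data.table(routine)
  if (!is.null(days)) {
    segs <- segs[(floor(start / SECS_DAY) + 1L) %in% as.integer(days)]
  }
  set.seed(cfg$seed)
  simulate_segments(layout, segs, cfg)
}

#' Remove gateway messages during configured failure windows
#'
#' Deletes all RSSI records of the named gateways on whole days inside each
#' `[start_day, end_day]` window (1-based, inclusive); acceleration is left
#' untouched.
#'
#' @param stream a `sensor_stream`.
#' @param cfg a [sim_config()] whose `failure_windows` is a
#'   `data.frame(gateway, start_day, end_day)`.
#' @param roster known gateway ids used to validate the windows; defaults to
#'   gateways present in the stream.
#' @return the filtered `sensor_stream`.
#' @export
inject_failures <- function(stream, cfg, roster = NULL) {
  fw <- cfg$failure_windows
  if (is.null(fw) || nrow(fw) == 0) return(stream)
  roster <- roster %||% unique(stream$rssi$gateway)
  bad <- setdiff(fw$gateway, roster)
  if (length(bad)) stop("unknown gateway-id in failure windows: ",
                        paste(bad, collapse = ", "))
  rssi <- copy(stream$rssi)
  day <- floor(rssi$time / SECS_DAY) + 1L
  drop <- rep(FALSE, nrow(rssi))
  for (k in seq_len(nrow(fw))) {
    drop <- drop | (rssi$gateway == fw$gateway[k] &
                    day >= fw$start_day[k] & day <= fw$end_day[k])
  }
  structure(list(rssi = rssi[!drop], accel = stream$accel),
            class = "sensor_stream")
}

#' Simulate the technician walk-around annotation protocol
#'
#' A technician carries the wearable into every room in turn, dwelling about
#' 50 s per room, for `repeats` passes (the deployment protocol performs one at
#' installation and one at removal). Returns the sensor stream together with
#' the location-labelled annotation intervals that align with the dwells.
#'
#' @param layout a `home_layout`.
#' @param cfg a [sim_config()].
#' @param repeats number of walk-around passes (>= 1), default 2.
#' @param dwell_range dwell-time range per room in seconds.
#' @param start_time stream start time in seconds.
#' @return list with `stream` (a `sensor_stream`) and `annotations`
#'   (data.table start, end, label, kind = "location").
#' @export
simulate_walkaround <- function(layout, cfg = sim_config(), repeats = 2,
                                dwell_range = c(45, 55), start_time = 0) {
  if (repeats < 1) stop("repeats must be >= 1")
  set.seed(cfg$seed)
  labels <- layout$rooms$label
  n_int <- repeats * length(labels)
  dur <- round(runif(n_int, dwell_range[1], dwell_range[2]))
  start <- start_time + cumsum(c(0, dur[-n_int]))
  ann <- data.table(start = start, end = start + dur,
                    label = rep(labels, repeats), kind = "location")
  segs <- data.table(start = ann$start, end = ann$end, room = ann$label,
                     activity = "stand", intensity = 1)
  list(stream = simulate_segments(layout, segs, cfg), annotations = ann)
}

#' Simulate a short scripted activity-annotation experiment
#'
#' Emulates the "day in fast-forward" protocol: the wearer performs the five
#' posture/ambulation activities in short scripted bouts over 5-10 minutes
#' while video annotation records the activity intervals.
#'
#' @param layout a `home_layout`.
#' @param cfg a [sim_config()].
#' @param seed RNG seed for the script (stream noise uses `cfg$seed`).
#' @param duration total script length in seconds (default drawn in 300-600).
#' @param start_time stream start time in seconds.
#' @return list with `stream` and `annotations` (kind = "activity").
#' @export
simulate_script <- function(layout, cfg = sim_config(), seed = 1,
                            duration = NULL, start_time = 0) {
  set.seed(seed)
  duration <- duration %||% round(runif(1, 300, 600))
  rooms <- layout$rooms$label
  segs <- list(); t <- start_time
  acts <- character(0)
  while (t < start_time + duration) {
    # cycle so every class appears before random sampling takes over
    remaining <- setdiff(ACTIVITY_CLASSES, acts)
    act <- if (length(remaining)) remaining[1] else sample(ACTIVITY_CLASSES, 1)
    acts <- c(acts, act)
    dur <- round(runif(1, 20, 45))
    segs <- c(segs, list(data.table(
      start = t, end = min(t + dur, start_time + duration),
      room = sample(rooms, 1), activity = act, intensity = 1)))
    t <- t + dur
  }
  segs <- rbindlist(segs)
  ann <- data.table(start = segs$start, end = segs$end,
                    label = segs$activity, kind = "activity")
  cfg2 <- cfg; cfg2$seed <- cfg$seed + seed
  set.seed(cfg2$seed)
  list(stream = simulate_segments(layout, segs, cfg2), annotations = ann)
}

#' Annotation track from routine ground truth
#'
#' Converts a routine's segments into non-overlapping annotation intervals,
#' either room labels (`location`, OUT segments dropped) or activity labels
#' (`activity`, segments without an activity dropped).
#'
#' @param routine a `routine`.
#' @param kind `"location"` or `"activity"`.
#' @return data.table with start, end, label, kind.
#' @export
annotations_from_routine <- function(routine, kind = c("location", "activity")) {
  kind <- match.arg(kind)
  segs <- as.data.table(routine)
  if (kind == "location") {
    segs <- segs[room != "OUT"]
    data.table(start = segs$start, end = segs$end, label = segs$room, kind = kind)
  } else {
    segs <- segs[!is.na(activity)]
    data.table(start = segs$start, end = segs$end, label = segs$activity, kind = kind)
  }
}

#' Bundled patient-reported outcome fixtures
#'
#' Oxford Hip Score (0-48, higher = fewer symptoms) and HOOS Quality-of-Life
#' subscale (0-100%, higher = fewer problems) for the two post-operative
#' participants at baseline and three follow-ups.
#'
#' @return data.frame with columns participant, instrument
#'   (`"OHS"`/`"HOOS-QOL"`), timepoint (`BL`, `FU1`, `FU2`, `FU3`), score.
#' @export
load_prom_fixture <- function() {
  path <- system.file("extdata", "proms.csv", package = "recoverhome")
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$timepoint <- factor(out$timepoint, levels = c("BL", "FU1", "FU2", "FU3"))
  out
}
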