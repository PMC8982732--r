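test_that("home generation honours counts, labels and determinism", {
  h1 <- generate_home(1, 1, seed = 3)
  expect_equal(nrow(h1$rooms), 1)
  expect_equal(nrow(h1$gateways), 1)
  expect_equal(nrow(h1$adjacency), 0)

  h <- generate_home(7, 5, seed = 3)
  expect_true(all(c("bedroom", "kitchen", "bathroom", "living room") %in% h$rooms$label))
  expect_false(any(duplicated(h$rooms$label)))
  expect_identical(generate_home(7, 5, seed = 3), h)

  expect_error(generate_home(0, 1))
  expect_error(generate_home(3, 0))
})

test_that("large homes contain adjoining room pairs under 1.5 m apart", {
  h <- generate_home(11, 5, seed = 7)
  d <- function(a, b) {
    i <- match(a, h$rooms$label); j <- match(b, h$rooms$label)
    sqrt((h$rooms$x[i] - h$rooms$x[j])^2 + (h$rooms$y[i] - h$rooms$y[j])^2)
  }
  expect_lt(d("kitchen", "laundry"), 1.5)
  expect_lt(d("hall", "stairs"), 1.5)
})

test_that("every room is reachable through the adjacency graph", {
  h <- generate_home(11, 5, seed = 2)
  labels <- h$rooms$label
  reach <- labels[1]
  repeat {
    nxt <- unique(c(h$adjacency$b[h$adjacency$a %in% reach],
                    h$adjacency$a[h$adjacency$b %in% reach]))
    grown <- union(reach, nxt)
    if (length(grown) == length(reach)) break
    reach <- grown
  }
  expect_setequal(reach, labels)
})

test_that("routines cover the full span without overlap", {
  for (pr in c("control", "recovering", "withdrawing")) {
    r <- generate_routine(pr, 1, seed = 4)
    expect_equal(r$start[1], 0)
    expect_equal(r$end[nrow(r)], 86400)
    expect_true(all(r$start[-1] == r$end[-nrow(r)])) # contiguous, no overlap
  }
  expect_error(generate_routine("unknownprofile", 7))
  r <- generate_routine("control", 5, seed = 4)
  expect_length(attr(r, "sleep_onset"), 5)
})

test_that("control profile leaves home on weekdays but not weekends", {
  r <- generate_routine("control", 7, seed = 8) # day 1 = Monday
  dt <- as.data.frame(r)
  day <- floor(dt$start / 86400) + 1
  for (d in 1:5) expect_true(any(dt$room[day == d] == "OUT"), label = paste("weekday", d))
  for (d in 6:7) expect_false(any(dt$room[day == d] == "OUT"), label = paste("weekend", d))
})

test_that("withdrawing routine retreats to the bedroom over 90 days", {
  r <- generate_routine("withdrawing", 90, seed = 5)
  dt <- as.data.frame(r)
  dt$day <- floor(dt$start / 86400) + 1
  dt$dur <- dt$end - dt$start
  share <- function(days) {
    sub <- dt[dt$day %in% days, ]
    sum(sub$dur[sub$room == "bedroom"]) / sum(sub$dur)
  }
  expect_gt(share(84:90), share(1:7))
})

test_that("OUT-only segments emit no sensor records", {
  h <- easy_home()
  segs <- data.table(start = 0, end = 3600, room = "OUT",
                     activity = NA_character_, intensity = NA_real_)
  s <- simulate_stream(h, segs, sim_config(seed = 1))
  expect_equal(nrow(s$rssi), 0)
  expect_equal(nrow(s$accel), 0)
  expect_error(simulate_stream(h, segs[0], sim_config()), "empty routine")
})

test_that("lying still with zero noise gives exactly 1 g magnitude", {
  h <- easy_home()
  segs <- data.table(start = 0, end = 600, room = "bedroom",
                     activity = "lay down", intensity = 0.3)
  s <- simulate_stream(h, segs, sim_config(seed = 1, accel_noise_sd = 0))
  A <- magnitude(s)$A
  expect_equal(A, rep(1, length(A)), tolerance = 1e-12)
})

test_that("streams are bit-identical for identical config and seed", {
  h <- easy_home()
  r <- generate_routine("control", 1, seed = 1)
  cfg <- sim_config(seed = 9, accel_hz = 5)
  s1 <- simulate_stream(h, r, cfg)
  s2 <- simulate_stream(h, r, cfg)
  expect_identical(s1$rssi, s2$rssi)
  expect_identical(s1$accel, s2$accel)
})

test_that("mean RSSI decreases with distance when shadowing is zero", {
  h <- easy_home()
  cfg <- sim_config(seed = 1, shadow_sd = 0)
  g <- h$gateways[1]
  d <- sqrt((h$rooms$x - g$x)^2 + (h$rooms$y - g$y)^2)
  mu <- vapply(h$rooms$label, function(rm) {
    segs <- data.table(start = 0, end = 120, room = rm,
                       activity = "stand", intensity = 1)
    s <- simulate_stream(h, segs, cfg)
    mean(s$rssi$rssi[s$rssi$gateway == g$gateway])
  }, numeric(1))
  ord <- order(d)
  expect_true(all(diff(mu[ord]) < 0))
})

test_that("walk windows move more than sit windows", {
  h <- easy_home()
  cfg <- sim_config(seed = 13)
  mk <- function(act) {
    segs <- data.table(start = 0, end = 1550, room = "living room",
                       activity = act, intensity = 1)
    s <- simulate_stream(h, segs, cfg)
    f <- featurise_activity(s$accel, hz = 25)
    f$gf_sd
  }
  walk <- mk("walk"); sit <- mk("sit")
  expect_gte(length(walk) + length(sit), 1000)
  expect_gt(min(walk), max(sit))
})

test_that("gravity-free variability orders lay down < sit < stand < walk", {
  h <- easy_home()
  cfg <- sim_config(seed = 17)
  m <- vapply(c("lay down", "sit", "stand", "walk"), function(act) {
    segs <- data.table(start = 0, end = 800, room = "bedroom",
                       activity = act, intensity = 1)
    s <- simulate_stream(h, segs, cfg)
    mean(featurise_activity(s$accel, hz = 25)$gf_sd)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("failure injection removes exactly the configured gateway-days", {
  h <- easy_home()
  r <- generate_routine("control", 7, seed = 2)
  cfg0 <- sim_config(seed = 3, accel_hz = 1)
  s <- simulate_stream(h, r, cfg0, days = 2:6)

  expect_identical(inject_failures(s, cfg0), s) # no windows -> identity

  cfg <- sim_config(seed = 3, failure_windows = data.frame(
    gateway = c("gw1", "gw2"), start_day = 3, end_day = 4))
  s2 <- inject_failures(s, cfg, roster = h$gateways$gateway)
  day <- floor(s2$rssi$time / 86400) + 1
  expect_equal(sum(s2$rssi$gateway %in% c("gw1", "gw2") & day %in% 3:4), 0)
  # untouched elsewhere
  expect_gt(sum(s2$rssi$gateway == "gw1" & day == 2), 0)
  expect_identical(s2$accel, s$accel)

  bad <- sim_config(failure_windows = data.frame(gateway = "nope",
                                                 start_day = 1, end_day = 1))
  expect_error(inject_failures(s, bad, roster = h$gateways$gateway), "unknown gateway")
})

test_that("technician walk-around dwells about 50 s in every room", {
  wa <- easy_walkaround()
  ann <- wa$annotations
  expect_equal(nrow(ann), 2 * 7)
  expect_true(all(ann$end - ann$start >= 45 & ann$end - ann$start <= 55))
  expect_equal(sort(unique(ann$label)), sort(easy_home()$rooms$label))
  # annotated time covers the stream's RSSI span
  expect_equal(sum(ann$end - ann$start), max(ann$end) - min(ann$start))
  expect_true(max(wa$stream$rssi$time) <= max(ann$end))

  h1 <- generate_home(1, 1, seed = 1)
  wa1 <- simulate_walkaround(h1, sim_config(seed = 1), repeats = 1)
  expect_equal(nrow(wa1$annotations), 1)
})

test_that("PROM fixtures reproduce the study's score table", {
  px <- load_prom_fixture()
  val <- function(p, ins, tp) px$score[px$participant == p & px$instrument == ins &
                                        px$timepoint == tp]
  expect_equal(val("B", "OHS", "FU3"), 42)
  expect_equal(val("C", "OHS", "BL"), 32)
  expect_equal(val("B", "HOOS-QOL", "FU3"), 100)
  ohs <- px$score[px$instrument == "OHS"]
  expect_true(all(ohs >= 0 & ohs <= 48))
  hoos <- px$score[px$instrument == "HOOS-QOL"]
  expect_true(all(hoos >= 0 & hoos <= 100))
})

test_that("control routine's least-active 5 h falls inside the sleep window", {
  # a full week: weekday out-of-home gaps are zero-imputed, so the weekend
  # contribution is what keeps the daytime average above the sleeping level
  h <- easy_home()
  r <- generate_routine("control", 7, seed = 21)
  s <- simulate_stream(h, r, sim_config(seed = 22, accel_hz = 5))
  ep <- epochise(magnitude(s))
  lm <- l5_m10(ep)
  onset <- lm$l5_onset
  # L5 window (onset, onset+5h) inside scheduled sleep 23:00-07:00, wrapping
  in_sleep <- function(m) (m %% 1440) >= 23 * 60 || (m %% 1440) < 7 * 60
  expect_true(in_sleep(onset))
  expect_true(in_sleep(onset + 300 - 1))
})
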