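test_that("magnitude is the Euclidean norm of the axes", {
  acc <- data.frame(time = 0:2, x = c(3, 0, 1), y = c(4, 0, 2), z = c(0, 0, 2))
  expect_equal(magnitude(acc)$A, c(5, 0, 3))
  expect_error(magnitude(data.frame(time = numeric(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0))),
               "no acceleration")
})

test_that("epochising flags and fills gaps per strategy", {
  tt <- seq(0, 3599.8, by = 0.2)
  mag <- data.table(time = tt, A = 1)
  ep <- epochise(mag)
  expect_equal(nrow(ep), 60)
  expect_false(any(ep$imputed))

  # gap 12:00-13:00 within a 11:00-14:00 record, zero imputation
  tt2 <- seq(11 * 3600, 14 * 3600 - 0.2, by = 0.2)
  keep <- tt2 < 12 * 3600 | tt2 >= 13 * 3600
  ep2 <- epochise(data.table(time = tt2[keep], A = 1))
  gap <- ep2$minute >= 12 * 60 & ep2$minute < 13 * 60
  expect_true(all(ep2$imputed[gap]))
  expect_true(all(ep2$mean_g[gap] == 0))
  expect_true(all(ep2$std_g[gap] == 0))
  expect_false(any(ep2$imputed[!gap]))

  # interpolation recovers a linear ramp across the gap exactly
  ramp <- data.table(time = tt2[keep], A = tt2[keep] / 3600)
  ep3 <- epochise(ramp, impute = "interpolate")
  mid <- (ep3$minute * 60 + 29.9) / 3600 # mean sample time within each minute
  expect_equal(ep3$mean_g, mid, tolerance = 1e-6)
  expect_error(epochise(mag, impute = "nearest"))
})

test_that("L5/M10 windows sit where the average profile says", {
  const <- make_epochs(rep(2, 1440))
  lm <- l5_m10(const)
  expect_equal(lm$l5_mean, 2)
  expect_equal(lm$m10_mean, 2)
  expect_equal(lm$l5_onset, 0)   # ties -> earliest clock time
  expect_equal(lm$m10_onset, 0)

  # sinusoid with trough at 03:00: symmetric 5-h window starts 00:30
  tod <- 0:1439
  act <- 1 + cos(2 * pi * (tod - 180) / 1440 + pi)
  lm2 <- l5_m10(make_epochs(rep(act, 2)))
  expect_equal(lm2$l5_onset, 30)
  expect_equal(lm2$m10_onset, (180 + 720 - 300) %% 1440) # 10-h window about the crest

  # square wave: zero activity 23:00-07:00; every 5-h window inside ties at 0
  act3 <- ifelse(tod >= 23 * 60 | tod < 7 * 60, 0, 1)
  lm3 <- l5_m10(make_epochs(rep(act3, 2)))
  expect_equal(lm3$l5_mean, 0)
  onset <- lm3$l5_onset
  expect_true(onset >= 23 * 60 || onset <= 2 * 60) # within wrapped [23:00, 02:00]

  expect_error(l5_m10(make_epochs(rep(1, 100))), "complete day|24")
})

test_that("interdaily stability matches its definition and limits", {
  day <- runif(24)
  expect_equal(interdaily_stability(rep(day, 5)), 1)

  set.seed(41)
  x <- rnorm(24 * 30)
  expect_equal(interdaily_stability(x), bf_is(x), tolerance = 1e-12)
  vals <- vapply(1:5, function(s) { set.seed(s); interdaily_stability(rnorm(720)) },
                 numeric(1))
  expect_true(all(vals < 0.15)) # shuffled noise: no repeating daily structure
  expect_error(interdaily_stability(rep(1, 48)), "zero-variance")
})

test_that("intradaily variability hits its closed forms", {
  alt <- rep(c(1, -1), 24)
  expect_equal(intradaily_variability(alt), 4)

  x <- sin(2 * pi * seq_len(720) / 24)
  expect_equal(intradaily_variability(x), 2 * (1 - cos(2 * pi / 24)),
               tolerance = 5e-3)

  vals <- vapply(1:5, function(s) { set.seed(s); intradaily_variability(rnorm(720)) },
                 numeric(1))
  expect_true(all(abs(vals - 2) < 0.2))

  set.seed(42)
  z <- rnorm(240)
  expect_equal(intradaily_variability(z), bf_iv(z), tolerance = 1e-12)
  expect_warning(iv <- intradaily_variability(rep(3, 48)), "constant")
  expect_true(is.na(iv))
})

test_that("relative amplitude contrasts rest and active levels", {
  expect_equal(relative_amplitude(0, 5), 1)
  expect_equal(relative_amplitude(2, 2), 0)
  expect_equal(relative_amplitude(1, 3), 0.5)
  expect_error(relative_amplitude(0, 0))
  expect_error(relative_amplitude(-1, 2))
})

test_that("delta T is a signed circular difference in minutes", {
  expect_equal(delta_t("01:00", "23:00"), 120)
  expect_equal(delta_t("23:25", "00:00"), -35)
  expect_equal(delta_t("22:00", "22:00"), 0)
  expect_equal(delta_t("10:00", "22:00"), 720) # antipodal maps to +720
})

test_that("movement trend averages observed minutes only", {
  ep <- make_epochs(rep(0, 2 * 1440))
  mt <- movement_trend(ep)
  expect_equal(mt$movement, c(0, 0))

  act <- rep(1, 1440); act[600:659] <- 99
  ep2 <- make_epochs(act)
  ep2$imputed[600:659] <- TRUE
  expect_equal(movement_trend(ep2)$movement, 1)
})

test_that("rhythm metrics are equivariant under a 6-h time shift", {
  tod <- 0:1439
  act <- 1.2 + sin(2 * pi * tod / 1440) + 0.3 * cos(4 * pi * tod / 1440)
  ep <- make_epochs(rep(act, 4))
  ep_shift <- make_epochs(rep(act, 4), start_minute = 360)  # same values, +6 h

  lm <- l5_m10(ep); lms <- l5_m10(ep_shift)
  expect_equal(lms$l5_onset, (lm$l5_onset + 360) %% 1440)
  expect_equal(lms$m10_onset, (lm$m10_onset + 360) %% 1440)
  expect_equal(lms$l5_mean, lm$l5_mean, tolerance = 1e-10)

  expect_equal(interdaily_stability(ep_shift), interdaily_stability(ep),
               tolerance = 1e-9)
  expect_equal(intradaily_variability(ep_shift), intradaily_variability(ep),
               tolerance = 0.05)
  ra <- function(e) { l <- l5_m10(e); relative_amplitude(l$l5_mean, l$m10_mean) }
  expect_equal(ra(ep_shift), ra(ep), tolerance = 1e-9)
})

test_that("imputation strategy shifts IV by the documented amount", {
  set.seed(99)
  tt <- seq(0, 3 * 86400 - 0.2, by = 0.2)
  tod <- (tt %% 86400) / 86400
  A <- 1 + rnorm(length(tt), 0, 0.02 + 0.015 * sin(2 * pi * tod))
  gap <- tt >= 86400 + 12 * 3600 & tt < 86400 + 16 * 3600
  mag <- data.table(time = tt[!gap], A = A[!gap])
  delta <- intradaily_variability(epochise(mag, "zero")) -
    intradaily_variability(epochise(mag, "interpolate"))
  expect_equal(delta, 0.04095417, tolerance = 1e-6)
})

test_that("metric ranges hold over random epoch series", {
  for (s in 1:5) {
    set.seed(s)
    ep <- make_epochs(abs(rnorm(3 * 1440, 0.05, 0.04)))
    expect_gte(interdaily_stability(ep), 0)
    expect_lte(interdaily_stability(ep), 1)
    expect_gte(intradaily_variability(ep), 0)
    lm <- l5_m10(ep)
    ra <- relative_amplitude(lm$l5_mean, lm$m10_mean)
    expect_gte(ra, 0); expect_lte(ra, 1)
  }
})
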