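# Shared fixtures and independent brute-force oracles. Expensive simulations
# are cached per test run so several files can reuse them.

library(data.table)

.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# construct an epoch_activity table directly from a per-minute activity vector
make_epochs <- function(act, start_minute = 0, mean_g = 1, imputed = FALSE) {
  n <- length(act)
  out <- data.table(
    epoch = (start_minute + seq_len(n) - 1L) * 60,
    minute = start_minute + seq_len(n) - 1L,
    mean_g = rep_len(mean_g, n), min_g = rep_len(mean_g, n),
    max_g = rep_len(mean_g, n), std_g = act,
    imputed = rep_len(imputed, n)
  )
  setattr(out, "class", c("epoch_activity", class(out)))
  out
}

# brute-force per-window RSSI statistics straight from the raw readings
bf_rssi_features <- function(rssi, roster, oor = -100) {
  wins <- sort(unique(floor(rssi$time)))
  rows <- lapply(wins, function(w) {
    inw <- rssi[floor(rssi$time) == w, ]
    vals <- unlist(lapply(roster, function(g) {
      v <- inw$rssi[inw$gateway == g]
      if (length(v) == 0) v <- oor
      c(sum(v), mean(v), min(v), max(v), mean((v - mean(v))^2))
    }))
    c(w, vals)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("window",
                   as.vector(t(outer(roster, c("sum", "mean", "min", "max", "var"),
                                     paste, sep = "_"))))
  m
}

# brute-force double-loop interdaily stability on an hourly vector
bf_is <- function(x, p = 24) {
  n <- length(x); xbar <- mean(x)
  num <- 0
  for (h in 0:(p - 1)) {
    xh <- x[seq_along(x)[(seq_along(x) - 1) %% p == h]]
    num <- num + (mean(xh) - xbar)^2
  }
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - xbar)^2
  (n * num) / (p * den)
}

# brute-force intradaily variability
bf_iv <- function(x) {
  n <- length(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  den <- 0
  for (i in seq_len(n)) den <- den + (x[i] - mean(x))^2
  (n * num) / ((n - 1) * den)
}

# brute-force activity-window features for one window of samples
bf_activity_features <- function(w) {
  gf <- sqrt(w$x^2 + w$y^2 + w$z^2) - 1
  gfc <- pmin(pmax(gf, -4), 4 - 1e-12)
  h <- tabulate(floor((gfc + 4) / 0.8) + 1, 10) / nrow(w)
  c(x_mean = mean(w$x), x_sd = sd(w$x), y_mean = mean(w$y), y_sd = sd(w$y),
    z_mean = mean(w$z), z_sd = sd(w$z), gf_mean = mean(gf), gf_sd = sd(gf),
    setNames(h, paste0("h", 1:10)))
}

# shared 7-room/5-gateway home and a fast-trained localiser on its walk-around
easy_home <- function() cached("easy_home", generate_home(7, 5, seed = 1))

easy_walkaround <- function() cached("easy_walkaround", {
  simulate_walkaround(easy_home(), sim_config(seed = 2, shadow_sd = 3))
})

easy_labelled <- function() cached("easy_labelled", {
  wa <- easy_walkaround()
  label_features(featurise_rssi(wa$stream, easy_home()$gateways$gateway),
                 wa$annotations)
})

fast_grid <- data.frame(solver = "adam", learning_rate = 1e-2, momentum = 0.9)

easy_localiser_fast <- function() cached("easy_localiser_fast", {
  train_localiser(easy_labelled(), seed = 1, grid = fast_grid)
})

# pooled labelled windows from ten scripted activity experiments at 25 Hz
activity_corpus <- function() cached("activity_corpus", {
  h <- easy_home()
  cfg <- sim_config(seed = 5)
  rbindlist(lapply(1:10, function(i) {
    sc <- simulate_script(h, cfg, seed = i)
    label_windows(featurise_activity(sc$stream, hz = 25), sc$annotations)
  }))
})
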