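# Indoor localisation from RSSI fingerprints: 1-s window statistics per
# gateway, MLP room classifier with grid-search tuning, per-second location
# timelines, daily occupancy distributions and gateway-health diagnostics.

RSSI_STATS <- c("sum", "mean", "min", "max", "var")

feature_cols <- function(roster) {
  as.vector(t(outer(roster, RSSI_STATS, paste, sep = "_")))
}

#' RSSI fingerprint features over 1-s windows
#'
#' Windows are half-open `[t, t+1)` aligned to integer epoch seconds. For each
#' gateway with readings in the window, the sum, mean, minimum, maximum and
#' variance (population definition) of RSSI are computed. A gateway silent in a
#' window where at least one other gateway reports is substituted with a single
#' synthetic reading at the out-of-range constant, giving the block
#' `(-100, -100, -100, -100, 0)`. Windows in which every gateway is silent
#' produce no feature vector.
#'
#' @param stream a `sensor_stream` (or a data.table with time, gateway, rssi).
#' @param roster character vector of gateway ids fixing block order.
#' @param oor_db out-of-range substitution constant in dB (default -100).
#' @return data.table with `window` (window start, s) and `5 * length(roster)`
#'   feature columns named `<gateway>_<stat>`; attribute `roster`.
#' @export
featurise_rssi <- function(stream, roster, oor_db = -100) {
  if (length(roster) == 0) stop("empty roster")
  rssi <- if (inherits(stream, "sensor_stream")) stream$rssi else as.data.table(stream)
  cols <- feature_cols(roster)
  if (nrow(rssi) == 0) {
    out <- setNames(data.table(numeric(0)), "window")
    for (cl in cols) out[, (cl) := numeric(0)]
    setattr(out, "roster", roster)
    return(out)
  }
  rssi <- rssi[gateway %in% roster]
  dt <- rssi[, .(time, gateway, rssi)]
  dt[, window := floor(time)]
  st <- dt[, .(
    sum = sum(rssi), mean = mean(rssi), min = min(rssi), max = max(rssi),
    var = mean((rssi - mean(rssi))^2)
  ), by = .(window, gateway)]
  long <- melt(st, id.vars = c("window", "gateway"),
               variable.name = "stat", variable.factor = FALSE)
  long[, gateway := factor(gateway, levels = roster)]
  wide <- dcast(long, window ~ gateway + stat, value.var = "value",
                drop = c(TRUE, FALSE))
  # silent-gateway substitution: one synthetic -100 dB reading
  for (g in roster) {
    for (stat in RSSI_STATS) {
      cl <- paste(g, stat, sep = "_")
      if (!cl %in% names(wide)) wide[, (cl) := NA_real_]
      fill <- if (stat == "var") 0 else oor_db
      set(wide, which(is.na(wide[[cl]])), cl, fill)
    }
  }
  setcolorder(wide, c("window", cols))
  setorder(wide, window)
  setattr(wide, "roster", roster)
  wide[]
}

#' Label feature vectors from an annotation track
#'
#' A vector receives the label of the (non-overlapping) annotation interval
#' containing its window start; vectors outside every interval are dropped.
#' Vectors from all walk-around repeats are pooled.
#'
#' @param vectors output of [featurise_rssi()].
#' @param annotations data.table start/end/label (location kind).
#' @return the labelled subset with a `label` column.
#' @export
label_features <- function(vectors, annotations) {
  ann <- as.data.table(annotations)
  if ("kind" %in% names(ann) && any(ann$kind != "location")) {
    stop("annotations must be location-kind")
  }
  setorder(ann, start)
  idx <- findInterval(vectors$window, ann$start)
  ok <- idx >= 1 & vectors$window < ann$end[pmax(idx, 1)]
  if (!any(ok)) stop("no overlap between feature vectors and annotations")
  out <- copy(vectors)[ok]
  out[, label := ann$label[idx[ok]]]
  setattr(out, "roster", attr(vectors, "roster"))
  out[]
}

#' Default hyperparameter grid for the localiser
#'
#' Solver (adaptive-moment vs gradient descent with momentum), learning rate
#' and momentum; selection is by training-set accuracy.
#' @return data.frame grid.
#' @export
localiser_grid <- function() {
  expand.grid(solver = c("adam", "sgd"), learning_rate = c(1e-2, 1e-3, 1e-4),
              momentum = c(0.5, 0.9), stringsAsFactors = FALSE)
}

#' Train the per-home room classifier
#'
#' Labelled fingerprint vectors are shuffled and split 60/40 (stratified by
#' room) into training and test sets. An MLP with three 10-node hidden layers
#' is tuned by grid search over solver, learning rate and momentum, the
#' configuration with the highest training-set accuracy being selected; test
#' metrics (accuracy, support-weighted precision/recall/F1, support) are
#' reported on the held-out 40%. Features are standardised internally using
#' training-set moments. A degenerate single-label set yields a trivial
#' constant classifier with a warning.
#'
#' @param labelled output of [label_features()].
#' @param seed RNG seed controlling split, initialisation and tuning.
#' @param grid hyperparameter grid (see [localiser_grid()]).
#' @param hidden hidden-layer widths.
#' @param max_epochs training epochs per fit.
#' @return object of class `localiser` with the fitted network, scaling,
#'   labels, roster, tuning record, split indices, test `metrics` and
#'   `confusion` matrix.
#' @export
train_localiser <- function(labelled, seed = 1, grid = localiser_grid(),
                            hidden = c(10, 10, 10), max_epochs = 400) {
  roster <- attr(labelled, "roster")
  cols <- feature_cols(roster)
  x <- as.matrix(as.data.table(labelled)[, cols, with = FALSE])
  y <- factor(labelled$label)

  if (nlevels(y) < 2) {
    warning("single-label training set: returning trivial constant classifier")
    metrics <- list(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                    support = length(y))
    return(structure(list(constant = levels(y), roster = roster,
                          labels = levels(y), seed = seed, metrics = metrics,
                          confusion = table(y, y)), class = "localiser"))
  }
  if (any(table(y) < 10)) stop("need >= 10 examples per label")

  split <- stratified_split(y, 0.6, seed)
  centre <- colMeans(x[split$train, , drop = FALSE])
  scl <- apply(x[split$train, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scl, "/")
  xtr <- xs[split$train, , drop = FALSE]; ytr <- y[split$train]
  xte <- xs[split$test, , drop = FALSE];  yte <- y[split$test]

  fits <- vector("list", nrow(grid)); score <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    fits[[k]] <- fit_mlp(xtr, ytr, hidden = hidden, solver = grid$solver[k],
                         learning_rate = grid$learning_rate[k],
                         momentum = grid$momentum[k],
                         max_epochs = max_epochs, seed = seed)
    score[k] <- mean(predict(fits[[k]], xtr) == ytr)
  }
  best <- which.max(score)
  net <- fits[[best]]
  pred <- predict(net, xte)
  metrics <- weighted_metrics(yte, pred, labels = levels(y))
  tuning <- cbind(grid, train_accuracy = score,
                  chosen = seq_len(nrow(grid)) == best)
  structure(list(net = net, centre = centre, scale = scl, roster = roster,
                 labels = levels(y), seed = seed, tuning = tuning,
                 split = split,
                 metrics = metrics[c("accuracy", "precision", "recall", "f1", "support")],
                 per_class = metrics$per_class, confusion = metrics$confusion),
            class = "localiser")
}

#' @export
print.localiser <- function(x, ...) {
  cat("<localiser> rooms:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  test accuracy %.3f  weighted F1 %.3f  support %d\n",
                x$metrics$accuracy, x$metrics$f1 %||% NA, x$metrics$support))
  }
  invisible(x)
}

predict_rooms <- function(model, vectors) {
  if (!is.null(model$constant)) {
    return(factor(rep(model$constant, nrow(vectors)), levels = model$labels))
  }
  cols <- feature_cols(model$roster)
  x <- as.matrix(as.data.table(vectors)[, cols, with = FALSE])
  xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
  predict(model$net, xs)
}

#' Per-second location timeline
#'
#' Applies a trained localiser to a stream; every integer second in the span
#' receives a room label, or `"unknown"` when no feature vector exists for that
#' second (wearable out of range of every gateway).
#'
#' @param model a `localiser`.
#' @param stream a `sensor_stream`.
#' @param span optional `c(start, end)` seconds; defaults to the range of the
#'   stream's records.
#' @return data.table `time`, `label` (factor over rooms + "unknown").
#' @export
predict_timeline <- function(model, stream, span = NULL) {
  feats <- featurise_rssi(stream, model$roster)
  if (is.null(span)) {
    lo <- suppressWarnings(min(stream$rssi$time, stream$accel$time))
    hi <- suppressWarnings(max(stream$rssi$time, stream$accel$time))
    if (!is.finite(lo)) stop("empty stream and no span given")
    span <- c(floor(lo), ceiling(hi))
  }
  secs <- seq(floor(span[1]), ceiling(span[2]) - 1)
  lev <- c(model$labels, "unknown")
  label <- factor(rep("unknown", length(secs)), levels = lev)
  if (nrow(feats) > 0) {
    pred <- predict_rooms(model, feats)
    hit <- match(feats$window, secs)
    ok <- !is.na(hit)
    label[hit[ok]] <- as.character(pred)[ok]
  }
  data.table(time = secs, label = label)
}

#' Daily location distribution
#'
#' Percentage of each day spent per label (rooms plus "unknown"); seconds of a
#' day not covered by the timeline's span are excluded, so percentages sum to
#' 100 within each day.
#'
#' @param timeline output of [predict_timeline()] (data.table time, label).
#' @return data.table `day` (1-based), `label`, `percent`.
#' @export
daily_distribution <- function(timeline) {
  if (nrow(timeline) == 0) stop("empty timeline")
  tl <- copy(as.data.table(timeline))
  tl[, day := floor(time / SECS_DAY) + 1L]
  out <- tl[, .N, by = .(day, label)]
  out[, percent := 100 * N / sum(N), by = day]
  setorder(out, day, label)
  out[, .(day, label, percent)]
}

#' Gateway health report
#'
#' Daily message counts per gateway and outage flags: a gateway-day is flagged
#' when that gateway reports nothing while other gateways do. Consecutive
#' flagged days are consolidated into outage ranges.
#'
#' @param stream a `sensor_stream`.
#' @param roster gateway ids to audit.
#' @return object of class `gateway_health`: list with `counts`
#'   (day, gateway, n) and `outages` (gateway, start_day, end_day).
#' @export
gateway_health <- function(stream, roster) {
  rssi <- stream$rssi
  if (nrow(rssi) == 0) {
    return(structure(list(
      counts = data.table(day = integer(0), gateway = character(0), n = integer(0)),
      outages = data.table(gateway = character(0), start_day = integer(0),
                           end_day = integer(0))), class = "gateway_health"))
  }
  dt <- rssi[, .(day = floor(time / SECS_DAY) + 1L, gateway)]
  days <- seq(min(dt$day), max(dt$day))
  grid <- CJ(day = days, gateway = roster)
  counts <- dt[, .(n = .N), by = .(day, gateway)]
  counts <- counts[grid, on = c("day", "gateway")]
  counts[is.na(n), n := 0L]
  counts[, total := sum(n), by = day]
  flagged <- counts[n == 0L & total > 0L]
  outages <- if (nrow(flagged)) {
    setorder(flagged, gateway, day)
    flagged[, grp := cumsum(c(1L, diff(day) != 1L)), by = gateway]
    flagged[, .(start_day = min(day), end_day = max(day)), by = .(gateway, grp)][
      , .(gateway, start_day, end_day)]
  } else {
    data.table(gateway = character(0), start_day = integer(0), end_day = integer(0))
  }
  counts[, total := NULL]
  structure(list(counts = counts[], outages = outages[]), class = "gateway_health")
}

#' @export
print.gateway_health <- function(x, ...) {
  cat("<gateway_health> ", nrow(x$counts), " gateway-days, ",
      nrow(x$outages), " outage range(s)\n", sep = "")
  invisible(x)
}
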