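# Posture/ambulation classification from sliding 6-s acceleration windows:
# per-axis and gravity-free statistics plus a 10-bin histogram feed a
# 100-tree random forest evaluated by stratified 5-fold cross-validation.

HIST_EDGES <- seq(-4, 4, length.out = 11)

#' Gravity-free signal of an acceleration window
#'
#' Euclidean norm of the tri-axial signal with the static 1 g gravity offset
#' subtracted, so motionless samples centre on 0 (and free fall maps to -1).
#'
#' @param window data.frame with columns x, y, z (g).
#' @return numeric vector, g units.
#' @export
gravity_free <- function(window) {
  sqrt(window$x^2 + window$y^2 + window$z^2) - 1
}

#' Sliding-window activity features
#'
#' Applies a 6-s window with a 3-s step to the acceleration record (windows
#' with fewer than `width * hz` samples are dropped). Each window yields an
#' 18-dimensional vector: per-axis mean and standard deviation (6), mean and
#' standard deviation of the gravity-free signal (2), and a normalised 10-bin
#' histogram of the gravity-free signal over `[-4, 4]` g (10); out-of-range
#' samples are clipped into the edge bins (count recorded in attribute
#' `clipped`), so the histogram always sums to 1.
#'
#' @param accel data.table time, x, y, z (or a `sensor_stream`).
#' @param hz sampling rate in Hz (wearable nominal 25).
#' @param width window length in seconds.
#' @param step window step in seconds.
#' @return data.table `window` (start, s), `x_mean`, `x_sd`, ..., `gf_mean`,
#'   `gf_sd`, `h1`..`h10`.
#' @export
featurise_activity <- function(accel, hz = 25, width = 6, step = 3) {
  acc <- if (inherits(accel, "sensor_stream")) accel$accel else as.data.table(accel)
  if (nrow(acc) == 0) stop("no acceleration records")
  need <- as.integer(round(width * hz))
  t0 <- min(acc$time)
  offsets <- seq(0, width - step, by = step)
  clipped_total <- 0L

  res <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    off <- offsets[i]
    dt <- acc[, .(time, x, y, z)]
    dt[, ws := t0 + off + width * floor((time - t0 - off) / width)]
    dt <- dt[ws >= t0]
    dt[, gf := sqrt(x^2 + y^2 + z^2) - 1]
    clipped_total <- clipped_total + sum(dt$gf < -4 | dt$gf > 4)
    dt[, bin := pmin(pmax(floor((gf + 4) / 0.8), 0), 9)]
    st <- dt[, .(
      n = .N,
      x_mean = mean(x), x_sd = sd(x), y_mean = mean(y), y_sd = sd(y),
      z_mean = mean(z), z_sd = sd(z), gf_mean = mean(gf), gf_sd = sd(gf)
    ), by = ws]
    hc <- dt[, .(count = .N), by = .(ws, bin)]
    hw <- dcast(hc, ws ~ bin, value.var = "count", fill = 0L)
    for (b in 0:9) if (!as.character(b) %in% names(hw)) hw[, (as.character(b)) := 0L]
    setcolorder(hw, c("ws", as.character(0:9)))
    setnames(hw, as.character(0:9), paste0("h", 1:10))
    st <- st[hw, on = "ws"]
    res[[i]] <- st[n == need]
  }
  out <- rbindlist(res)
  for (b in paste0("h", 1:10)) out[, (b) := get(b) / n]
  out[, n := NULL]
  setnames(out, "ws", "window")
  setorder(out, window)
  setattr(out, "clipped", clipped_total)
  setattr(out, "hz", hz)
  out[]
}

#' Label activity windows from an annotation track
#'
#' A window is labelled with the activity of the interval that fully contains
#' it (`[window, window + width]`); windows straddling interval boundaries or
#' outside every interval are dropped.
#'
#' @param features output of [featurise_activity()].
#' @param annotations data.table start/end/label (activity kind).
#' @param width window length in seconds.
#' @return the labelled subset with a `label` column.
#' @export
label_windows <- function(features, annotations, width = 6) {
  ann <- as.data.table(annotations)
  if ("kind" %in% names(ann) && any(ann$kind != "activity")) {
    stop("annotations must be activity-kind")
  }
  setorder(ann, start)
  idx <- findInterval(features$window, ann$start)
  ok <- idx >= 1 & (features$window + width) <= ann$end[pmax(idx, 1)]
  out <- copy(features)[ok]
  out[, label := ann$label[idx[ok]]]
  out[]
}

activity_feature_cols <- function() {
  c("x_mean", "x_sd", "y_mean", "y_sd", "z_mean", "z_sd",
    "gf_mean", "gf_sd", paste0("h", 1:10))
}

#' Train the posture/ambulation classifier
#'
#' A random forest (100 trees, Gini splits, sqrt(p) features per split,
#' bootstrap resampling) on the 18-dimensional window features. Several
#' candidate seeds are tried and the one with the highest training accuracy is
#' kept (an optimistic selection, preserved deliberately); generalisation is
#' estimated by stratified 5-fold cross-validation whose pooled out-of-fold
#' predictions form the confusion matrix. The final model is refit on all data
#' with the winning seed.
#'
#' @param features output of [featurise_activity()] (pooled across scripted
#'   experiments), or any data.frame containing the feature columns.
#' @param labels factor/character of activity labels, same length.
#' @param seeds candidate RNG seeds, default 10 consecutive ones.
#' @param nfolds folds for cross-validation.
#' @param ntree trees in the forest.
#' @param fold_seed seed for the fold assignment.
#' @return object of class `activity_model`: the forest, class levels, chosen
#'   seed, seed record, pooled CV `confusion` and `cv_accuracy`.
#' @export
train_activity <- function(features, labels, seeds = 1:10, nfolds = 5,
                           ntree = 100, fold_seed = 1) {
  x <- as.data.frame(features)[, activity_feature_cols()]
  y <- factor(as.character(labels),
              levels = intersect(ACTIVITY_CLASSES, unique(as.character(labels))))
  if (nlevels(y) < 2) stop("need >= 2 activity classes")

  train_acc <- vapply(seeds, function(s) {
    set.seed(s)
    rf <- randomForest(x, y, ntree = ntree)
    mean(predict(rf, x) == y)
  }, numeric(1))
  chosen <- seeds[which.max(train_acc)]

  fold <- stratified_folds(y, nfolds, fold_seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(nfolds)) {
    set.seed(chosen + k)
    rf_k <- randomForest(x[fold != k, ], y[fold != k], ntree = ntree)
    pred[fold == k] <- predict(rf_k, x[fold == k, ])
  }
  confusion <- table(true = y, predicted = pred)
  set.seed(chosen)
  forest <- randomForest(x, y, ntree = ntree)
  structure(list(forest = forest, levels = levels(y), seed = chosen,
                 seed_record = data.frame(seed = seeds, train_accuracy = train_acc),
                 confusion = confusion,
                 cv_accuracy = mean(pred == y)),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat("<activity_model> classes:", paste(x$levels, collapse = ", "), "\n")
  cat(sprintf("  CV accuracy %.3f (seed %d)\n", x$cv_accuracy, x$seed))
  invisible(x)
}

#' Daily activity distribution
#'
#' Classifies every full 6-s window of the stream and reports the percentage
#' of classified windows per activity class per day (percentages sum to 100
#' within each day). The per-window timeline is attached as attribute
#' `timeline`.
#'
#' @param model an `activity_model`.
#' @param stream a `sensor_stream` or acceleration data.table.
#' @param hz accelerometer sampling rate.
#' @return data.table `day` (1-based), `label`, `percent`; attribute
#'   `timeline` (data.table window, label).
#' @export
predict_daily_activity <- function(model, stream, hz = 25) {
  feats <- featurise_activity(stream, hz = hz)
  pred <- predict(model$forest, as.data.frame(feats)[, activity_feature_cols()])
  timeline <- data.table(window = feats$window, label = pred)
  tl <- copy(timeline)
  tl[, day := floor(window / SECS_DAY) + 1L]
  out <- tl[, .N, by = .(day, label)]
  out[, percent := 100 * N / sum(N), by = day]
  setorder(out, day, label)
  out <- out[, .(day, label, percent)]
  setattr(out, "timeline", timeline)
  out[]
}
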