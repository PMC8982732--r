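SECS_DAY <- 86400L
MINS_DAY <- 1440L

#' Parse a clock time to minutes past midnight
#'
#' Accepts `"HH:MM"` strings or numeric minutes; values are wrapped onto
#' `[0, 1440)`.
#' @param x character `"HH:MM"` vector or numeric minutes.
#' @return numeric minutes past midnight in `[0, 1440)`.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x %% MINS_DAY)
  vapply(strsplit(x, ":", fixed = TRUE), function(p) {
    as.numeric(p[[1]]) * 60 + as.numeric(p[[2]])
  }, numeric(1)) %% MINS_DAY
}

#' Format minutes past midnight as "HH:MM"
#' @param m numeric minutes past midnight.
#' @return character vector.
#' @export
format_clock <- function(m) {
  m <- floor(m) %% MINS_DAY
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# signed circular difference a - b in minutes, range (-720, 720]
clock_diff <- function(a, b) {
  d <- (a - b) %% MINS_DAY
  ifelse(d > 720, d - MINS_DAY, d)
}

# stratified train/test split; returns list(train=, test=) of integer indices
stratified_split <- function(y, p = 0.6, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (lev in levels(factor(y))) {
    idx <- which(y == lev)
    idx <- sample(idx)
    n_tr <- max(1L, floor(p * length(idx)))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# stratified k-fold assignment; errors if a class has fewer members than k
stratified_folds <- function(y, k = 5, seed = 1) {
  set.seed(seed)
  y <- factor(y)
  if (any(table(y) < k)) {
    stop("stratification failure: a class has fewer than ", k, " examples")
  }
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# accuracy plus support-weighted precision/recall/F1 and confusion matrix
weighted_metrics <- function(true, pred, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(as.character(true), as.character(pred))))
  true <- factor(true, levels = labels)
  pred <- factor(pred, levels = labels)
  cm <- table(true = true, predicted = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  w <- support / sum(support)
  list(
    accuracy = mean(as.character(true) == as.character(pred)),
    precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1),
    support = sum(support),
    per_class = data.frame(label = labels, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           support = as.numeric(support)),
    confusion = cm
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
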