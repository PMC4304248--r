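#' Confusion counts
#'
#' @param truth,predicted class label vectors; `NA` predictions are dropped.
#' @param positive the class counted as positive (default `"abnormal"`, the
#'   clinical detection target).
#' @return list of class `aeeg_confusion`: `tp`, `fn`, `tn`, `fp`,
#'   `positive`.
#' @export
confusion_counts <- function(truth, predicted, positive = "abnormal") {
  positive <- match.arg(positive, AEEG_CLASSES)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length")
  }
  keep <- !is.na(predicted)
  truth <- truth[keep]
  predicted <- predicted[keep]
  if (!length(truth)) stop("no evaluated samples")
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p),
                 positive = positive),
            class = "aeeg_confusion")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity is the true-positive rate `tp / (tp + fn)`, specificity the
#' true-negative rate `tn / (tn + fp)`, the correct rate the overall
#' accuracy, F1 the harmonic mean of precision and recall, and the G-mean
#' the geometric mean `sqrt(sensitivity * specificity)` — a summary that is
#' independent of the class distribution and is maximal only when both
#' rates are high, which is what matters on imbalanced data.
#'
#' Ratios with a zero denominator are returned as `NA` (flagged, never
#' silently 0).
#'
#' @param counts an [confusion_counts()] result.
#' @return list of class `aeeg_metrics`: `correct_rate`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `g_mean`, `n`, `positive`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "aeeg_confusion"))
  total <- counts$tp + counts$fn + counts$tn + counts$fp
  if (total == 0) stop("no evaluated samples")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(counts$tp, counts$tp + counts$fn)
  spec <- rat(counts$tn, counts$tn + counts$fp)
  prec <- rat(counts$tp, counts$tp + counts$fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  g <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  structure(list(correct_rate = (counts$tp + counts$tn) / total,
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1 = f1, g_mean = g, n = total,
                 positive = counts$positive),
            class = "aeeg_metrics")
}

#' @export
print.aeeg_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%5.2f", 100 * v)
  cat(sprintf(paste0(
    "correct rate %s%%  sensitivity %s%%  specificity %s%%  ",
    "F1 %s%%  G-mean %s%%  (n = %d, positive = %s)\n"),
    pct(x$correct_rate), pct(x$sensitivity), pct(x$specificity),
    pct(x$f1), pct(x$g_mean), x$n, x$positive))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin. The fold position carries over between classes so the
# remainder samples of different classes land on different folds, keeping
# overall fold sizes within one of each other as well.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  fold <- integer(n)
  pos <- 0L
  with_seed(seed, function() {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <<- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <<- pos + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into `k` stratified folds (class proportions preserved to
#' within one sample), trains on k-1 folds and evaluates on the held-out
#' fold, then pools the confusion counts over folds.
#'
#' @param x feature matrix.
#' @param labels class labels.
#' @param k number of folds (default 10).
#' @param train_fn `function(x, labels)` returning a model
#'   (default: [rf_fit()] with `config`).
#' @param predict_fn `function(model, x)` returning class labels
#'   (default: [rf_predict()]).
#' @param config forest config used by the default `train_fn`.
#' @param seed fold-assignment seed.
#' @param positive positive class for the metrics.
#' @return list with `fold_metrics` (list of [compute_metrics()] results),
#'   `pooled` (metrics from summed counts), and `folds` (assignment vector).
#' @export
kfold_cv <- function(x, labels, k = 10L, train_fn = NULL, predict_fn = NULL,
                     config = forest_config(), seed = 1L,
                     positive = "abnormal") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > min(table(labels))) {
    stop("k exceeds the minority class count; folds would be unusable")
  }
  if (is.null(train_fn)) {
    train_fn <- function(xt, lt) rf_fit(xt, lt, config)
  }
  if (is.null(predict_fn)) {
    predict_fn <- function(model, xt) rf_predict(model, xt)$class
  }
  fold <- stratified_folds(labels, k, seed)
  pooled <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_fn(x[!test, , drop = FALSE], labels[!test])
    pred <- predict_fn(model, x[test, , drop = FALSE])
    cc <- confusion_counts(labels[test], pred, positive)
    pooled <- pooled + c(tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp)
    fold_metrics[[f]] <- compute_metrics(cc)
  }
  pooled_cc <- structure(
    list(tp = as.numeric(pooled["tp"]), fn = as.numeric(pooled["fn"]),
         tn = as.numeric(pooled["tn"]), fp = as.numeric(pooled["fp"]),
         positive = positive),
    class = "aeeg_confusion")
  list(fold_metrics = fold_metrics, pooled = compute_metrics(pooled_cc),
       folds = fold)
}

sweep_seed <- function(master, grid_index, rep) {
  derive_seed(master, 1009L * grid_index + rep)
}

#' Sweep the forest size
#'
#' For each candidate `n_tree`, fits `repeats` forests under derived seeds
#' and reports the mean out-of-bag error. The error stabilizes once the
#' forest is large enough; the sweep shows where.
#'
#' @param x feature matrix.
#' @param labels class labels.
#' @param grid candidate `n_tree` values.
#' @param config base [forest_config()] (its `m_try`, weights and master
#'   seed are used).
#' @param repeats seeded repeats averaged per grid value (default 5).
#' @return data.frame `(n_tree, oob_error)`, sorted by `n_tree`.
#' @export
sweep_ntree <- function(x, labels, grid, config = forest_config(),
                        repeats = 5L) {
  if (!length(grid)) stop("empty grid")
  grid <- sort(as.integer(grid))
  err <- vapply(seq_along(grid), function(gi) {
    mean(vapply(seq_len(repeats), function(r) {
      cfg <- config
      cfg$n_tree <- grid[gi]
      cfg$seed <- sweep_seed(config$seed, gi, r)
      fit <- rf_fit(x, labels, cfg)
      as.numeric(oob_error(fit, x, labels))
    }, 0.0))
  }, 0.0)
  data.frame(n_tree = grid, oob_error = err)
}

#' Sweep the number of candidate variables per split
#'
#' As [sweep_ntree()], with the forest size held fixed and `m_try` varied.
#'
#' @param x feature matrix.
#' @param labels class labels.
#' @param grid candidate `m_try` values in `[1, p]`.
#' @param n_tree forest size per fit (default 1000).
#' @param config base [forest_config()].
#' @param repeats seeded repeats per grid value.
#' @return data.frame `(m_try, oob_error)`, sorted by `m_try`.
#' @export
sweep_mtry <- function(x, labels, grid, n_tree = 1000L,
                       config = forest_config(), repeats = 5L) {
  if (!length(grid)) stop("empty grid")
  grid <- sort(as.integer(grid))
  if (any(grid < 1L) || any(grid > ncol(x))) {
    stop("m_try grid values must be in [1, ", ncol(x), "]")
  }
  err <- vapply(seq_along(grid), function(gi) {
    mean(vapply(seq_len(repeats), function(r) {
      cfg <- config
      cfg$n_tree <- as.integer(n_tree)
      cfg$m_try <- grid[gi]
      cfg$seed <- sweep_seed(config$seed, gi, r)
      fit <- rf_fit(x, labels, cfg)
      as.numeric(oob_error(fit, x, labels))
    }, 0.0))
  }, 0.0)
  data.frame(m_try = grid, oob_error = err)
}

#' Sweep the abnormal:normal class-weight ratio
#'
#' Raising the minority (abnormal) weight makes its misclassification more
#' costly, trading specificity for sensitivity; the G-mean balances the
#' two. For each ratio the function fits `repeats` forests, computes
#' out-of-bag metrics with abnormal as the positive class, and averages.
#' The recommended ratio is the G-mean argmax (ties to the smaller ratio).
#'
#' @param x feature matrix.
#' @param labels class labels.
#' @param ratios positive abnormal:normal weight ratios.
#' @param config base [forest_config()].
#' @param repeats seeded repeats per ratio.
#' @return data.frame `(ratio, correct_rate, g_mean, sensitivity,
#'   specificity)` with attribute `recommended_ratio`.
#' @export
sweep_class_weight <- function(x, labels, ratios = c(1, 2, 3, 5),
                               config = forest_config(), repeats = 5L) {
  if (any(ratios <= 0)) stop("ratios must be > 0")
  rows <- lapply(seq_along(ratios), function(gi) {
    ms <- lapply(seq_len(repeats), function(r) {
      cfg <- config
      cfg$class_weights <- c(abnormal = ratios[gi], normal = 1)
      cfg$seed <- sweep_seed(config$seed, gi, r)
      fit <- rf_fit(x, labels, cfg)
      op <- oob_predict(fit, x)
      compute_metrics(confusion_counts(labels, op$class, "abnormal"))
    })
    avg <- function(fld) mean(vapply(ms, function(m) m[[fld]], 0.0))
    data.frame(ratio = ratios[gi], correct_rate = avg("correct_rate"),
               g_mean = avg("g_mean"), sensitivity = avg("sensitivity"),
               specificity = avg("specificity"))
  })
  out <- do.call(rbind, rows)
  best <- which(out$g_mean == max(out$g_mean))
  attr(out, "recommended_ratio") <- out$ratio[best[which.min(out$ratio[best])]]
  out
}
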