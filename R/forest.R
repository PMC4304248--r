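#' Default number of candidate variables per split
#'
#' The customary random-forest default: the square root of the number of
#' input variables, rounded. For the 119-dimensional combined aEEG feature
#' set this gives 11.
#'
#' @param p number of features.
#' @return integer >= 1.
#' @export
default_mtry <- function(p) max(1L, as.integer(round(sqrt(p))))

#' Forest configuration
#'
#' @param n_tree number of trees (default 1000).
#' @param m_try candidate features per node; default `round(sqrt(p))`,
#'   resolved at fit time.
#' @param class_weights named positive weights, `c(abnormal =, normal =)`.
#'   Default 3:1 — the minority abnormal class carries the higher
#'   misclassification cost. Weights enter the Gini criterion and the leaf
#'   vote, not the bootstrap.
#' @param seed master seed; per-tree seeds are derived from it so the forest
#'   is reproducible independent of execution order.
#' @param min_leaf minimum samples per child (default 1; trees are grown
#'   fully, no depth cap, no pruning).
#' @param vote_mode `"prob"` averages per-tree weighted leaf probability
#'   vectors (soft vote, default); `"vote"` counts hard per-tree class votes.
#' @return list of class `aeeg_forest_config`.
#' @export
forest_config <- function(n_tree = 1000L, m_try = NULL,
                          class_weights = c(abnormal = 3, normal = 1),
                          seed = 1L, min_leaf = 1L,
                          vote_mode = c("prob", "vote")) {
  vote_mode <- match.arg(vote_mode)
  n_tree <- as.integer(n_tree)
  if (n_tree < 1L) stop("n_tree must be >= 1")
  if (!all(AEEG_CLASSES %in% names(class_weights))) {
    stop("class_weights must be named with: ",
         paste(AEEG_CLASSES, collapse = ", "))
  }
  cw <- as.numeric(class_weights[AEEG_CLASSES])
  names(cw) <- AEEG_CLASSES
  if (any(!is.finite(cw)) || any(cw <= 0)) stop("class weights must be > 0")
  structure(list(n_tree = n_tree, m_try = m_try, class_weights = cw,
                 seed = as.integer(seed), min_leaf = as.integer(min_leaf),
                 vote_mode = vote_mode),
            class = "aeeg_forest_config")
}

# Map labels to the internal 0/1 coding (0 = abnormal, 1 = normal).
encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), AEEG_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  match(labels, AEEG_CLASSES) - 1L
}

#' Weighted Gini impurity
#'
#' Gini impurity of the class-weight-scaled proportions
#' `p_k = w_k n_k / sum_j w_j n_j`: `1 - sum p_k^2`. Up-weighting the
#' minority class makes nodes containing minority samples look less pure,
#' steering split selection toward isolating them.
#'
#' @param class_counts named non-negative counts.
#' @param weights named positive weights for the same classes.
#' @return impurity in `[0, 1)`.
#' @export
weighted_gini <- function(class_counts, weights) {
  if (is.null(names(class_counts)) || is.null(names(weights))) {
    stop("class_counts and weights must be named")
  }
  w <- weights[names(class_counts)]
  if (anyNA(w)) stop("weights missing for some classes")
  if (any(class_counts < 0) || any(w <= 0)) {
    stop("counts must be >= 0 and weights > 0")
  }
  mass <- as.numeric(w) * as.numeric(class_counts)
  if (sum(mass) == 0) stop("all class counts are zero")
  p <- mass / sum(mass)
  1 - sum(p^2)
}

#' Best weighted-Gini split at a node
#'
#' Scans all midpoint thresholds of the candidate features and returns the
#' split maximizing the weighted-Gini impurity decrease. Ties go to the
#' lowest feature index, then the lowest threshold. Returns `NULL` when no
#' split reduces impurity (pure node or all candidates constant).
#'
#' @param x numeric matrix (rows = samples at the node).
#' @param labels class labels for the rows.
#' @param candidates integer feature column indices to consider.
#' @param weights named class weights.
#' @param min_leaf minimum child size.
#' @return list `(feature, threshold, gain)` or `NULL`.
#' @export
best_split <- function(x, labels, candidates,
                       weights = c(abnormal = 1, normal = 1), min_leaf = 1L) {
  if (length(candidates) == 0L) stop("empty candidate feature set")
  x <- as.matrix(x)
  if (any(candidates < 1L) || any(candidates > ncol(x))) {
    stop("candidate index out of range")
  }
  y <- encode_labels(labels)
  w <- forest_config(class_weights = weights)$class_weights
  res <- best_split_cpp(x, y, as.numeric(w),
                        seq_len(nrow(x)) - 1L, as.integer(candidates) - 1L,
                        as.integer(min_leaf))
  if (is.na(res$feature)) return(NULL)
  res
}

#' Grow one fully grown weighted classification tree
#'
#' Recursion stops only at node purity, fewer than two samples, or when no
#' candidate split reduces the weighted Gini impurity; there is no depth cap
#' and no pruning. A fresh size-`m_try` feature subset is drawn without
#' replacement at every node. Leaves store the weighted class-probability
#' vector `p_k = w_k n_k / sum w_j n_j`.
#'
#' @param x full feature matrix.
#' @param labels labels for all rows of `x`.
#' @param rows integer row indices forming the (bootstrap) sample.
#' @param config an [forest_config()]; its seed drives the feature draws.
#' @return a tree: flat parallel arrays (feature, threshold, left, right,
#'   prob), nodes 1-based, node 1 the root, child index 0 marking a leaf.
#' @export
grow_tree <- function(x, labels, rows = seq_len(nrow(x)),
                      config = forest_config()) {
  x <- as.matrix(x)
  y <- encode_labels(labels)
  m_try <- if (is.null(config$m_try)) default_mtry(ncol(x)) else
    as.integer(config$m_try)
  if (m_try < 1L || m_try > ncol(x)) stop("m_try out of [1, p]")
  with_seed(config$seed, function() {
    grow_tree_cpp(x, y, as.numeric(config$class_weights),
                  as.integer(rows) - 1L, m_try, config$min_leaf)
  })
}

#' Fit a class-weighted random forest
#'
#' For each of `n_tree` trees: draw a uniform size-n bootstrap (with
#' replacement), then grow an unpruned tree with per-node random feature
#' selection and weighted-Gini splitting. Bootstrap membership is stored so
#' out-of-bag estimation and permutation significance need no extra data.
#' Each tree runs on its own derived seed, so the fit is reproducible.
#'
#' @param x numeric feature matrix (n x p), columns named.
#' @param labels `"normal"`/`"abnormal"` for each row; both classes required.
#' @param config an [forest_config()].
#' @return object of class `aeeg_forest`.
#' @export
rf_fit <- function(x, labels, config = forest_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples")
  if (length(labels) != n) stop("labels length must match rows of x")
  y <- encode_labels(labels)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  m_try <- if (is.null(config$m_try)) default_mtry(ncol(x)) else
    as.integer(config$m_try)
  if (m_try < 1L || m_try > ncol(x)) stop("m_try out of [1, p]")
  w <- as.numeric(config$class_weights)
  trees <- vector("list", config$n_tree)
  inbag <- vector("list", config$n_tree)
  for (b in seq_len(config$n_tree)) {
    tree_seed <- derive_seed(config$seed, b)
    with_seed(tree_seed, function() {
      rows <- sample.int(n, n, replace = TRUE)
      inbag[[b]] <<- rows
      trees[[b]] <<- grow_tree_cpp(x, y, w, rows - 1L, m_try,
                                   config$min_leaf)
    })
  }
  structure(
    list(trees = trees, inbag = inbag, config = config, m_try = m_try,
         feature_names = colnames(x), classes = AEEG_CLASSES, n_train = n),
    class = "aeeg_forest"
  )
}

#' @export
print.aeeg_forest <- function(x, ...) {
  cat(sprintf(
    "<aeeg_forest> %d trees, m_try = %d, weights %s, %d training samples\n",
    length(x$trees), x$m_try,
    paste(sprintf("%s=%g", names(x$config$class_weights),
                  x$config$class_weights), collapse = " "),
    x$n_train))
  invisible(x)
}

# Sum of per-tree contributions for the rows of x over the given trees:
# soft mode accumulates weighted leaf probability vectors, hard mode
# accumulates one-hot class votes (argmax, tie -> abnormal).
accumulate_votes <- function(forest, x, tree_idx, mode) {
  acc <- matrix(0, nrow(x), 2L)
  for (b in tree_idx) {
    pr <- predict_tree_cpp(forest$trees[[b]], x)
    if (mode == "vote") {
      cls <- ifelse(pr[, 1L] >= pr[, 2L], 1L, 2L)
      pr <- matrix(0, nrow(x), 2L)
      pr[cbind(seq_len(nrow(x)), cls)] <- 1
    }
    acc <- acc + pr
  }
  acc
}

#' Predict with a fitted forest
#'
#' Averages the per-tree weighted leaf probability vectors (or hard votes,
#' per the config's `vote_mode`) and returns the class with the larger
#' averaged probability; exact ties go to `"abnormal"`, the
#' higher-cost minority class.
#'
#' @param forest an [rf_fit()] result.
#' @param x feature vector (length p) or matrix (m x p).
#' @return list with `class` (character vector) and `prob` (m x 2 matrix,
#'   columns abnormal/normal, rows summing to 1).
#' @export
rf_predict <- function(forest, x) {
  stopifnot(inherits(forest, "aeeg_forest"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- length(forest$feature_names)
  if (p > 0L && ncol(x) != p) {
    stop("feature dimension mismatch: got ", ncol(x), ", expected ", p)
  }
  acc <- accumulate_votes(forest, x, seq_along(forest$trees),
                          forest$config$vote_mode)
  prob <- acc / length(forest$trees)
  colnames(prob) <- forest$classes
  cls <- forest$classes[ifelse(prob[, 1L] >= prob[, 2L], 1L, 2L)]
  list(class = cls, prob = prob)
}

#' Out-of-bag predictions
#'
#' For every training sample, aggregate only the trees whose bootstrap
#' excluded it. Samples in every bootstrap (possible in tiny forests) get
#' `NA` and are excluded from error rates.
#'
#' @param forest an [rf_fit()] result.
#' @param x the training feature matrix the forest was fitted on.
#' @return list with `class`, `prob`, and `n_oob_trees` per sample.
#' @export
oob_predict <- function(forest, x) {
  stopifnot(inherits(forest, "aeeg_forest"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n != forest$n_train) {
    stop("x must be the training matrix (", forest$n_train, " rows)")
  }
  acc <- matrix(0, n, 2L)
  n_oob <- integer(n)
  mode <- forest$config$vote_mode
  for (b in seq_along(forest$trees)) {
    oob <- which(tabulate(forest$inbag[[b]], nbins = n) == 0L)
    if (!length(oob)) next
    pr <- predict_tree_cpp(forest$trees[[b]], x[oob, , drop = FALSE])
    if (mode == "vote") {
      cls <- ifelse(pr[, 1L] >= pr[, 2L], 1L, 2L)
      pr <- matrix(0, length(oob), 2L)
      pr[cbind(seq_along(oob), cls)] <- 1
    }
    acc[oob, ] <- acc[oob, ] + pr
    n_oob[oob] <- n_oob[oob] + 1L
  }
  prob <- acc / pmax(n_oob, 1L)
  prob[n_oob == 0L, ] <- NA_real_
  colnames(prob) <- forest$classes
  cls <- ifelse(n_oob == 0L, NA_character_,
                forest$classes[ifelse(prob[, 1L] >= prob[, 2L], 1L, 2L)])
  list(class = cls, prob = prob, n_oob_trees = n_oob)
}

#' Out-of-bag error rate
#'
#' Fraction of training samples misclassified by their out-of-bag vote;
#' samples that are out-of-bag for no tree are excluded from the
#' denominator. About one third of the training set is out-of-bag for each
#' tree, so this is an internal, unbiased test-error estimate.
#'
#' @param forest an [rf_fit()] result.
#' @param x the training feature matrix.
#' @param labels the training labels.
#' @return error rate in `[0, 1]`, with attribute `n_evaluated`.
#' @export
oob_error <- function(forest, x, labels) {
  op <- oob_predict(forest, x)
  ok <- !is.na(op$class)
  if (!any(ok)) stop("no sample is out-of-bag for any tree")
  err <- mean(op$class[ok] != as.character(labels)[ok])
  attr(err, "n_evaluated") <- sum(ok)
  err
}

#' Permutation feature significance
#'
#' For each tree: count the correct out-of-bag class votes; then, for each
#' feature, permute that feature's values within the tree's out-of-bag
#' cases, re-classify, and count again. The per-tree significance of a
#' feature is the drop in correct-vote fraction; the raw significance score
#' is its mean over all trees. Features the forest never relies on score
#' near zero; informative features score positive.
#'
#' Per-tree class votes are hard (argmax of the weighted leaf probability,
#' tie toward abnormal) regardless of the forest-level `vote_mode`.
#'
#' @param forest an [rf_fit()] result.
#' @param x training feature matrix.
#' @param labels training labels.
#' @param seed seed for the permutation draws.
#' @return data.frame of class `aeeg_importance`: `feature`, `importance`,
#'   in feature-index order.
#' @export
permutation_importance <- function(forest, x, labels, seed = 1L) {
  stopifnot(inherits(forest, "aeeg_forest"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n != forest$n_train) {
    stop("x must be the training matrix (", forest$n_train, " rows)")
  }
  y <- encode_labels(labels)
  p <- ncol(x)
  fi_sum <- numeric(p)
  with_seed(seed, function() {
    for (b in seq_along(forest$trees)) {
      oob <- which(tabulate(forest$inbag[[b]], nbins = n) == 0L)
      if (!length(oob)) next
      xb <- x[oob, , drop = FALSE]
      pr <- predict_tree_cpp(forest$trees[[b]], xb)
      correct0 <- sum((pr[, 1L] >= pr[, 2L]) == (y[oob] == 0L))
      for (j in seq_len(p)) {
        xp <- xb
        xp[, j] <- xb[sample.int(length(oob)), j]
        prj <- predict_tree_cpp(forest$trees[[b]], xp)
        correctj <- sum((prj[, 1L] >= prj[, 2L]) == (y[oob] == 0L))
        fi_sum[j] <<- fi_sum[j] + (correct0 - correctj) / length(oob)
      }
    }
  })
  out <- data.frame(
    feature = if (is.null(forest$feature_names)) paste0("x", seq_len(p))
              else forest$feature_names,
    importance = fi_sum / length(forest$trees),
    stringsAsFactors = FALSE
  )
  class(out) <- c("aeeg_importance", "data.frame")
  out
}
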