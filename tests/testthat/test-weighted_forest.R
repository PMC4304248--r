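test_that("weighted Gini matches hand arithmetic", {
  expect_equal(weighted_gini(c(abnormal = 5, normal = 5),
                             c(abnormal = 1, normal = 1)), 0.5)
  expect_equal(weighted_gini(c(abnormal = 4, normal = 0),
                             c(abnormal = 3, normal = 1)), 0)
  # counts (abnormal 1, normal 2), weights (3, 1): p = (0.6, 0.4)
  expect_equal(weighted_gini(c(abnormal = 1, normal = 2),
                             c(abnormal = 3, normal = 1)), 0.48)
  expect_error(weighted_gini(c(abnormal = 0, normal = 0),
                             c(abnormal = 1, normal = 1)), "all class counts")
})

test_that("best_split equals the exhaustive oracle on small fixtures", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(4:8, 1)
    p <- sample(2:4, 1)
    x <- matrix(round(rnorm(n * p), 2), n, p)
    y <- sample(c("abnormal", "normal"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("abnormal", "normal"), y)[1]
    w <- if (s %% 2 == 0) c(abnormal = 3, normal = 1) else
      c(abnormal = 1, normal = 1)
    got <- best_split(x, y, seq_len(p), weights = w)
    want <- oracle_best_split(x, match(y, c("abnormal", "normal")) - 1L,
                              unname(w))
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-10)
    }
  }
})

test_that("a perfectly separating candidate is chosen with gain = parent", {
  x <- cbind(c(1, 2, 3, 10, 11, 12), c(5, 5, 5, 5, 5, 5))
  y <- rep(c("abnormal", "normal"), each = 3)
  s <- best_split(x, y, 1:2)
  expect_equal(s$feature, 1L)
  expect_equal(s$threshold, 6.5)
  expect_equal(s$gain, 0.5)  # unweighted parent impurity of a 3/3 node
  expect_null(best_split(x, y, 2L))  # constant candidate -> no split
  expect_error(best_split(x, y, integer(0)), "empty candidate")
})

test_that("trees grow to purity and fit separable training data", {
  toy <- toy_matrix(n_per_class = 15, p = 3, shift = 4, seed = 3)
  tree <- grow_tree(toy$x, toy$labels, config = forest_config(seed = 1))
  expect_true(any(is.na(tree$feature)))  # has leaves
  expect_equal(rowSums(tree$prob), rep(1, nrow(tree$prob)))
  # pure bootstrap -> single leaf
  pure <- grow_tree(toy$x, rep("normal", nrow(toy$x)),
                    config = forest_config(seed = 1))
  expect_length(pure$feature, 1L)
  expect_equal(pure$prob[1, ], c(0, 1))
  # determinism
  t2 <- grow_tree(toy$x, toy$labels, config = forest_config(seed = 1))
  expect_identical(tree, t2)
})

test_that("forest fit is deterministic and validates inputs", {
  toy <- toy_matrix(seed = 7)
  cfg <- forest_config(n_tree = 25, seed = 11)
  f1 <- rf_fit(toy$x, toy$labels, cfg)
  f2 <- rf_fit(toy$x, toy$labels, cfg)
  grid <- matrix(rnorm(50 * 5), 50)
  expect_identical(rf_predict(f1, grid), rf_predict(f2, grid))
  expect_length(rf_fit(toy$x, toy$labels,
                       forest_config(n_tree = 1, seed = 1))$trees, 1L)
  expect_error(rf_fit(toy$x, rep("normal", nrow(toy$x)), cfg),
               "both classes")
  expect_error(rf_predict(f1, rnorm(4)), "dimension mismatch")
  expect_error(forest_config(class_weights = c(abnormal = -1, normal = 1)),
               "> 0")
})

test_that("training accuracy is perfect on separable data (fully grown)", {
  toy <- toy_matrix(n_per_class = 20, p = 4, shift = 5, seed = 13)
  fit <- rf_fit(toy$x, toy$labels, forest_config(n_tree = 30, seed = 2))
  pred <- rf_predict(fit, toy$x)
  expect_equal(pred$class, toy$labels)
  expect_equal(rowSums(pred$prob), rep(1, nrow(toy$x)))
})

test_that("leaf probabilities carry the class weights into the vote", {
  # one constant feature: the tree cannot split, so the root is a leaf
  # holding counts (abnormal 1, normal 2); weights 3:1 give p = (0.6, 0.4)
  x <- matrix(1, 3, 1)
  tree <- grow_tree(x, c("abnormal", "normal", "normal"), rows = 1:3,
                    config = forest_config(
                      seed = 1, class_weights = c(abnormal = 3, normal = 1)))
  expect_equal(tree$prob[1, ], c(0.6, 0.4))
  # the weighted leaf votes abnormal although normal has the count majority
  expect_gt(tree$prob[1, 1], tree$prob[1, 2])
})

test_that("exact probability ties resolve toward abnormal", {
  x <- matrix(1, 2, 1)
  tree <- grow_tree(x, c("abnormal", "normal"), rows = 1:2,
                    config = forest_config(seed = 1,
                      class_weights = c(abnormal = 1, normal = 1)))
  expect_equal(tree$prob[1, ], c(0.5, 0.5))
  fit <- rf_fit(rbind(c(1), c(1)), c("abnormal", "normal"),
                forest_config(n_tree = 5, seed = 3,
                              class_weights = c(abnormal = 1, normal = 1)))
  expect_equal(rf_predict(fit, matrix(1))$class, "abnormal")
})

test_that("unit class weights reproduce unweighted behaviour", {
  toy <- toy_matrix(n_per_class = 25, p = 5, shift = 1.5, seed = 21)
  # (a) leaf probabilities equal plain count proportions
  x1 <- matrix(1, 5, 1)
  y1 <- c("abnormal", "abnormal", "normal", "normal", "normal")
  tree <- grow_tree(x1, y1, rows = 1:5,
                    config = forest_config(seed = 1,
                      class_weights = c(abnormal = 1, normal = 1)))
  expect_equal(tree$prob[1, ], c(0.4, 0.6))
  # (b) scale invariance: (1,1) and (7,7) give identical forests
  fa <- rf_fit(toy$x, toy$labels,
               forest_config(n_tree = 40, seed = 9,
                             class_weights = c(abnormal = 1, normal = 1)))
  fb <- rf_fit(toy$x, toy$labels,
               forest_config(n_tree = 40, seed = 9,
                             class_weights = c(abnormal = 7, normal = 7)))
  expect_identical(fa$trees, fb$trees)
  grid <- matrix(rnorm(40 * 5), 40)
  expect_identical(rf_predict(fa, grid), rf_predict(fb, grid))
  # (c) split selection at unit weights equals the unweighted oracle
  set.seed(33)
  for (i in 1:10) {
    x <- matrix(rnorm(24), 6, 4)
    y <- c("abnormal", "normal")[c(1, 1, 1, 2, 2, 2)]
    got <- best_split(x, y, 1:4, weights = c(abnormal = 1, normal = 1))
    want <- oracle_best_split(x, c(0, 0, 0, 1, 1, 1), c(1, 1))
    expect_equal(got$feature, want$feature)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("hard-vote mode agrees with soft mode away from ties", {
  toy <- toy_matrix(n_per_class = 20, p = 4, shift = 4, seed = 5)
  soft <- rf_fit(toy$x, toy$labels,
                 forest_config(n_tree = 30, seed = 4, vote_mode = "prob"))
  hard <- rf_fit(toy$x, toy$labels,
                 forest_config(n_tree = 30, seed = 4, vote_mode = "vote"))
  expect_identical(soft$trees, hard$trees)
  expect_identical(rf_predict(soft, toy$x)$class,
                   rf_predict(hard, toy$x)$class)
})

test_that("OOB error is zero for a forest of perfect trees", {
  # duplicated, widely separated rows: every tree classifies perfectly
  base <- rbind(matrix(0, 10, 3), matrix(10, 10, 3))
  labels <- rep(c("abnormal", "normal"), each = 10)
  fit <- rf_fit(base, labels, forest_config(n_tree = 50, seed = 6))
  err <- oob_error(fit, base, labels)
  expect_equal(as.numeric(err), 0)
  expect_gt(attr(err, "n_evaluated"), 0)
})

test_that("single-tree OOB uses only that tree's out-of-bag samples", {
  toy <- toy_matrix(n_per_class = 10, p = 3, shift = 3, seed = 8)
  fit <- rf_fit(toy$x, toy$labels, forest_config(n_tree = 1, seed = 2))
  op <- oob_predict(fit, toy$x)
  inbag <- unique(fit$inbag[[1]])
  expect_true(all(is.na(op$class[inbag])))
  expect_true(all(!is.na(op$class[-inbag])))
  err <- oob_error(fit, toy$x, toy$labels)
  expect_equal(attr(err, "n_evaluated"), nrow(toy$x) - length(inbag))
})

test_that("JSON round trip reproduces predictions and OOB exactly", {
  toy <- toy_matrix(n_per_class = 12, p = 4, shift = 2, seed = 10)
  fit <- rf_fit(toy$x, toy$labels, forest_config(
    n_tree = 15, seed = 3, class_weights = c(abnormal = 3, normal = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  rf_save(fit, path)
  back <- rf_load(path)
  grid <- matrix(rnorm(30 * 4), 30)
  expect_identical(rf_predict(fit, grid), rf_predict(back, grid))
  expect_equal(as.numeric(oob_error(fit, toy$x, toy$labels)),
               as.numeric(oob_error(back, toy$x, toy$labels)))
  expect_identical(back$feature_names, fit$feature_names)
})

test_that("permutation importance matches a hand-unrolled computation", {
  toy <- toy_matrix(n_per_class = 5, p = 3, shift = 3, seed = 14)
  fit <- rf_fit(toy$x, toy$labels, forest_config(n_tree = 2, seed = 7))
  seed <- 19
  imp <- permutation_importance(fit, toy$x, toy$labels, seed = seed)
  # hand-unrolled Eq-by-Eq recomputation using the same permutation stream
  y01 <- match(toy$labels, c("abnormal", "normal")) - 1L
  fi <- numeric(3)
  set.seed(seed)
  for (b in 1:2) {
    oob <- setdiff(seq_len(nrow(toy$x)), fit$inbag[[b]])
    xb <- toy$x[oob, , drop = FALSE]
    pred_cls <- function(m) {
      pr <- aeegrf:::predict_tree_cpp(fit$trees[[b]], m)
      ifelse(pr[, 1] >= pr[, 2], 0L, 1L)
    }
    c0 <- sum(pred_cls(xb) == y01[oob])
    for (j in 1:3) {
      xp <- xb
      xp[, j] <- xb[sample.int(length(oob)), j]
      fi[j] <- fi[j] + (c0 - sum(pred_cls(xp) == y01[oob])) / length(oob)
    }
  }
  expect_equal(imp$importance, fi / 2, tolerance = 1e-12)
})

test_that("a perfectly predictive feature ranks first in importance", {
  set.seed(41)
  n <- 60
  labels <- rep(c("abnormal", "normal"), each = n / 2)
  x <- cbind(sep = ifelse(labels == "abnormal", 0, 1) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 4), n, 4))
  colnames(x) <- paste0("f", 1:5)
  fit <- rf_fit(x, labels, forest_config(n_tree = 40, seed = 15))
  imp <- permutation_importance(fit, x, labels, seed = 1)
  expect_equal(which.max(imp$importance), 1L)
  expect_gt(imp$importance[1], 0.2)
})

test_that("unit-weight OOB error agrees with the reference implementation", {
  skip_if_not_installed("randomForest")
  set.seed(1)
  n <- 40; p <- 5
  x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, 1), n))
  colnames(x) <- paste0("f", 1:p)
  labels <- rep(c("abnormal", "normal"), each = n)
  ours <- vapply(1:5, function(s) {
    as.numeric(oob_error(rf_fit(x, labels, forest_config(
      n_tree = 300, seed = s,
      class_weights = c(abnormal = 1, normal = 1))), x, labels))
  }, 0.0)
  ref <- vapply(1:5, function(s) {
    set.seed(s)
    fit <- randomForest::randomForest(x, factor(labels), ntree = 300)
    mean(stats::predict(fit) != labels)
  }, 0.0)
  expect_lt(abs(mean(ours) - mean(ref)), 0.05)
})
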