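test_that("stratified group k-fold partitions subjects with balanced classes", {
  labels <- setNames(rep(c(TRUE, FALSE), c(12, 18)), paste0("s", 1:30))
  f <- stratified_group_kfold(labels, 5, seed = 3)
  expect_setequal(names(f), names(labels))
  expect_true(all(f %in% 1:5))
  expect_equal(as.vector(table(f)), rep(6, 5))
  # positives spread evenly (12 positives over 5 folds -> 2 or 3 each)
  pos_per_fold <- table(f[labels])
  expect_true(all(pos_per_fold %in% 2:3))
  expect_identical(f, stratified_group_kfold(labels, 5, seed = 3))
  expect_error(stratified_group_kfold(labels, 1), "folds")
})

make_separable <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(x1 = rnorm(n) + ifelse(y, 3, 0), x2 = rnorm(n))
  list(X = X, y = y)
}

test_that("the balanced random forest separates and is deterministic", {
  d <- make_separable()
  fit <- balanced_rf_fit(d$X, d$y, seed = 5)
  calls <- predict(fit, d$X) >= 0.5
  bal_acc <- (mean(calls[d$y]) + mean(!calls[!d$y])) / 2
  expect_gte(bal_acc, 0.95)
  fit2 <- balanced_rf_fit(d$X, d$y, seed = 5)
  expect_identical(predict(fit, d$X), predict(fit2, d$X))
  expect_error(balanced_rf_fit(d$X, rep(TRUE, 100)), "both classes")
})

test_that("per-tree class balancing centres null predictions near 0.5", {
  set.seed(42)
  n <- 200
  y <- rep(c(TRUE, FALSE), c(20, 180))          # 1:9 imbalance
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))  # labels independent
  fit <- balanced_rf_fit(X, y, seed = 11)
  set.seed(43)
  Xnew <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, colnames(X)))
  m <- mean(predict(fit, Xnew))
  expect_gt(m, 0.35)   # an unbalanced forest would sit near 0.1
  expect_lt(m, 0.65)
})

planted_data <- function(n = 60, p = 21, informative = 7, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, informative] <- X[, informative] + ifelse(y, 2.5, 0)
  list(X = X, y = y, groups = paste0("g", seq_len(n)))
}

test_that("forward selection recovers a planted informative feature", {
  hits <- 0
  for (seed in 1:10) {
    d <- planted_data(seed = seed)
    sel <- sequential_select(d$X, d$y, d$groups, n_folds = 5, max_k = 2,
                             seed = seed, num_trees = 40)
    if (length(sel) >= 1 && sel[1] == 7) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("forward selection respects max_k and halts on pure noise", {
  d <- planted_data(seed = 3)
  sel1 <- sequential_select(d$X, d$y, d$groups, n_folds = 5, max_k = 1,
                            seed = 1, num_trees = 40)
  expect_length(sel1, 1)
  set.seed(99)
  Xn <- matrix(rnorm(60 * 15), 60, 15, dimnames = list(NULL, paste0("n", 1:15)))
  yn <- rep(c(TRUE, FALSE), length.out = 60)
  seln <- sequential_select(Xn, yn, paste0("g", 1:60), n_folds = 5,
                            max_k = 10, seed = 2, num_trees = 40)
  expect_lt(length(seln), 6)
  expect_warning(
    sequential_select(d$X, d$y, d$groups, n_folds = 5, max_k = 100,
                      seed = 1, num_trees = 10),
    "clipped")
})

test_that("grid search is exhaustive, deterministic, and prefers sane models", {
  d <- make_separable(seed = 2)
  single <- data.frame(num_trees = 77L, max_depth = 3L, mtry = 1L)
  got <- grid_search(d$X, d$y, paste0("g", 1:100), selected = 1:2,
                     grid = single, n_folds = 5, seed = 4)
  expect_equal(got[c("num_trees", "max_depth", "mtry")],
               list(num_trees = 77L, max_depth = 3L, mtry = 1L))

  grid <- data.frame(num_trees = c(1L, 200L), max_depth = c(1L, 0L),
                     mtry = c(1L, NA))
  g1 <- grid_search(d$X, d$y, paste0("g", 1:100), 1:2, grid,
                    n_folds = 5, seed = 4)
  g2 <- grid_search(d$X, d$y, paste0("g", 1:100), 1:2, grid,
                    n_folds = 5, seed = 4)
  expect_identical(g1, g2)
  expect_equal(g1$num_trees, 200L)
  expect_error(grid_search(d$X, d$y, paste0("g", 1:100), 1:2,
                           grid[0, ], 5, 1), "empty")
})

test_that("threshold calibration matches the enumeration contract", {
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.95)
  labels <- c(rep(FALSE, 5), TRUE)
  expect_equal(calibrate_threshold(probs, labels, 0.8), 0.9)
  expect_equal(calibrate_threshold(probs, labels, 0), 0.1)
  thr1 <- calibrate_threshold(probs, labels, 0.999)
  expect_gt(thr1, 0.9)
  expect_error(calibrate_threshold(c(0.2, 0.4), c(TRUE, TRUE), 0.8),
               "negatives")

  # contract: the returned threshold always attains the target on its
  # own calibration set
  set.seed(5)
  for (i in 1:50) {
    pr <- runif(40)
    lb <- runif(40) < 0.4
    if (!any(!lb)) lb[1] <- FALSE
    tgt <- runif(1)
    t <- calibrate_threshold(pr, lb, tgt)
    expect_gte(mean(pr[!lb] < t), tgt)
  }
})

test_that("patient aggregation is the any-territory rule", {
  expect_true(aggregate_patient(c(FALSE, FALSE, TRUE)))
  expect_false(aggregate_patient(c(FALSE, FALSE, FALSE)))
  expect_true(aggregate_patient(c(TRUE, TRUE, TRUE)))
  expect_error(aggregate_patient(c(TRUE, FALSE)), "exactly 3")
  expect_error(aggregate_patient(c(TRUE, NA, FALSE)), "exactly 3")
})

test_that("sensitivity and specificity follow their definitions", {
  truth <- rep(c(TRUE, FALSE), c(10, 10))
  calls <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 8))
  expect_equal(sensitivity_specificity(calls, truth),
               c(sensitivity = 0.5, specificity = 0.8))
  expect_equal(sensitivity_specificity(truth, truth),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(!truth, truth),
               c(sensitivity = 0, specificity = 0))
  expect_warning(sensitivity_specificity(calls, rep(TRUE, 20)), "absent")
})

test_that("the McNemar test matches its closed forms", {
  # b = 2 correct by A only, c = 8 correct by B only
  truth <- rep(TRUE, 12)
  a <- c(rep(TRUE, 2), rep(FALSE, 8), TRUE, TRUE)
  b <- c(rep(FALSE, 2), rep(TRUE, 8), TRUE, TRUE)
  r <- mcnemar_test(a, b, truth, exact = "never")
  expect_equal(r$statistic, 3.6)
  expect_equal(r$b, 2)
  expect_equal(r$c, 8)
  expect_equal(r$p_value, pchisq(3.6, 1, lower.tail = FALSE))

  r2 <- mcnemar_test(c(rep(TRUE, 5), rep(FALSE, 5)),
                     c(rep(FALSE, 5), rep(TRUE, 5)), rep(TRUE, 10))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  r3 <- mcnemar_test(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10),
                     exact = "always")
  expect_equal(r3$b, 10)
  expect_equal(r3$c, 0)
  expect_equal(r3$p_value, 2 * 0.5^10)

  r4 <- mcnemar_test(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4))
  expect_true(is.nan(r4$statistic))
  expect_equal(r4$p_value, 1)
})

test_that("feature ranking counts per-fold base-name indicators", {
  fake <- structure(list(selections = list(
    c("basal|fo_median|bin2", "mid|fo_median|bin7"),
    c("apical|szm_large_area_emphasis|bin1", "basal|fo_median|bin1"),
    character(0))), class = "cv_result")
  rk <- feature_ranking(fake)
  expect_equal(rk$frequency[rk$feature == "fo_median"], 2L)
  expect_equal(rk$frequency[rk$feature == "szm_large_area_emphasis"], 1L)
  expect_equal(sum(rk$frequency), 3L)
  expect_equal(rk$feature[1], "fo_median")
})

test_that("nested CV partitions subjects and audits fold isolation", {
  deltas <- shared_small_deltas()
  cc <- cv_config(n_outer_folds = 3, n_inner_folds = 4,
                  max_selected_features = 2, sfs_num_trees = 25,
                  screen_size = 12, seed = 8,
                  grid = data.frame(num_trees = 50L, max_depth = 0L,
                                    mtry = NA_integer_))
  cv <- nested_cv(deltas, cc)
  subj <- unique(deltas$meta$subject)
  # every subject tested exactly once across outer folds
  expect_setequal(cv$patient$subject, subj)
  expect_equal(nrow(cv$patient), length(subj))
  expect_equal(nrow(cv$territory), 3 * length(subj))
  for (a in cv$audit) {
    expect_length(intersect(a$outer_train, a$outer_test), 0)
    for (i in seq_along(a$inner_train)) {
      expect_length(intersect(a$inner_train[[i]], a$inner_val[[i]]), 0)
      expect_true(all(c(a$inner_train[[i]], a$inner_val[[i]]) %in%
                        a$outer_train))
    }
  }
  # determinism under the same config seed
  cv2 <- nested_cv(deltas, cc)
  expect_identical(cv$territory$prob, cv2$territory$prob)
  expect_identical(cv$sensitivity, cv2$sensitivity)
})
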