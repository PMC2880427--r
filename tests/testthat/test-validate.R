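test_that("confusion metrics reproduce the worked example and edge cases", {
  m <- confusion_metrics(list(TP = 54, FN = 13, TN = 47, FP = 13))
  expect_equal(round(unname(m), 1), c(79.5, 80.6, 78.3))
  all_right <- confusion_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(all_right), c(100, 100, 100))
  hand <- confusion_metrics(list(TP = 0, FN = 1, TN = 1, FP = 0))
  expect_equal(unname(hand), c(50, 0, 100))
  expect_error(confusion_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "empty")
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- c(rnorm(n1), rnorm(n0))
    if (seed %% 2 == 0) s <- round(s)  # force ties half the time
    truth <- rep(c(TRUE, FALSE), c(n1, n0))
    pairs <- outer(s[truth], s[!truth],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, truth)$auc, mean(pairs),
                 info = paste("seed", seed))
  }
})

test_that("ROC conventions: separation, ties, complement identity", {
  s <- c(3, 2, 1, -1, -2)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- roc_auc(s, truth)
  expect_equal(r$auc, 1)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  set.seed(3)
  s2 <- rnorm(20); t2 <- rep(c(TRUE, FALSE), 10)
  expect_equal(roc_auc(s2, t2)$auc + roc_auc(-s2, t2)$auc, 1)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- rnorm(40); truth <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_auc(s, truth)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, s, quiet = TRUE))))
})

test_that("double cross-validation output contract holds", {
  xy <- make_xy(16, 30, n_signal = 5, effect = 2, seed = 91)
  cv <- double_cv(xy$X, xy$y, A_max = 4, fold_details = TRUE)
  expect_equal(nrow(cv$samples), 16L)
  expect_true(all(is.finite(cv$samples$score)))
  expect_equal(cv$TP + cv$FN, sum(xy$y > 0))
  expect_equal(cv$TN + cv$FP, sum(xy$y < 0))
  expect_equal(cv$samples$predicted_class, classify(cv$samples$score))
  expect_length(cv$selected, 16L)
  expect_error(double_cv(xy$X[1:5, ], xy$y[1:5]), "at least 6")
})

test_that("held-out samples cannot influence their fold's selection", {
  # spy test: perturbing the held-out sample's expression must not change
  # which probes its fold selects
  xy <- make_xy(14, 25, n_signal = 4, effect = 2, seed = 101)
  m <- 5
  fold <- function(X) {
    sr <- select_and_refit(X, xy$y, A_max = 4, keep_idx = setdiff(1:14, m))
    sr$selected_probe_ids
  }
  sel1 <- fold(xy$X)
  Xp <- xy$X
  Xp[m, ] <- Xp[m, ] + 100  # gross perturbation of the held-out sample
  expect_identical(fold(Xp), sel1)
})

test_that("permutation test is seeded, bounded and uses the add-one rule", {
  xy <- make_xy(14, 20, n_signal = 4, effect = 2, seed = 111)
  p1 <- permutation_test(xy$X, xy$y, k = 5, seed = 3, A_max = 4)
  p2 <- permutation_test(xy$X, xy$y, k = 5, seed = 3, A_max = 4)
  expect_identical(p1$accuracy, p2$accuracy)
  expect_identical(p1$auc, p2$auc)
  expect_true(all(p1$accuracy >= 0 & p1$accuracy <= 1, na.rm = TRUE))
  expect_gt(p1$p_accuracy, 0)   # add-one convention: never exactly 0
  expect_gt(p1$p_auc, 0)
  cv <- double_cv(xy$X, xy$y, A_max = 4)
  expect_equal(p1$observed_accuracy,
               unname(confusion_metrics(cv)["accuracy"]) / 100)
})

test_that("learning curve: full fraction equals the full double-CV AUC", {
  xy <- make_xy(14, 20, n_signal = 5, effect = 2, seed = 121)
  lc <- learning_curve(xy$X, xy$y, fractions = 1, reps = 1, seed = 1,
                       A_max = 4)
  cv <- double_cv(xy$X, xy$y, A_max = 4)
  expect_equal(lc$mean_auc,
               roc_auc(cv$samples$score, cv$samples$true_class)$auc)
  expect_error(learning_curve(xy$X, xy$y, fractions = 0.2, reps = 1,
                              A_max = 4), "fewer than 3")
  expect_error(learning_curve(xy$X, xy$y, fractions = 1.2, reps = 1),
               "\\(0, 1\\]")
})

test_that("misclassification association reproduces the Fisher examples", {
  # DCIS x false-negative table among 67 cases: [[4,6],[9,48]] -> p ~ 0.09
  samples <- data.frame(
    array_id = sprintf("a%03d", 1:127),
    true_class = rep(c("case", "control_healthy"), c(67, 60)),
    score = 0, predicted_class = NA_character_,
    n_selected_probes = NA_integer_, a_opt = NA_integer_, failed = FALSE,
    stringsAsFactors = FALSE)
  # 13 false negatives among cases: 4 of 10 DCIS, 9 of 57 others
  dcis <- c(rep(TRUE, 10), rep(FALSE, 57), rep(FALSE, 60))
  mis_case <- c(rep(TRUE, 4), rep(FALSE, 6),      # DCIS
                rep(TRUE, 9), rep(FALSE, 48))     # non-DCIS
  samples$predicted_class[1:67] <- ifelse(mis_case, "control_healthy", "case")
  samples$predicted_class[68:127] <- "control_healthy"
  cv <- structure(list(samples = samples, TP = 54, FN = 13, TN = 60, FP = 0,
                       n = 127), class = "CVResult")
  names(dcis) <- samples$array_id
  r <- misclass_association(cv, dcis, among = "false_negatives")
  expect_equal(round(r$p, 2), 0.09)
  expect_equal(as.vector(r$table), c(4, 9, 6, 48))
  # independent 2x2 -> p = 1
  flat <- stats::fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value
  expect_equal(flat, 1)
  expect_error(
    misclass_association(cv, setNames(rep(TRUE, 127), samples$array_id),
                         among = "false_negatives"),
    "single level")
})

test_that("fisher p matches exhaustive hypergeometric enumeration", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d <- sample(0:6, 1)
    tab <- matrix(c(a, b, c_, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- a + b; n_ <- c_ + d; k <- a + c_
    probs <- dhyper(max(0, k - n_):min(k, m), m, n_, k)
    p_brute <- sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
    expect_equal(stats::fisher.test(tab)$p.value, p_brute,
                 tolerance = 1e-8, info = paste(a, b, c_, d))
  }
})
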