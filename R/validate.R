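#' Double (nested) leave-one-out cross-validation
#'
#' The outer loop holds out one sample at a time; the entire training
#' procedure — inner leave-one-out component choice, jackknife probe
#' selection, refit, second component choice — is rerun from scratch on
#' the remaining samples, and the held-out sample is scored by the
#' fold's refitted model. The held-out sample therefore never
#' influences which probes its fold selects or how many components it
#' uses, so the resulting error estimate is free of selection bias.
#'
#' @param X samples-by-probes matrix (complete, preprocessed).
#' @param y -1/+1 response (see [response_vector()]).
#' @param alpha jackknife selection threshold (default 0.05).
#' @param A_max maximum component count for both inner loops.
#' @param K0 optional precomputed `tcrossprod(X)`; computed once and
#'   reused across folds (and across permutations by
#'   [permutation_test()]).
#' @param keep_idx optional integer subset of samples (used internally
#'   by [learning_curve()]).
#' @param progress print a dot per fold.
#' @param fold_details keep each fold's selected probe ids (list element
#'   `selected`, one character vector per fold).
#' @return A `CVResult`: list with `samples` (data.frame: `array_id`,
#'   `true_class`, `score`, `predicted_class`, `n_selected_probes`,
#'   `a_opt`, `failed`), confusion counts `TP`, `FN`, `TN`, `FP`, and
#'   `n`.
#' @export
double_cv <- function(X, y, alpha = 0.05, A_max = NULL, K0 = NULL,
                      keep_idx = NULL, progress = FALSE,
                      fold_details = FALSE) {
  X <- as.matrix(X)
  if (is.null(keep_idx)) keep_idx <- seq_len(nrow(X))
  n <- length(keep_idx)
  yk <- y[keep_idx]
  if (n < 6 || min(table(yk)) < 3)
    stop("need at least 6 samples with both classes >= 3")
  if (is.null(K0)) K0 <- tcrossprod(X)
  ids <- rownames(X)[keep_idx]
  if (is.null(ids)) ids <- as.character(keep_idx)
  rec <- data.frame(array_id = ids,
                    true_class = ifelse(yk > 0, "case", "control_healthy"),
                    score = NA_real_, predicted_class = NA_character_,
                    n_selected_probes = NA_integer_, a_opt = NA_integer_,
                    failed = FALSE, stringsAsFactors = FALSE)
  selected <- if (fold_details) vector("list", n)
  for (m in seq_len(n)) {
    fold <- tryCatch(
      select_and_refit(X, y, alpha = alpha, A_max = A_max, K0 = K0,
                       keep_idx = keep_idx[-m]),
      error = function(e) e)
    if (inherits(fold, "error")) {
      rec$failed[m] <- TRUE
      next
    }
    sc <- predict_score(fold$model,
                        X[keep_idx[m], fold$selected_probe_ids,
                          drop = FALSE])
    rec$score[m] <- sc
    rec$predicted_class[m] <- classify(sc)
    rec$n_selected_probes[m] <- length(fold$selected_probe_ids)
    rec$a_opt[m] <- fold$model$A
    if (fold_details) selected[[m]] <- fold$selected_probe_ids
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  ok <- !rec$failed
  TP <- sum(ok & rec$true_class == "case" & rec$predicted_class == "case")
  FN <- sum(ok & rec$true_class == "case" & rec$predicted_class != "case")
  TN <- sum(ok & rec$true_class == "control_healthy" &
              rec$predicted_class == "control_healthy")
  FP <- sum(ok & rec$true_class == "control_healthy" &
              rec$predicted_class != "control_healthy")
  structure(list(samples = rec, TP = TP, FN = FN, TN = TN, FP = FP,
                 n = sum(ok), n_failed = sum(!ok),
                 selected = selected),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  m <- confusion_metrics(x)
  cat(sprintf("CVResult: n = %d (TP %d, FN %d, TN %d, FP %d)\n",
              x$n, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' Classification metrics from a cross-validation result
#'
#' @param cv a `CVResult`, or a list/vector with elements `TP`, `FN`,
#'   `TN`, `FP`.
#' @return Named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`, as percentages.
#' @export
confusion_metrics <- function(cv) {
  TP <- cv$TP; FN <- cv$FN; TN <- cv$TN; FP <- cv$FP
  n <- TP + FN + TN + FP
  if (n == 0) stop("empty cross-validation result")
  if (TP + FN == 0 || TN + FP == 0) stop("a class has zero samples")
  c(accuracy = 100 * (TP + TN) / n,
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP))
}

#' ROC curve and area under the curve
#'
#' AUC is computed by the rank (Mann-Whitney) statistic with half
#' credit for ties, which equals the trapezoidal area under the ROC
#' curve traced over all score thresholds. Curve points are
#' (1 - specificity, sensitivity) at every distinct score.
#'
#' @param scores numeric raw prediction scores (higher = more case-like).
#' @param truth true classes: logical (case = `TRUE`), -1/+1 numeric, or
#'   character "case"/"control_healthy".
#' @return List `auc` and `curve` (data.frame `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, truth) {
  case <- truth_to_logical(truth)
  if (length(scores) != length(case)) stop("length mismatch")
  keep <- is.finite(scores)
  scores <- scores[keep]; case <- case[keep]
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)          # midranks: ties get half credit
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(scores[case] >= s), 0)
  fpr <- vapply(thr, function(s) mean(scores[!case] >= s), 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  list(auc = auc, curve = curve)
}

truth_to_logical <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) return(truth > 0)
  truth == "case"
}

#' Permutation test of the double cross-validation
#'
#' Permutes the -1/+1 response against the fixed (already preprocessed)
#' expression matrix `k` times; each permutation reruns the full double
#' cross-validation, so selection and component choice are repeated
#' under the null. Reports the permuted accuracy/AUC distributions,
#' their maxima, and add-one empirical p-values
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (k + 1)} for the observed
#' statistics.
#'
#' @inheritParams double_cv
#' @param k number of permutations.
#' @param seed RNG seed for the permutation sequence.
#' @param cv_observed optional precomputed observed `CVResult` (avoids
#'   refitting; computed here when `NULL`).
#' @return A `PermutationResult`: list with `k`, `seed`, `accuracy`,
#'   `auc` (length-k vectors, failed permutations `NA`), `observed_*`,
#'   `max_*`, `p_accuracy`, `p_auc`, `n_failed`.
#' @export
permutation_test <- function(X, y, k, seed = 1L, alpha = 0.05,
                             A_max = NULL, cv_observed = NULL,
                             progress = FALSE) {
  if (k < 1) stop("k must be >= 1")
  X <- as.matrix(X)
  K0 <- tcrossprod(X)
  if (is.null(cv_observed))
    cv_observed <- double_cv(X, y, alpha = alpha, A_max = A_max, K0 = K0)
  obs_acc <- unname(confusion_metrics(cv_observed)["accuracy"]) / 100
  obs_auc <- roc_auc(cv_observed$samples$score,
                     cv_observed$samples$true_class)$auc
  set.seed(seed)
  acc <- rep(NA_real_, k); auc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    yp <- sample(y)
    cvp <- tryCatch(
      double_cv(X, yp, alpha = alpha, A_max = A_max, K0 = K0),
      error = function(e) NULL)
    if (is.null(cvp)) next
    acc[i] <- (cvp$TP + cvp$TN) / cvp$n
    auc[i] <- roc_auc(cvp$samples$score, cvp$samples$true_class)$auc
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  ok <- !is.na(acc)
  structure(list(
    k = k, seed = seed, accuracy = acc, auc = auc,
    observed_accuracy = obs_acc, observed_auc = obs_auc,
    max_accuracy = max(acc[ok]), max_auc = max(auc[ok]),
    p_accuracy = (1 + sum(acc[ok] >= obs_acc)) / (sum(ok) + 1),
    p_auc = (1 + sum(auc[ok] >= obs_auc)) / (sum(ok) + 1),
    n_failed = sum(!ok)), class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(paste0("PermutationResult: k = %d, max accuracy %.1f%%, ",
                     "max AUC %.2f\n  observed accuracy %.1f%% (p = %.4g), ",
                     "observed AUC %.2f (p = %.4g)\n"),
              x$k, 100 * x$max_accuracy, x$max_auc,
              100 * x$observed_accuracy, x$p_accuracy, x$observed_auc,
              x$p_auc))
  invisible(x)
}

#' Learning curve over balanced subsamples
#'
#' For each sample fraction, draws `reps` class-balanced random subsets,
#' reruns the double cross-validation on each, and summarises the AUC.
#'
#' @inheritParams double_cv
#' @param fractions numeric vector in (0, 1].
#' @param reps repetitions per fraction.
#' @param seed RNG seed for the subsampling.
#' @return A `LearningCurveResult`: data.frame with `fraction`,
#'   `mean_auc`, `sd_auc`, `reps`, plus attribute `auc` (the full
#'   fraction x rep matrix).
#' @export
learning_curve <- function(X, y, fractions = c(0.4, 0.6, 0.8, 1),
                           reps = 3, seed = 1L, alpha = 0.05,
                           A_max = NULL) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  X <- as.matrix(X)
  K0 <- tcrossprod(X)
  idx_case <- which(y > 0); idx_ctrl <- which(y <= 0)
  set.seed(seed)
  aucs <- matrix(NA_real_, length(fractions), reps)
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n1 <- round(f * length(idx_case)); n0 <- round(f * length(idx_ctrl))
    if (n1 < 3 || n0 < 3)
      stop("fraction ", f, " leaves fewer than 3 samples in a class")
    for (r in seq_len(reps)) {
      keep <- c(sample(idx_case, n1), sample(idx_ctrl, n0))
      cv <- double_cv(X, y, alpha = alpha, A_max = A_max, K0 = K0,
                      keep_idx = sort(keep))
      aucs[fi, r] <- roc_auc(cv$samples$score, cv$samples$true_class)$auc
    }
  }
  res <- data.frame(fraction = fractions,
                    mean_auc = rowMeans(aucs),
                    sd_auc = apply(aucs, 1, stats::sd),
                    reps = reps)
  attr(res, "auc") <- aucs
  attr(res, "seed") <- seed
  class(res) <- c("LearningCurveResult", class(res))
  res
}

#' Association between misclassification and a covariate
#'
#' Among the relevant true class (cases for false negatives, healthy
#' controls for false positives), cross-tabulates a binary covariate
#' against misclassification and computes the two-sided Fisher exact
#' (hypergeometric) p-value.
#'
#' @param cv a `CVResult`.
#' @param feature named logical/0-1 vector keyed by array id (must cover
#'   the relevant class), or an unnamed vector aligned with the rows of
#'   `cv$samples`.
#' @param among `"false_negatives"` (covariate among true cases) or
#'   `"false_positives"` (among true healthy).
#' @return List `table` (2x2: covariate x misclassified) and `p`.
#' @export
misclass_association <- function(cv, feature,
                                 among = c("false_negatives",
                                           "false_positives")) {
  among <- match.arg(among)
  s <- cv$samples[!cv$samples$failed, , drop = FALSE]
  cls <- if (among == "false_negatives") "case" else "control_healthy"
  s <- s[s$true_class == cls, , drop = FALSE]
  f <- if (!is.null(names(feature))) {
    miss <- setdiff(s$array_id, names(feature))
    if (length(miss))
      stop("feature not defined for: ", paste(utils::head(miss, 5),
                                              collapse = ", "))
    as.logical(feature[s$array_id])
  } else {
    if (length(feature) != nrow(cv$samples))
      stop("unnamed feature must align with cv$samples")
    as.logical(feature[match(s$array_id, cv$samples$array_id)])
  }
  if (length(unique(f)) < 2)
    stop("covariate has a single level among the relevant class")
  mis <- s$predicted_class != s$true_class
  tab <- table(feature = factor(f, c(TRUE, FALSE)),
               misclassified = factor(mis, c(TRUE, FALSE)))
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}
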