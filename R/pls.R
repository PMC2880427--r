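#' Fit a PLS1 regression model by NIPALS
#'
#' Univariate-response partial least squares regression. Predictors are
#' centered (and optionally scaled) and deflated component by component:
#' at step a the weight vector is \eqn{w_a = X_{a-1}' y} (normalized),
#' scores \eqn{t_a = X_{a-1} w_a}, x-loadings
#' \eqn{p_a = X_{a-1}' t_a / t_a' t_a}, y-loading
#' \eqn{q_a = y' t_a / t_a' t_a}, and \eqn{X_a = X_{a-1} - t_a p_a'}.
#' Regression coefficient vectors for every truncation
#' \eqn{B_a = W_{1:a} (P_{1:a}' W_{1:a})^{-1} q_{1:a}} are stored, so a
#' fitted model predicts at any number of components up to `A`.
#'
#' Components are stopped early (with the model's `A` reduced) when the
#' residual weight norm underflows, i.e. when `X` has been deflated to
#' numerical rank.
#'
#' @param X numeric samples-by-probes matrix (no missing values); column
#'   names identify probes.
#' @param y numeric response, here the -1/+1 class coding (any
#'   non-constant numeric response is accepted).
#' @param A number of latent components; must satisfy
#'   `A <= min(n - 1, p)`.
#' @param scale logical; scale columns to unit sd in addition to
#'   centering (default `FALSE`: the pipeline standardizes probes during
#'   preprocessing).
#' @return A `PLSModel`: list with `x_mean`, `x_scale`, `y_mean`, `A`,
#'   `W` (p x A weights), `P` (p x A x-loadings), `q` (y-loadings), `T`
#'   (n x A scores), `B` (p x A coefficients, column a = coefficients of
#'   the a-component model) and `probe_ids`.
#' @export
fit_pls1 <- function(X, y, A, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (stats::var(y) == 0) stop("constant response")
  if (A < 1 || A > min(n - 1, p))
    stop("A must be in 1..min(n - 1, p)")
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  Xd <- Xc
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- drop(crossprod(Xd, t)) / tt
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t
    q[a] <- sum(yc * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    a_eff <- a
  }
  if (a_eff == 0L) stop("no usable component (X deflates to zero)")
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  Tm <- Tm[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  B <- matrix(0, p, a_eff)
  V <- crossprod(P, W)   # upper triangular in exact arithmetic
  for (a in seq_len(a_eff)) {
    B[, a] <- W[, seq_len(a), drop = FALSE] %*%
      solve(V[seq_len(a), seq_len(a), drop = FALSE], q[seq_len(a)])
  }
  rownames(B) <- colnames(X)
  structure(list(x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 A = a_eff, W = W, P = P, q = q, T = Tm, B = B,
                 probe_ids = colnames(X)),
            class = "PLSModel")
}

#' @export
print.PLSModel <- function(x, ...) {
  cat(sprintf("PLSModel: %d probes, %d latent components\n",
              length(x$x_mean), x$A))
  invisible(x)
}

#' Continuous prediction scores from a PLS1 model
#'
#' Applies the stored centering/scaling and returns
#' \eqn{\hat y = \bar y + (x - \bar x)' B_a}. When `X_new` carries
#' column names the columns are aligned to the model's probes by id, so
#' probe order is irrelevant.
#'
#' @param model a `PLSModel`.
#' @param X_new samples-by-probes matrix holding the model's probes.
#' @param a number of components to use (default: the model's `A`).
#' @return Numeric vector of raw prediction scores.
#' @export
predict_score <- function(model, X_new, a = model$A) {
  if (a < 1 || a > model$A) stop("a must be in 1..model$A")
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model$probe_ids)) {
    miss <- setdiff(model$probe_ids, colnames(X_new))
    if (length(miss))
      stop("X_new lacks model probes: ",
           paste(utils::head(miss, 5), collapse = ", "))
    X_new <- X_new[, model$probe_ids, drop = FALSE]
  } else if (ncol(X_new) != length(model$x_mean)) {
    stop("X_new has ", ncol(X_new), " probes; model expects ",
         length(model$x_mean))
  }
  Xc <- sweep(sweep(X_new, 2, model$x_mean), 2, model$x_scale, "/")
  drop(model$y_mean + Xc %*% model$B[, a])
}

#' @export
predict.PLSModel <- function(object, newdata, a = object$A, ...) {
  predict_score(object, newdata, a = a)
}

#' Classify a raw prediction score
#'
#' A sample is called a case when its score is strictly greater than
#' zero, and healthy otherwise (a score of exactly zero is healthy).
#'
#' @param score numeric vector of finite raw scores.
#' @return Character vector in \{"case", "control_healthy"\}.
#' @export
classify <- function(score) {
  if (any(!is.finite(score))) stop("non-finite score")
  ifelse(score > 0, "case", "control_healthy")
}

## ---- kernel PLS1 machinery -------------------------------------------
## The leave-one-out loops work on the samples-by-samples Gram matrix
## K = X X', which makes each refit O(n^2 A) instead of O(n p A): every
## NIPALS quantity for centered, unscaled X lives in the row space of X,
## so weights are W = X'R and coefficients B = X'c for n-vectors held in
## R / c. The plain NIPALS fit above is the reference; the kernel path
## is verified against it in the test suite.

# fit on a centered Gram matrix; returns score basis and y-loadings
kernel_pls1_fit <- function(K, yc, A) {
  n <- length(yc)
  Tm <- matrix(0, n, A); Rt <- matrix(0, n, A)
  q <- numeric(A); tt <- numeric(A)
  r <- yc
  a_eff <- 0L
  for (a in seq_len(A)) {
    u <- drop(K %*% r)
    wn2 <- sum(r * u)
    if (wn2 < 1e-12) break
    t <- u
    if (a > 1) {
      prev <- seq_len(a - 1L)
      t <- t - Tm[, prev, drop = FALSE] %*%
        (crossprod(Tm[, prev, drop = FALSE], u) / tt[prev])
    }
    t <- t / sqrt(wn2)
    t2 <- sum(t^2)
    if (t2 < 1e-12) break
    Tm[, a] <- t; Rt[, a] <- r / sqrt(wn2); tt[a] <- t2
    q[a] <- sum(yc * t) / t2
    r <- r - t * (sum(t * yc) / t2)
    a_eff <- a
  }
  if (a_eff == 0L) return(NULL)
  idx <- seq_len(a_eff)
  Tm <- Tm[, idx, drop = FALSE]; Rt <- Rt[, idx, drop = FALSE]
  q <- q[idx]; tt <- tt[idx]
  # V = P'W (a x a): P = X' T diag(1/tt), W = X' Rt => V = diag(1/tt) T' K Rt
  KR <- K %*% Rt
  V <- crossprod(Tm, KR) / tt
  list(T = Tm, R = Rt, q = q, tt = tt, V = V, A = a_eff)
}

# prediction scores for a new sample given its centered kernel vector
# kstar (length n); returns scores at every component count 1..A
kernel_pls1_predict <- function(fit, kstar, y_mean) {
  g <- drop(crossprod(fit$R, kstar))
  A <- fit$A
  tstar <- numeric(A)
  for (a in seq_len(A)) {
    s <- g[a]
    if (a > 1) s <- s - sum(tstar[seq_len(a - 1)] * fit$V[seq_len(a - 1), a])
    tstar[a] <- s
  }
  y_mean + cumsum(tstar * fit$q)
}

# n-vector c with B = X_c' c at component count a
kernel_pls1_cvec <- function(fit, a) {
  idx <- seq_len(a)
  drop(fit$R[, idx, drop = FALSE] %*%
         solve(fit$V[idx, idx, drop = FALSE], fit$q[idx]))
}

# double-center a Gram submatrix: rows/cols idx of K0, centered by the
# column means of X[idx, ]; also returns pieces to center new kernels
center_gram <- function(K0, idx) {
  K <- K0[idx, idx, drop = FALSE]
  rm <- rowMeans(K)
  gm <- mean(rm)
  Kc <- sweep(sweep(K, 1, rm), 2, rm) + gm
  list(K = Kc, row_means = rm, grand_mean = gm)
}

# centered kernel vector between a new sample (row j of K0) and the
# training rows idx: k*_i = (x_j - xbar)'(x_i - xbar)
center_kvec <- function(K0, idx, j, cg) {
  drop(K0[j, idx]) - mean(K0[j, idx]) - cg$row_means + cg$grand_mean
}

#' Leave-one-out cross-validation for PLS1 component choice
#'
#' For each sample, fits PLS1 on the remaining samples at every
#' component count up to `A_max`, predicts the held-out sample and
#' classifies it by the sign rule. `err[a]` is the fraction of samples
#' misclassified at `a` components; the optimal order `a_opt` is the
#' smallest `a` attaining the minimum (ties broken toward fewer
#' components). The per-segment coefficient vectors at `a_opt` are
#' returned for jackknife testing, together with the full-data
#' coefficients at `a_opt`.
#'
#' Computation runs on the samples-by-samples Gram matrix (predictors
#' centered per training set, unscaled), which is exactly equivalent to
#' refitting NIPALS on each leave-one-out split.
#'
#' @param X samples-by-probes matrix (complete).
#' @param y -1/+1 response.
#' @param A_max maximum component count (default `min(30, n - 2)`).
#' @param K0 optional precomputed `tcrossprod(X)` (reused across outer
#'   folds and permutations by the nested cross-validation drivers).
#' @param keep_idx optional integer subset of samples to use (rows of
#'   `X` / entries of `y`); defaults to all.
#' @return List `a_opt`, `err` (length `A_max`), `B_segments`
#'   (probes x n matrix of per-left-out-sample coefficients at `a_opt`),
#'   `b_full` (full-data coefficients at `a_opt`), `scores`
#'   (n x `A_max` held-out scores), `y_mean_full`.
#' @export
loo_cv <- function(X, y, A_max = NULL, K0 = NULL, keep_idx = NULL) {
  X <- as.matrix(X)
  if (is.null(keep_idx)) keep_idx <- seq_len(nrow(X))
  n <- length(keep_idx)
  if (n < 3) stop("need at least 3 samples")
  if (is.null(A_max)) A_max <- min(30L, n - 2L)
  if (A_max > n - 2) stop("A_max must be <= n - 2")
  if (is.null(K0)) K0 <- tcrossprod(X)
  yk <- y[keep_idx]
  if (length(unique(yk)) < 2) stop("response constant over samples used")
  idx0 <- as.integer(keep_idx - 1L)
  fit <- cpp_loo_fit(K0, as.numeric(y), idx0, as.integer(A_max))
  scores <- fit$scores
  failed <- !is.finite(scores[, 1])
  if (any(failed))
    warning(sum(failed), " leave-one-out segment(s) failed (one-class ",
            "training set or rank-deficient split) and were skipped")
  ok <- !failed
  if (!any(ok)) stop("all leave-one-out segments failed")
  pred_class <- scores > 0
  true_case <- yk > 0
  err <- colMeans(pred_class[ok, , drop = FALSE] != true_case[ok])
  a_opt <- which.min(err)  # which.min takes the first (smallest) minimum
  # per-segment coefficient carriers at a_opt: B_m = X_tr'c - xbar_tr sum(c)
  Cm <- cpp_loo_cvecs(fit$Rstore, fit$Vstore, fit$qstore, fit$A,
                      as.integer(a_opt))
  flags <- fit$A > 0
  Cmat <- Cm[, flags, drop = FALSE]                # keep-space, 0 at held-out
  Xk <- X[keep_idx, , drop = FALSE]
  Braw <- crossprod(Xk, Cmat)                      # p x M = X_tr' c
  shift <- colSums(Cmat)
  csX <- colSums(Xk)
  p <- ncol(X); M <- sum(flags)
  Xb <- (matrix(csX, p, M) - t(Xk[which(flags), , drop = FALSE])) / (n - 1)
  B_segments <- Braw - Xb * matrix(shift, p, M, byrow = TRUE)
  rownames(B_segments) <- colnames(X)
  colnames(B_segments) <- rownames(X)[keep_idx[flags]]
  # full-data fit at a_opt
  full <- cpp_full_cvec(K0, as.numeric(y), idx0, as.integer(a_opt))
  cf <- full[seq_len(n)]
  b_full <- drop(crossprod(Xk, cf)) - (csX / n) * sum(cf)
  names(b_full) <- colnames(X)
  list(a_opt = a_opt, err = err, B_segments = B_segments,
       b_full = b_full, scores = scores, y_mean_full = mean(yk),
       n_failed = sum(failed))
}

#' Jackknife test of PLS regression coefficients
#'
#' Tests each probe's full-data regression coefficient against zero
#' using its perturbations across the M leave-one-out segments:
#' \deqn{se_i^2 = \frac{M-1}{M} \sum_m (b_{i} - b_{i,m})^2,\qquad
#'       t_i = b_i / se_i,}
#' with a two-sided p-value from Student's t with M-1 degrees of
#' freedom. Probes with zero jackknife se get p = 1 when their
#' coefficient is zero and p = 0 otherwise (degenerate limit).
#'
#' @param b_full named numeric vector of full-data coefficients.
#' @param B_segments probes-by-M matrix of per-segment coefficients.
#' @return A `JackknifeResult` data.frame with columns `probe_id`, `b`,
#'   `se`, `t`, `p`, and attribute `M`.
#' @export
jackknife_test <- function(b_full, B_segments) {
  M <- ncol(B_segments)
  if (M < 3) stop("need at least 3 jackknife segments")
  dev2 <- (B_segments - b_full)^2
  se <- sqrt((M - 1) / M * rowSums(dev2))
  t <- ifelse(se > 0, b_full / se, ifelse(b_full == 0, 0, Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(b_full / se), df = M - 1),
              ifelse(b_full == 0, 1, 0))
  res <- data.frame(probe_id = names(b_full), b = unname(b_full),
                    se = unname(se), t = unname(t), p = unname(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "M") <- M
  class(res) <- c("JackknifeResult", class(res))
  res
}

#' Jackknife probe selection and refit
#'
#' The single-dataset training procedure: a first leave-one-out
#' cross-validation picks the component count and yields per-segment
#' coefficients; the jackknife test keeps probes with p <= `alpha`; a
#' PLS1 model is rebuilt on the survivors and a second leave-one-out
#' cross-validation picks its component count. When no probe passes the
#' threshold the single smallest-p probe is kept (and flagged in the
#' result).
#'
#' @inheritParams loo_cv
#' @param alpha jackknife selection threshold on the two-sided p-value
#'   (default 0.05, inclusive).
#' @return List `selected_probe_ids`, `model` (a `PLSModel` on the
#'   selected probes at `a_opt2` components), `a_opt1`, `a_opt2`,
#'   `jackknife` (the full `JackknifeResult`), `fallback` (logical).
#' @export
select_and_refit <- function(X, y, alpha = 0.05, A_max = NULL, K0 = NULL,
                             keep_idx = NULL) {
  X <- as.matrix(X)
  if (is.null(keep_idx)) keep_idx <- seq_len(nrow(X))
  inner <- loo_cv(X, y, A_max = A_max, K0 = K0, keep_idx = keep_idx)
  jk <- jackknife_test(inner$b_full, inner$B_segments)
  sel <- jk$probe_id[jk$p <= alpha]
  fallback <- FALSE
  if (length(sel) == 0) {
    sel <- jk$probe_id[which.min(jk$p)]
    fallback <- TRUE
  }
  Xs <- X[keep_idx, sel, drop = FALSE]
  ys <- y[keep_idx]
  n <- length(keep_idx)
  A2 <- min(if (is.null(A_max)) min(30L, n - 2L) else A_max,
            n - 2L, length(sel))
  inner2 <- loo_cv(Xs, ys, A_max = A2)
  model <- fit_pls1(Xs, ys, A = min(inner2$a_opt, length(sel)))
  list(selected_probe_ids = sel, model = model,
       a_opt1 = inner$a_opt, a_opt2 = inner2$a_opt,
       jackknife = jk, fallback = fallback, err1 = inner$err,
       err2 = inner2$err)
}
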