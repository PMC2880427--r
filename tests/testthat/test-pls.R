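test_that("full-component PLS1 reproduces ordinary least squares", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 12; p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    y <- rnorm(n)
    m <- fit_pls1(X, y, A = p)
    Z <- cbind(1, X)
    ols <- drop(Z %*% solve(crossprod(Z), crossprod(Z, y)))
    expect_equal(predict_score(m, X), ols, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("single-probe PLS1 equals simple linear regression", {
  set.seed(9)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "g1"))
  y <- 2 * X[, 1] + rnorm(20, sd = 0.1)
  m <- fit_pls1(X, y, A = 1)
  lmfit <- stats::lm(y ~ X)
  expect_equal(predict_score(m, X), unname(fitted(lmfit)), tolerance = 1e-10)
})

test_that("scores are mutually orthogonal and coefficient routes agree", {
  set.seed(11)
  X <- matrix(rnorm(15 * 9), 15, 9, dimnames = list(NULL, paste0("g", 1:9)))
  y <- rep(c(-1, 1), length.out = 15)
  m <- fit_pls1(X, y, A = 5)
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
  # prediction through B truncations equals the component recursion
  Xc <- sweep(X, 2, m$x_mean)
  for (a in 1:m$A) {
    via_B <- m$y_mean + Xc %*% m$B[, a]
    tstar <- Xc %*% m$W[, 1:a, drop = FALSE] %*%
      solve(crossprod(m$P[, 1:a, drop = FALSE], m$W[, 1:a, drop = FALSE]))
    via_T <- m$y_mean + tstar %*% m$q[1:a]
    expect_equal(drop(via_B), drop(via_T), tolerance = 1e-8)
  }
})

test_that("predicting the centering point returns the response mean", {
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y <- rnorm(10)
  m <- fit_pls1(X, y, A = 2)
  expect_equal(predict_score(m, matrix(m$x_mean, 1,
                                       dimnames = list(NULL, names(m$x_mean)))),
               mean(y), tolerance = 1e-12)
})

test_that("prediction aligns probes by id, not position", {
  set.seed(13)
  X <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(-1, 1), 4)
  m <- fit_pls1(X, y, A = 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(predict_score(m, X[, perm]), predict_score(m, X))
  expect_error(predict_score(m, X[, 1:3]), "lacks model probes")
})

test_that("fit preconditions are enforced", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("g", 1:3)))
  expect_error(fit_pls1(X, rep(1, 4), A = 1), "constant")
  expect_error(fit_pls1(X, c(-1, 1, -1, 1), A = 4), "A must be")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_pls1(Xna, c(-1, 1, -1, 1), A = 1), "missing")
})

test_that("classification uses a strict zero threshold", {
  expect_equal(classify(c(0.1, 0, -0.5)),
               c("case", "control_healthy", "control_healthy"))
  expect_error(classify(NaN), "non-finite")
})

test_that("kernel leave-one-out equals brute-force NIPALS refits", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 12 + seed; p <- sample(c(6, 15, 25), 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
    y <- rep(c(-1, 1), length.out = n)
    A_max <- min(6, n - 2)
    r <- loo_cv(X, y, A_max = A_max)
    expect_equal(r$err, naive_loo_err(X, y, A_max), info = paste("seed", seed))
    Bn <- vapply(seq_len(n), function(m)
      fit_pls1(X[-m, , drop = FALSE], y[-m], A = A_max)$B[, r$a_opt],
      numeric(p))
    expect_equal(unname(r$B_segments), unname(Bn), tolerance = 1e-9)
    expect_equal(unname(r$b_full),
                 unname(fit_pls1(X, y, A = A_max)$B[, r$a_opt]),
                 tolerance = 1e-9)
  }
})

test_that("error curve definition: a_opt attains the minimum, smallest first", {
  xy <- make_xy(20, 10, n_signal = 4, effect = 3, seed = 21)
  r <- loo_cv(xy$X, xy$y, A_max = 6)
  expect_true(all(r$err >= 0 & r$err <= 1))
  expect_equal(r$err[r$a_opt], min(r$err))
  expect_false(any(r$err[seq_len(r$a_opt - 1)] == min(r$err)))
})

test_that("wide-margin one-component data selects one component", {
  set.seed(31)
  n <- 24; p <- 12
  t1 <- rep(c(-2, 2), each = n / 2)
  X <- outer(t1, rnorm(p)) + matrix(rnorm(n * p, sd = 0.05), n, p)
  colnames(X) <- paste0("g", 1:p)
  y <- rep(c(-1, 1), each = n / 2)
  r <- loo_cv(X, y, A_max = 5)
  expect_equal(naive_loo_err(X, y, 5), r$err)
  expect_equal(r$a_opt, 1L)
})

test_that("select_and_refit with alpha = 1 keeps every probe", {
  xy <- make_xy(16, 8, n_signal = 3, effect = 2, seed = 41)
  sr <- select_and_refit(xy$X, xy$y, alpha = 1, A_max = 5)
  expect_setequal(sr$selected_probe_ids, colnames(xy$X))
  expect_false(sr$fallback)
})

test_that("null data selects roughly alpha of the probes", {
  sel_frac <- vapply(1:5, function(s) {
    xy <- make_xy(30, 400, seed = 50 + s)
    sr <- select_and_refit(xy$X, xy$y, alpha = 0.05, A_max = 8)
    length(sr$selected_probe_ids) / 400
  }, 0)
  # binomial 3-se band around 0.05 for pooled 2000 probes
  expect_gt(mean(sel_frac), 0.05 - 3 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(mean(sel_frac), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("probes constant within a training split get zero coefficients", {
  set.seed(61)
  X <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("g", 1:5)))
  X[, 3] <- 0  # identically zero probe: centered away entirely
  y <- rep(c(-1, 1), 5)
  r <- loo_cv(X, y, A_max = 3)
  expect_true(all(r$B_segments["g3", ] == 0))
  expect_equal(unname(r$b_full["g3"]), 0)
})
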