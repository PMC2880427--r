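# Shared fixtures, built in code at test time.

# Random samples-by-probes matrix with an optional planted class shift.
make_xy <- function(n, p, n_signal = 0, effect = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("g%04d", seq_len(p))))
  y <- rep(c(1, -1), length.out = n)  # alternating cases/controls
  sig <- integer(0)
  if (n_signal > 0) {
    sig <- sample.int(p, n_signal)
    signs <- sample(c(-1, 1), n_signal, replace = TRUE)
    X[y > 0, sig] <- X[y > 0, sig] +
      matrix(rep(signs * effect, each = sum(y > 0)), sum(y > 0), n_signal)
  }
  list(X = X, y = y, signal = colnames(X)[sig])
}

# Tiny ExpressionMatrix with full quality grids.
make_em <- function(p = 6, n = 4, seed = 1, snr = NULL, flag = NULL) {
  set.seed(seed)
  v <- matrix(stats::rnorm(p * n, 8, 2), p, n,
              dimnames = list(sprintf("P%03d", seq_len(p)),
                              sprintf("A%02d", seq_len(n))))
  if (is.null(snr)) snr <- matrix(10, p, n)
  if (is.null(flag)) flag <- matrix(0, p, n)
  expression_matrix(v, snr = snr, flag = flag)
}

make_annot <- function(array_ids, class_label, batch_id = "B01",
                       subject_id = NULL, replicate_group = NA_character_) {
  data.frame(array_id = array_ids,
             subject_id = if (is.null(subject_id)) array_ids else subject_id,
             batch_id = batch_id, class_label = class_label,
             replicate_group = replicate_group, stringsAsFactors = FALSE)
}

# Brute-force reference: leave-one-out error curve via plain NIPALS fits.
naive_loo_err <- function(X, y, A_max) {
  n <- nrow(X)
  errs <- matrix(NA, n, A_max)
  for (m in seq_len(n)) {
    f <- fit_pls1(X[-m, , drop = FALSE], y[-m], A = A_max)
    s <- vapply(seq_len(A_max),
                function(a) predict_score(f, X[m, , drop = FALSE],
                                          a = min(a, f$A)), 0)
    errs[m, ] <- (s > 0) != (y[m] > 0)
  }
  colMeans(errs)
}
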