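#' Per-probe influence statistics of the global test
#'
#' The set-level global test statistic used here is the mean over
#' probes of the per-probe influence
#' \deqn{Q_i = \left(\sum_j x_{ij} (y_j - \bar y)\right)^2,}
#' the squared covariance-type association between each probe and the
#' centered class code. A probe orthogonal to the centered response has
#' zero influence; the squared form makes every influence invariant to
#' flipping the response sign.
#'
#' @param X samples-by-probes matrix (standardized probes).
#' @param y -1/+1 class code (any non-constant numeric accepted).
#' @return Named numeric vector of influences, with attribute `Q` (the
#'   set statistic, mean influence).
#' @export
gene_influences <- function(X, y) {
  X <- as.matrix(X)
  if (stats::var(y) == 0) stop("constant response")
  yc <- y - mean(y)
  Qi <- drop(crossprod(X, yc))^2
  names(Qi) <- colnames(X)
  attr(Qi, "Q") <- mean(Qi)
  Qi
}

#' Permutation calibration of the global test
#'
#' Estimates the null mean and sd of every probe's influence from `B`
#' seeded permutations of the response, yielding per-probe z-scores
#' \eqn{z_i = (Q_i - E_i)/s_i} ("standard deviations of influence above
#' the reference line"), a set-level add-one permutation p-value
#' \eqn{(1 + \#\{Q^{perm} \ge Q^{obs}\})/(B + 1)}, and a direction
#' (up/down) from the sign of each probe's covariance with the case
#' code. Probes with zero covariance are assigned direction "up" with a
#' warning; their z-scores never reach the core threshold.
#'
#' @inheritParams gene_influences
#' @param B number of permutations (at least 100).
#' @param seed RNG seed.
#' @param chunk permutations computed per matrix multiplication block
#'   (memory/speed trade-off; no effect on results).
#' @return A `GlobalTestResult`: list with `set_p`, `Q_obs`, `B`,
#'   `seed`, and data.frame `probes` (`probe_id`, `Q`, `E`, `sd`, `z`,
#'   `direction`).
#' @export
null_calibrate <- function(X, y, B = 10000, seed = 1L, chunk = 2000) {
  X <- as.matrix(X)
  if (B < 100) stop("B must be >= 100")
  Qi <- gene_influences(X, y)
  Qobs <- attr(Qi, "Q")
  yc <- y - mean(y)
  p <- ncol(X)
  set.seed(seed)
  sum1 <- numeric(p); sum2 <- numeric(p)
  n_ge <- 0L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Yp <- vapply(seq_len(nb), function(i) sample(yc), yc)  # n x nb
    QP <- crossprod(X, Yp)^2                               # p x nb
    sum1 <- sum1 + rowSums(QP)
    sum2 <- sum2 + rowSums(QP^2)
    n_ge <- n_ge + sum(colMeans(QP) >= Qobs)
    done <- done + nb
  }
  E <- sum1 / B
  s <- sqrt(pmax(sum2 / B - E^2, 0) * B / (B - 1))
  z <- ifelse(s > 0, (Qi - E) / s, 0)
  cov_sign <- drop(crossprod(X, yc))
  if (any(cov_sign == 0))
    warning(sum(cov_sign == 0), " probe(s) with zero covariance assigned ",
            "direction 'up'")
  direction <- ifelse(cov_sign >= 0, "up", "down")
  probes <- data.frame(probe_id = names(Qi), Q = unname(Qi),
                       E = E, sd = s, z = unname(z), direction = direction,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(set_p = (1 + n_ge) / (B + 1), Q_obs = Qobs, B = B,
                 seed = seed, probes = probes),
            class = "GlobalTestResult")
}

#' @export
print.GlobalTestResult <- function(x, ...) {
  cat(sprintf("GlobalTestResult: %d probes, B = %d, set p = %.4g\n",
              nrow(x$probes), x$B, x$set_p))
  core <- core_probes(x)
  cat(sprintf("  core probes (z > 2): %d up, %d down\n",
              length(core$up), length(core$down)))
  invisible(x)
}

#' Extract core probes by influence z-score
#'
#' Core probes are those whose influence z-score strictly exceeds
#' `z_min`, split by regulation direction.
#'
#' @param result a `GlobalTestResult`.
#' @param z_min z-score threshold (default 2, strict inequality).
#' @return List `up` and `down`: character vectors of probe ids.
#' @export
core_probes <- function(result, z_min = 2) {
  p <- result$probes
  hit <- p$z > z_min
  list(up = p$probe_id[hit & p$direction == "up"],
       down = p$probe_id[hit & p$direction == "down"])
}

#' Summarise influence z-scores by direction
#'
#' Median and sd of the z-scores of the up- and down-regulated probes;
#' the summary used to describe a signature's influence distribution.
#'
#' @param result a `GlobalTestResult`.
#' @return data.frame with `direction`, `n`, `median_z`, `sd_z`.
#' @export
z_summary <- function(result) {
  p <- result$probes
  do.call(rbind, lapply(split(p, p$direction), function(d)
    data.frame(direction = d$direction[1], n = nrow(d),
               median_z = stats::median(d$z), sd_z = stats::sd(d$z),
               stringsAsFactors = FALSE)))
}
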