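test_that("quality masking applies both strict thresholds", {
  em <- make_em(p = 2, n = 2)
  em$snr[1, 1] <- 2.9; em$flag[1, 1] <- 0      # low SNR -> masked
  em$snr[1, 2] <- 3.0; em$flag[1, 2] <- 8191   # both at boundary -> kept
  m <- mask_low_quality(em)
  expect_true(m$missing_mask[1, 1])
  expect_false(m$missing_mask[1, 2])
  expect_identical(m$values, em$values)  # values untouched

  em2 <- make_em(p = 2, n = 2)
  em2$flag[] <- c(0, 9000, 100, 8191)
  m2 <- mask_low_quality(em2)
  expect_equal(sum(m2$missing_mask), 1L)

  em3 <- expression_matrix(em$values)  # no quality grids
  expect_error(mask_low_quality(em3), "required")
})

test_that("probe filtering uses a strict 5% rule over all arrays", {
  set.seed(4)
  v <- matrix(rnorm(3 * 156), 3, 156)
  mask <- matrix(FALSE, 3, 156)
  mask[1, 1:8] <- TRUE   # 8/156 = 5.13% -> excluded
  mask[2, 1:7] <- TRUE   # 7/156 = 4.49% -> retained
  em <- expression_matrix(v, missing_mask = mask)
  f <- filter_probes(em)
  expect_equal(f$probe_ids, em$probe_ids[2:3])
})

test_that("standardization centers and scales per probe and is idempotent", {
  em <- make_em(p = 2, n = 3)
  em$values[1, ] <- c(1, 2, 3)
  s <- standardize(em)
  expect_equal(unname(s$values[1, ]), c(-1, 0, 1))
  s2 <- standardize(s)
  expect_equal(s$values, s2$values, tolerance = 1e-12)
  em$values[2, ] <- 5
  expect_error(standardize(em), "P002")
  expect_warning(s3 <- standardize(em, drop_constant = TRUE), "dropped")
  expect_equal(nrow(s3$values), 1L)
})

test_that("batch mean-centering zeroes every within-batch mean", {
  v <- matrix(c(4, 6, 6, 8), 1, 4,
              dimnames = list("P1", paste0("A", 1:4)))
  em <- expression_matrix(v)
  annot <- make_annot(colnames(v), rep(c("case", "control_healthy"), 2),
                      batch_id = rep(c("B1", "B2"), each = 2))
  b <- batch_adjust(em, annot)
  expect_equal(unname(b$values[1, ]), c(-1, 1, -1, 1))
  # invariance to per-batch constant shifts
  em2 <- em; em2$values[, 1:2] <- em2$values[, 1:2] + 7
  expect_equal(batch_adjust(em2, annot)$values, b$values)
  # single batch reduces to probe centering
  annot1 <- make_annot(colnames(v), rep("case", 4))
  b1 <- batch_adjust(em, annot1)
  expect_equal(unname(b1$values[1, ]), unname(v[1, ] - mean(v[1, ])))
  # singleton batches are refused
  annotS <- make_annot(colnames(v), rep("case", 4),
                       batch_id = c("B1", "B1", "B1", "B2"))
  expect_error(batch_adjust(em, annotS), "singleton")
})

test_that("batch means vanish after adjustment on simulated data", {
  d <- generate_dataset(sim_config(n_batches = 5, n_probes = 60,
                                   p_low_snr = 0, batch_sd = 1, seed = 3))
  b <- batch_adjust(d$em, d$annot)
  for (bid in unique(d$annot$batch_id)) {
    idx <- d$annot$batch_id == bid
    expect_lt(max(abs(rowMeans(b$values[, idx]))), 1e-10)
  }
})

test_that("technical-control removal and replicate averaging bookkeeping", {
  d <- generate_dataset(sim_config(n_probes = 40, n_signal_probes = 4,
                                   p_low_snr = 0, seed = 6))
  r <- drop_technical_controls(d$em, d$annot)
  expect_equal(ncol(r$em$values), 130L)
  expect_false(any(r$annot$class_label == "technical_control"))
  r2 <- collapse_replicates(r$em, r$annot)
  expect_equal(ncol(r2$em$values), 127L)
  expect_equal(anyDuplicated(r2$annot$subject_id), 0L)
  # averaged column equals the mean of its replicate columns
  g <- r$annot$replicate_group
  grp <- unique(g[!is.na(g)])[1]
  idx <- which(g == grp)
  kept <- r2$annot$array_id[r2$annot$subject_id == grp]
  expect_equal(r2$em$values[, kept],
               rowMeans(r$em$values[, idx]))
  # no replicates -> identity
  r3 <- collapse_replicates(r2$em, r2$annot)
  expect_identical(r3$em$values, r2$em$values)
  # conflicting class labels within a group are refused
  bad <- r$annot
  bad$class_label[idx[1]] <- "case"
  bad$class_label[idx[2]] <- "control_healthy"
  expect_error(collapse_replicates(r$em, bad), "conflicting")
})

test_that("global mean subtraction zeroes column means and is idempotent", {
  em <- make_em(p = 3, n = 2)
  em$values[, 1] <- c(1, 2, 3)
  g <- global_mean_subtract(em)
  expect_equal(unname(g$values[, 1]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(g$values))), 1e-12)
  expect_equal(global_mean_subtract(g)$values, g$values)
})

test_that("full pipeline: 156 arrays in, 127 out, complete output", {
  d <- generate_dataset(sim_config(n_probes = 300, seed = 8))
  pp <- preprocess_pipeline(d$em, d$annot)
  expect_equal(pp$report$n_arrays_in, 156L)
  expect_equal(pp$report$n_arrays_out, 127L)
  expect_false(anyNA(pp$em$values))
  expect_false(any(pp$em$missing_mask))
  expect_false(any(pp$annot$class_label == "technical_control"))
  expect_lte(pp$report$n_probes_out, pp$report$n_probes_in)
  expect_lt(max(abs(colMeans(pp$em$values))), 1e-12)
  steps <- pp$report$log$step
  expect_equal(steps[1], "mask_low_quality")
  expect_equal(steps[length(steps)], "global_mean_subtract")
})

test_that("max_missing_frac = 0 keeps only fully observed probes", {
  d <- generate_dataset(sim_config(n_batches = 2, n_probes = 200,
                                   p_low_snr = 0.05, seed = 10))
  m <- mask_low_quality(d$em)
  f <- filter_probes(m, preprocess_params(max_missing_frac = 0))
  expect_true(all(rowSums(f$missing_mask) == 0))
  expect_equal(nrow(f$values), sum(rowSums(m$missing_mask) == 0))
})

test_that("batch adjustment reduces the between-batch variance share", {
  d <- generate_dataset(sim_config(n_batches = 6, n_probes = 150,
                                   n_signal_probes = 0, effect_size = 0,
                                   batch_sd = 1.5, p_low_snr = 0, seed = 12))
  share <- function(em, annot) {
    v <- em$values
    batches <- split(seq_len(ncol(v)), annot$batch_id)
    between <- Reduce(`+`, lapply(batches, function(idx)
      length(idx) * (rowMeans(v[, idx, drop = FALSE]) - rowMeans(v))^2))
    total <- rowSums((v - rowMeans(v))^2)
    mean(between / total)
  }
  before <- share(d$em, d$annot)
  after <- share(batch_adjust(d$em, d$annot), d$annot)
  expect_lt(after, before)
})
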