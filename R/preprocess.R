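#' Preprocessing parameters
#'
#' Thresholds and tuning constants of the preprocessing chain: a
#' measurement is set missing when its signal-to-noise ratio is below
#' `snr_min` (strict) or its scanner flag exceeds `flag_max` (strict);
#' probes missing in more than `max_missing_frac` of arrays are dropped;
#' remaining gaps are filled by k-nearest-neighbour imputation over
#' probes with `knn_k` neighbours.
#'
#' @param snr_min signal-to-noise threshold (default 3).
#' @param flag_max flag threshold (default 8191).
#' @param max_missing_frac maximum tolerated per-probe missing fraction
#'   (default 0.05).
#' @param knn_k neighbour count for imputation (default 10).
#' @return A `PreprocessParams` list.
#' @export
preprocess_params <- function(snr_min = 3, flag_max = 8191,
                              max_missing_frac = 0.05, knn_k = 10) {
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("max_missing_frac must be in [0, 1]")
  if (knn_k < 1) stop("knn_k must be >= 1")
  structure(list(snr_min = snr_min, flag_max = flag_max,
                 max_missing_frac = max_missing_frac, knn_k = knn_k),
            class = "PreprocessParams")
}

#' Mask low-quality measurements
#'
#' Marks as missing every entry with signal-to-noise below `snr_min` or
#' flag above `flag_max` (both comparisons strict). Values are left in
#' place; only the mask changes.
#'
#' @param em `ExpressionMatrix` with both quality grids present.
#' @param params [preprocess_params()].
#' @return The matrix with an updated `missing_mask`.
#' @export
mask_low_quality <- function(em, params = preprocess_params()) {
  if (is.null(em$snr) || is.null(em$flag))
    stop("snr and flag grids are required to mask low-quality entries")
  mask <- em$missing_mask | em$snr < params$snr_min | em$flag > params$flag_max
  expression_matrix(em$values, snr = em$snr, flag = em$flag,
                    missing_mask = mask)
}

#' Drop probes with too many missing values
#'
#' Removes probes whose missing fraction across all arrays exceeds
#' `max_missing_frac` (strict). Survivor order is preserved.
#'
#' @inheritParams mask_low_quality
#' @return Filtered `ExpressionMatrix`.
#' @export
filter_probes <- function(em, params = preprocess_params()) {
  frac <- rowMeans(em$missing_mask)
  em_subset(em, probes = which(frac <= params$max_missing_frac))
}

#' Standardize probes
#'
#' Centers and scales each probe row to mean 0 and sample (n-1) sd 1
#' over its non-missing entries.
#'
#' @param em `ExpressionMatrix`.
#' @param drop_constant in pipeline use, constant (zero-variance) probes
#'   are dropped with a warning; when `FALSE` (default) they raise an
#'   error naming the probe.
#' @return Standardized `ExpressionMatrix`.
#' @export
standardize <- function(em, drop_constant = FALSE) {
  v <- em$values
  v[em$missing_mask] <- NA_real_
  mu <- rowMeans(v, na.rm = TRUE)
  sd <- apply(v, 1, stats::sd, na.rm = TRUE)
  bad <- which(!is.finite(sd) | sd == 0)
  if (length(bad)) {
    if (!drop_constant)
      stop("zero-variance probe(s): ",
           paste(utils::head(em$probe_ids[bad], 5), collapse = ", "))
    warning(length(bad), " zero-variance probe(s) dropped")
    em <- em_subset(em, probes = -bad)
    return(standardize(em, drop_constant = FALSE))
  }
  vs <- (em$values - mu) / sd
  expression_matrix(vs, snr = em$snr, flag = em$flag,
                    missing_mask = em$missing_mask)
}

#' K-nearest-neighbour imputation over probes
#'
#' Fills each masked entry with a 1/distance-weighted mean of the
#' `knn_k` nearest probes (Euclidean distance over mutually observed
#' arrays, rescaled by the number of shared arrays) among probes
#' observed at the target array. Distances of zero are guarded with an
#' epsilon of 1e-6 before inversion. With fewer than `knn_k` eligible
#' neighbours all eligible ones are used; with none, the probe's own
#' observed mean is used.
#'
#' @inheritParams mask_low_quality
#' @return Complete `ExpressionMatrix` (empty mask).
#' @export
knn_impute <- function(em, params = preprocess_params()) {
  v <- em$values
  v[em$missing_mask] <- NA_real_
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0))
    stop("probe(s) with all values missing cannot be imputed")
  if (!any(is.na(v))) return(em_complete(em, em$values))
  p <- nrow(v)
  z <- v; z[!obs] <- 0
  o <- obs * 1
  targets <- which(rowSums(!obs) > 0)
  # pairwise squared distances over shared arrays, rescaled by shared count
  zz <- z * z
  A <- zz[targets, , drop = FALSE] %*% t(o)     # sum x_t^2 over c-observed
  Bm <- o[targets, , drop = FALSE] %*% t(zz)    # sum x_c^2 over t-observed
  Cm <- z[targets, , drop = FALSE] %*% t(z)     # cross term (0 where unobs)
  S <- o[targets, , drop = FALSE] %*% t(o)      # shared array counts
  D2 <- (A + Bm - 2 * Cm) / S
  D2[S == 0] <- Inf
  out <- v
  for (ti in seq_along(targets)) {
    i <- targets[ti]
    d <- sqrt(pmax(D2[ti, ], 0))
    d[i] <- Inf
    ord <- order(d)
    ord <- ord[is.finite(d[ord])]
    for (j in which(!obs[i, ])) {
      elig <- ord[obs[ord, j]]
      if (length(elig) == 0) {
        out[i, j] <- mean(v[i, ], na.rm = TRUE)
      } else {
        nb <- elig[seq_len(min(params$knn_k, length(elig)))]
        w <- 1 / (d[nb] + 1e-6)
        out[i, j] <- sum(w * v[nb, j]) / sum(w)
      }
    }
  }
  em_complete(em, out)
}

em_complete <- function(em, values) {
  expression_matrix(values, snr = em$snr, flag = em$flag,
                    missing_mask = matrix(FALSE, nrow(values), ncol(values)))
}

#' Remove batch effects by per-probe batch mean-centering
#'
#' One-way ANOVA batch-effect removal: for each probe, the mean of the
#' arrays of a batch is subtracted from every entry of that batch, so
#' per-probe per-batch means are exactly zero afterwards. The grand
#' level is deliberately not restored; a later global mean subtraction
#' fixes the per-array level.
#'
#' @param em complete `ExpressionMatrix`.
#' @param annot annotation providing `batch_id` per array.
#' @return Batch-centered `ExpressionMatrix`.
#' @export
batch_adjust <- function(em, annot) {
  annot <- validate_annotation(annot, em)
  if (any(em$missing_mask))
    stop("batch adjustment requires a complete matrix")
  batches <- split(seq_len(ncol(em$values)), annot$batch_id)
  sizes <- lengths(batches)
  if (any(sizes < 2))
    stop("singleton batch(es): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- em$values
  for (idx in batches)
    v[, idx] <- v[, idx] - rowMeans(v[, idx, drop = FALSE])
  expression_matrix(v, snr = em$snr, flag = em$flag,
                    missing_mask = em$missing_mask)
}

#' Drop technical-control arrays
#'
#' @param em `ExpressionMatrix`.
#' @param annot annotation table.
#' @return List `em`, `annot` with technical controls removed.
#' @export
drop_technical_controls <- function(em, annot) {
  annot <- validate_annotation(annot, em)
  keep <- which(annot$class_label != "technical_control")
  list(em = em_subset(em, arrays = keep),
       annot = annot[keep, , drop = FALSE])
}

#' Average biological replicate arrays
#'
#' Collapses arrays sharing a `replicate_group` to their per-probe mean,
#' leaving one array per subject. Class labels must agree within a
#' group. The collapsed array keeps the first array's id and loses its
#' batch assignment (set to `NA`, since its arrays may span batches).
#'
#' @param em complete `ExpressionMatrix`.
#' @param annot annotation table.
#' @return List `em`, `annot`.
#' @export
collapse_replicates <- function(em, annot) {
  annot <- validate_annotation(annot, em)
  grp <- annot$replicate_group
  if (all(is.na(grp))) return(list(em = em, annot = annot))
  keep_rows <- logical(nrow(annot))
  v <- em$values
  out_cols <- list(); out_annot <- list()
  seen <- character(0)
  for (i in seq_len(nrow(annot))) {
    g <- grp[i]
    if (is.na(g)) {
      out_cols[[length(out_cols) + 1L]] <- v[, i]
      out_annot[[length(out_annot) + 1L]] <- annot[i, ]
    } else if (!(g %in% seen)) {
      seen <- c(seen, g)
      idx <- which(grp == g)
      cls <- unique(annot$class_label[idx])
      if (length(cls) > 1)
        stop("conflicting class labels in replicate group ", g)
      out_cols[[length(out_cols) + 1L]] <-
        rowMeans(v[, idx, drop = FALSE])
      a <- annot[idx[1], ]
      a$batch_id <- if (length(unique(annot$batch_id[idx])) == 1)
        a$batch_id else NA_character_
      out_annot[[length(out_annot) + 1L]] <- a
    }
  }
  vn <- do.call(cbind, out_cols)
  an <- do.call(rbind, out_annot)
  colnames(vn) <- an$array_id
  rownames(vn) <- em$probe_ids
  rownames(an) <- NULL
  list(em = expression_matrix(vn), annot = an)
}

#' Global mean subtraction (within-array normalization)
#'
#' Subtracts from each array its mean over all probes, so every column
#' mean is zero. Idempotent.
#'
#' @param em complete `ExpressionMatrix`.
#' @return Normalized `ExpressionMatrix`.
#' @export
global_mean_subtract <- function(em) {
  v <- sweep(em$values, 2, colMeans(em$values))
  expression_matrix(v, snr = em$snr, flag = em$flag,
                    missing_mask = em$missing_mask)
}

#' Full preprocessing chain
#'
#' Runs, in fixed order: quality masking, probe filtering,
#' standardization (constant probes dropped with a warning), KNN
#' imputation, batch mean-centering, technical-control removal,
#' replicate averaging, and global mean subtraction. Preprocessing is
#' performed once on the full dataset, before any cross-validation, as
#' in the toolchain this package follows; see the package vignette for
#' the information-leakage caveat this implies.
#'
#' @param em raw log2 `ExpressionMatrix` with quality grids.
#' @param annot annotation table.
#' @param params [preprocess_params()].
#' @return List `em`, `annot`, `report` (a `PreprocessReport` with
#'   in/out probe and array counts, masked-entry count and a per-step
#'   log data.frame).
#' @export
preprocess_pipeline <- function(em, annot, params = preprocess_params()) {
  annot <- validate_annotation(annot, em)
  steps <- list()
  log_step <- function(name, em) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, n_probes = nrow(em$values), n_arrays = ncol(em$values),
      n_masked = sum(em$missing_mask), stringsAsFactors = FALSE)
  }
  n_probes_in <- nrow(em$values); n_arrays_in <- ncol(em$values)
  em <- mask_low_quality(em, params);           log_step("mask_low_quality", em)
  n_masked <- sum(em$missing_mask)
  em <- filter_probes(em, params);              log_step("filter_probes", em)
  em <- withCallingHandlers(
    standardize(em, drop_constant = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  log_step("standardize", em)
  em <- knn_impute(em, params);                 log_step("knn_impute", em)
  em <- batch_adjust(em, annot);                log_step("batch_adjust", em)
  r <- drop_technical_controls(em, annot)
  em <- r$em; annot <- r$annot;                 log_step("drop_technical_controls", em)
  r <- collapse_replicates(em, annot)
  em <- r$em; annot <- r$annot;                 log_step("collapse_replicates", em)
  em <- global_mean_subtract(em);               log_step("global_mean_subtract", em)
  report <- structure(list(
    n_probes_in = n_probes_in, n_probes_out = nrow(em$values),
    n_arrays_in = n_arrays_in, n_arrays_out = ncol(em$values),
    n_masked_entries = n_masked,
    log = do.call(rbind, steps)), class = "PreprocessReport")
  list(em = em, annot = annot, report = report)
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat(sprintf("PreprocessReport: %d -> %d probes, %d -> %d arrays, %d entries masked\n",
              x$n_probes_in, x$n_probes_out, x$n_arrays_in, x$n_arrays_out,
              x$n_masked_entries))
  print(x$log, row.names = FALSE)
  invisible(x)
}
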