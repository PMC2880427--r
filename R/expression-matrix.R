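#' Expression matrix with quality grids
#'
#' Container for probe-by-array log2 intensities together with the
#' per-measurement quality fields produced by single-channel array
#' scanners: a signal-to-noise grid, an integer flag grid, and a logical
#' missingness mask. All grids share the same probe-by-array dimensions.
#' Masked entries keep their numeric value in `values` but must be
#' treated as absent by downstream arithmetic; the preprocessing chain
#' enforces this.
#'
#' @param values numeric matrix (probes x arrays) of log2 intensities.
#'   Must carry rownames (probe ids) and colnames (array ids), both unique.
#' @param snr optional nonnegative numeric matrix of signal-to-noise
#'   ratios, same dimensions as `values`.
#' @param flag optional nonnegative integer matrix of scanner flags,
#'   same dimensions as `values`.
#' @param missing_mask optional logical matrix marking entries to treat
#'   as missing; defaults to `is.na(values)`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `snr`, `flag`, `missing_mask`, `probe_ids`, `array_ids`.
#' @export
expression_matrix <- function(values, snr = NULL, flag = NULL,
                              missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- sprintf("A%03d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("probe ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("array ids must be unique")
  chk_grid <- function(g, nm) {
    if (is.null(g)) return(NULL)
    if (!is.matrix(g) || !all(dim(g) == dim(values)))
      stop(sprintf("`%s` must be a matrix with the same dimensions as `values`", nm))
    dimnames(g) <- dimnames(values)
    g
  }
  snr  <- chk_grid(snr, "snr")
  flag <- chk_grid(flag, "flag")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- chk_grid(missing_mask, "missing_mask")
  if (!is.logical(missing_mask))
    stop("`missing_mask` must be logical")
  structure(
    list(values = values, snr = snr, flag = flag,
         missing_mask = missing_mask,
         probe_ids = rownames(values), array_ids = colnames(values)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d arrays\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  masked entries: %d (%.2f%%)\n", sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  cat(sprintf("  quality grids: snr %s, flag %s\n",
              if (is.null(x$snr)) "absent" else "present",
              if (is.null(x$flag)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by probes and/or arrays
#'
#' All grids are subset in parallel so the object stays consistent.
#'
#' @param x an `ExpressionMatrix`.
#' @param probes,arrays index vectors (integer, logical or character).
#' @return An `ExpressionMatrix`.
#' @export
em_subset <- function(x, probes = NULL, arrays = NULL) {
  pi <- if (is.null(probes)) seq_len(nrow(x$values)) else probes
  ai <- if (is.null(arrays)) seq_len(ncol(x$values)) else arrays
  sub <- function(g) if (is.null(g)) NULL else g[pi, ai, drop = FALSE]
  expression_matrix(sub(x$values), snr = sub(x$snr), flag = sub(x$flag),
                    missing_mask = sub(x$missing_mask))
}

#' Extract the analysis matrix in samples-by-probes orientation
#'
#' Transposes the stored probes-by-arrays grid into the orientation used
#' by the modelling layer. Masked entries are returned as `NA`.
#'
#' @param x an `ExpressionMatrix`.
#' @return Numeric matrix, arrays in rows, probes in columns.
#' @export
em_samples_matrix <- function(x) {
  v <- x$values
  v[x$missing_mask] <- NA_real_
  t(v)
}

#' Validate a sample annotation table against an expression matrix
#'
#' The annotation must contain the columns `array_id`, `subject_id`,
#' `batch_id`, `class_label` and `replicate_group`, with exactly one row
#' per array of the matrix. `class_label` takes values in
#' \{`case`, `control_healthy`, `technical_control`\}.
#'
#' @param annot a data.frame of per-array annotations.
#' @param em optional `ExpressionMatrix` whose arrays must all be covered.
#' @return The annotation, reordered to the matrix's array order when
#'   `em` is given (invisibly validated otherwise).
#' @export
validate_annotation <- function(annot, em = NULL) {
  need <- c("array_id", "subject_id", "batch_id", "class_label",
            "replicate_group")
  miss <- setdiff(need, names(annot))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  ok <- c("case", "control_healthy", "technical_control")
  bad <- setdiff(unique(annot$class_label), ok)
  if (length(bad))
    stop("unknown class labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(annot$array_id))
    stop("duplicate array_id in annotation")
  if (!is.null(em)) {
    if (!setequal(annot$array_id, em$array_ids))
      stop("annotation arrays do not match matrix arrays")
    annot <- annot[match(em$array_ids, annot$array_id), , drop = FALSE]
    rownames(annot) <- NULL
  }
  annot
}

#' Case/control response coding
#'
#' Builds the -1/+1 dummy response used by the PLS1 classifier: +1 for
#' cases, -1 for healthy controls. Technical controls are not allowed.
#'
#' @param annot annotation table (see [validate_annotation()]).
#' @return Named numeric vector in \{-1, +1\} (names = array ids), with a
#'   `class_map` attribute recording the coding.
#' @export
response_vector <- function(annot) {
  if (any(annot$class_label == "technical_control"))
    stop("technical controls cannot be coded as a response")
  y <- ifelse(annot$class_label == "case", 1, -1)
  names(y) <- annot$array_id
  if (length(unique(y)) < 2)
    stop("both classes must be present to build a response")
  attr(y, "class_map") <- c(`-1` = "control_healthy", `1` = "case")
  y
}
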