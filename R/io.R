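#' Write a dataset to plain-text files
#'
#' Writes the expression values, quality grids and annotation of a
#' dataset as tab/comma-separated text that round-trips losslessly
#' through [read_dataset()]. The value, SNR and flag grids are TSVs with
#' a leading `probe_id` column and one column per array; missing values
#' are written as `NA`. The annotation is a CSV with columns
#' `array_id,subject_id,batch_id,class_label,replicate_group`.
#'
#' @param em an `ExpressionMatrix`.
#' @param annot annotation table matching `em`.
#' @param dir_path output directory (created if absent).
#' @return Invisibly, the named character vector of files written.
#' @export
write_dataset <- function(em, annot, dir_path) {
  annot <- validate_annotation(annot, em)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  files <- c(matrix = file.path(dir_path, "matrix.tsv"),
             annot = file.path(dir_path, "annotation.csv"),
             snr = file.path(dir_path, "snr.tsv"),
             flag = file.path(dir_path, "flag.tsv"))
  write_grid <- function(g, path) {
    ids <- if (is.null(rownames(g))) character(nrow(g)) else rownames(g)
    df <- data.frame(probe_id = ids, g, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  v <- em$values
  v[em$missing_mask] <- NA_real_
  write_grid(v, files[["matrix"]])
  if (!is.null(em$snr)) write_grid(em$snr, files[["snr"]]) else files <- files[names(files) != "snr"]
  if (!is.null(em$flag)) write_grid(em$flag, files[["flag"]]) else files <- files[names(files) != "flag"]
  utils::write.csv(annot, files[["annot"]], row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(files)
}

read_grid_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("expected first column `probe_id` in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$probe_id)
  m
}

#' Read an expression matrix TSV
#'
#' Dialect: first column `probe_id`, one tab-separated column per array,
#' missing entries written as `NA`.
#'
#' @param path TSV file path.
#' @param snr_path,flag_path optional TSVs with identical layout holding
#'   the signal-to-noise and flag grids.
#' @param log2_transform if `TRUE` the values are assumed to be on the
#'   raw linear scale and are log2-transformed on read (nonpositive
#'   entries become masked).
#' @return An `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, snr_path = NULL, flag_path = NULL,
                                log2_transform = FALSE) {
  v <- read_grid_tsv(path)
  if (log2_transform) {
    v[v <= 0] <- NA_real_
    v <- log2(v)
  }
  snr <- if (!is.null(snr_path)) read_grid_tsv(snr_path)
  flag <- if (!is.null(flag_path)) read_grid_tsv(flag_path)
  expression_matrix(v, snr = snr, flag = flag)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir_path directory holding `matrix.tsv`, `annotation.csv` and
#'   optionally `snr.tsv` / `flag.tsv`.
#' @return List with elements `em` and `annot`.
#' @export
read_dataset <- function(dir_path) {
  p <- function(f) file.path(dir_path, f)
  snr <- if (file.exists(p("snr.tsv"))) p("snr.tsv")
  flag <- if (file.exists(p("flag.tsv"))) p("flag.tsv")
  em <- read_expression_tsv(p("matrix.tsv"), snr_path = snr, flag_path = flag)
  annot <- utils::read.csv(p("annotation.csv"), stringsAsFactors = FALSE,
                           colClasses = "character")
  annot$replicate_group[annot$replicate_group == ""] <- NA_character_
  list(em = em, annot = validate_annotation(annot, em))
}

#' Read a GEO Series Matrix file
#'
#' Parses the plain-text GEO "series matrix" layout: metadata lines
#' starting with `!`, and a tab-separated expression table delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end` whose first
#' column is the probe reference and whose remaining columns are sample
#' accessions. Only the expression table and the sample titles (when
#' present) are extracted; quality grids are not part of this format.
#'
#' @param path file path (uncompressed text).
#' @return An `ExpressionMatrix` (no snr/flag grids; `NA` entries masked),
#'   with the `!Sample_title` line (if any) attached as attribute
#'   `sample_titles`.
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("no series matrix table found in ", path)
  tab <- lines[(beg + 1):(end - 1)]
  con <- textConnection(tab)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  em <- expression_matrix(m)
  titles <- grep("^!Sample_title\t", lines, value = TRUE)
  if (length(titles) == 1) {
    tt <- strsplit(sub("^!Sample_title\t", "", titles), "\t")[[1]]
    attr(em, "sample_titles") <- gsub('^"|"$', "", tt)
  }
  em
}
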