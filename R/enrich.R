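#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are counted once; empty member fields are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> members), with
#'   descriptions attached as attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s) (fewer than 3 fields): ",
         paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors, as from [read_gmt()].
#' @param path output path.
#' @param descriptions optional named descriptions (default "na").
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' For every set, builds the 2x2 table of query/background membership
#' and computes a one-sided over-representation p-value: `fisher` is the
#' hypergeometric upper tail \eqn{P(X \ge c)}; `ease` is the
#' conservative variant with the overlap count reduced by one (floored
#' at zero), the default score of the DAVID service. Fold enrichment is
#' \eqn{(c/|query|) / (|set \cap bg| / |bg|)}, and the
#' Benjamini-Hochberg adjusted p-value is reported in percent across
#' all returned sets.
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe (e.g. all
#'   genes surviving preprocessing).
#' @param sets named list of gene sets (see [read_gmt()]); each set is
#'   intersected with the background.
#' @param method `"ease"` (default) or `"fisher"`.
#' @param min_count drop sets overlapping the query in fewer genes
#'   (default 1).
#' @return data.frame of `EnrichmentRow`s ordered by p: `term_id`,
#'   `term_name`, `count`, `pct`, `p`, `fold`, `fdr_pct`, `genes`
#'   (comma-separated members).
#' @export
enrich <- function(query, background, sets, method = c("ease", "fisher"),
                   min_count = 1) {
  method <- match.arg(method)
  query <- unique(query); background <- unique(background)
  off <- setdiff(query, background)
  if (length(off))
    stop("query gene(s) absent from background: ",
         paste(utils::head(off, 5), collapse = ", "))
  N <- length(background); nq <- length(query)
  rows <- lapply(names(sets), function(nm) {
    term <- intersect(sets[[nm]], background)
    hit <- intersect(term, query)
    c_ <- length(hit); K <- length(term)
    if (c_ < min_count || K == 0) return(NULL)
    cc <- if (method == "ease") max(c_ - 1L, 0L) else c_
    p <- stats::phyper(cc - 1L, K, N - K, nq, lower.tail = FALSE)
    data.frame(term_id = nm, term_name = nm, count = c_,
               pct = 100 * c_ / nq, p = p,
               fold = (c_ / nq) / (K / N),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), term_name = character(),
                      count = integer(), pct = numeric(), p = numeric(),
                      fold = numeric(), fdr_pct = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  desc <- attr(sets, "descriptions")
  if (!is.null(desc)) out$term_name <- unname(desc[out$term_id])
  out$fdr_pct <- 100 * stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), c("term_id", "term_name", "count", "pct", "p",
                             "fold", "fdr_pct", "genes")]
  rownames(out) <- NULL
  out
}

#' Map probe ids to gene symbols
#'
#' Drops probes without an annotation (reporting how many) and
#' collapses duplicate gene symbols, preserving first-occurrence order.
#'
#' @param probe_ids character vector of probe ids.
#' @param annotation data.frame with columns `probe_id` and
#'   `gene_symbol` (empty or `NA` symbols count as unannotated).
#' @return Character vector of unique gene symbols, with attribute
#'   `n_unannotated`.
#' @export
map_probes_to_genes <- function(probe_ids, annotation) {
  sym <- annotation$gene_symbol[match(probe_ids, annotation$probe_id)]
  sym[!is.na(sym) & !nzchar(sym)] <- NA_character_
  n_un <- sum(is.na(sym))
  genes <- unique(sym[!is.na(sym)])
  attr(genes, "n_unannotated") <- n_un
  genes
}
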