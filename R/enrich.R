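# Over-representation of annotation terms (GO/KEGG) among repeat-bearing
# coding sequences: upper-tail hypergeometric test against a background
# annotation map, with Benjamini-Hochberg adjustment.

#' Read an annotation map (eggNOG-mapper-style TSV)
#'
#' Accepts either a two-column TSV (`id`, comma-separated terms) or an
#' eggNOG-mapper annotations table (comment lines starting `##`, header
#' line starting `#query`); term columns named `GOs` and/or
#' `KEGG_Pathway` are used, `-` meaning no terms.
#'
#' @param path TSV path.
#' @param term_columns columns to harvest terms from when the eggNOG
#'   layout is detected.
#' @return named list mapping sequence ID to a character vector of term
#'   IDs (class `ssr_annotation_map`).
#' @export
read_annotation_map <- function(path,
                                term_columns = c("GOs", "KEGG_Pathway")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^##", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  header <- grepl("^#query", lines[1])
  if (header) lines[1] <- sub("^#", "", lines[1])
  d <- utils::read.delim(text = paste(lines, collapse = "\n"),
                         header = header, stringsAsFactors = FALSE)
  if (header) {
    cols <- intersect(term_columns, names(d))
    if (!length(cols)) stop("no term column among: ",
                            paste(term_columns, collapse = ", "))
    ids <- d[[1]]
    terms <- apply(d[cols], 1L, function(r)
      paste(r[r != "-" & !is.na(r)], collapse = ","))
  } else {
    if (ncol(d) < 2) stop("expect at least two columns (id, terms)")
    ids <- d[[1]]
    terms <- d[[2]]
  }
  map <- lapply(strsplit(terms, ","), function(t)
    unique(t[nzchar(t) & t != "-"]))
  names(map) <- ids
  class(map) <- "ssr_annotation_map"
  map
}

#' Hypergeometric term enrichment
#'
#' For each term, tests whether the query set is enriched relative to the
#' background: upper-tail hypergeometric p = P(X >= k) with population
#' size N (background IDs), K background IDs carrying the term, sample
#' size n (query IDs) and k query IDs carrying the term.
#'
#' @param query character vector of sequence IDs (e.g. CDSs containing
#'   perfect SSRs). IDs absent from the background are dropped with a
#'   warning; an empty query after filtering is an error.
#' @param annot background map from [read_annotation_map()] (or a plain
#'   named list ID -> term vector).
#' @param p_cutoff optional raw-p filter for the returned rows (default
#'   keeps everything).
#' @return data.frame sorted by p ascending with columns `term`, `k`,
#'   `K`, `n`, `N`, `p`, `q` (BH-adjusted).
#' @export
enrich <- function(query, annot, p_cutoff = 1) {
  background <- names(annot)
  drop <- setdiff(query, background)
  if (length(drop))
    warning(length(drop), " query ID(s) absent from background dropped")
  query <- intersect(query, background)
  if (!length(query)) stop("empty query after background filtering")
  N <- length(background)
  n <- length(query)
  term_by_id <- unclass(annot)
  bg_tab <- table(unlist(term_by_id, use.names = FALSE))
  q_tab <- table(unlist(term_by_id[query], use.names = FALSE))
  terms <- names(bg_tab)
  k <- as.integer(q_tab[terms]); k[is.na(k)] <- 0L
  K <- as.integer(bg_tab[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[out$p <= p_cutoff, , drop = FALSE]
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
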