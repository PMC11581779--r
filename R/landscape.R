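# Normalized landscape statistics. Relative abundance is loci per Mbp of
# valid (non-N) sequence; relative density is repeat bp per Mbp of valid
# sequence; percent-of-genome uses the full assembly length including Ns.

#' Summarize an SSR landscape
#'
#' @param loci detection table ([detect_ssrs()] layout; a `region_label`
#'   column is required for `level = "by_region"`).
#' @param seqs the genome the loci were called on (named character vector).
#' @param level grouping: `"total"`, `"by_type"` (P/I/C), `"by_k"` (motif
#'   size, perfect loci), `"by_class"` (canonical class, perfect loci), or
#'   `"by_region"` (genic region, perfect loci).
#' @param species optional species label carried into the output.
#' @return data.frame with columns `species`, `group`, `count`,
#'   `total_length`, `rel_abundance` (loci/Mbp valid), `rel_density`
#'   (bp/Mbp valid), `gc_fraction` (of the locus sequences; NA when
#'   empty), `pct_genome` (% of full assembly length).
#' @export
summarize_landscape <- function(loci, seqs,
                                level = c("total", "by_type", "by_k",
                                          "by_class", "by_region"),
                                species = "genome") {
  level <- match.arg(level)
  seqs <- .as_genome(seqs)
  vl <- sum(valid_length(seqs))
  gl <- sum(nchar(seqs))
  if (vl == 0) stop("zero valid (non-N) length")
  if (level != "by_type" && "type" %in% names(loci) &&
      level %in% c("by_k", "by_class", "by_region"))
    loci <- loci[loci$type == "P", , drop = FALSE]
  groups <- switch(level,
    total = rep("total", nrow(loci)),
    by_type = loci$type,
    by_k = as.character(loci$k),
    by_class = loci$motif_class,
    by_region = {
      if (!"region_label" %in% names(loci))
        stop("by_region requires a region_label column (assign_regions)")
      loci$region_label
    })
  .one <- function(rows, g) {
    tl <- sum(loci$length[rows])
    gc <- if (length(rows)) .gc_of_loci(loci[rows, , drop = FALSE], seqs)
          else NA_real_
    data.frame(species = species, group = g, count = length(rows),
               total_length = tl,
               rel_abundance = length(rows) / (vl / 1e6),
               rel_density = tl / (vl / 1e6),
               gc_fraction = gc,
               pct_genome = 100 * tl / gl,
               stringsAsFactors = FALSE)
  }
  if (level == "total") {
    out <- .one(seq_len(nrow(loci)), "total")
  } else {
    gs <- sort(unique(groups))
    out <- do.call(rbind, lapply(gs, function(g) .one(which(groups == g), g)))
    if (is.null(out)) out <- .one(integer(0), NA_character_)[0, ]
  }
  attr(out, "valid_length") <- vl
  attr(out, "genome_length") <- gl
  rownames(out) <- NULL
  out
}

.gc_of_loci <- function(loci, seqs) {
  if (!nrow(loci)) return(NA_real_)
  s <- substr(seqs[loci$seq_id], loci$start, loci$end)
  s <- paste(s, collapse = "")
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  gc <- sum(counts[c("G", "C")], na.rm = TRUE)
  at <- sum(counts[c("A", "T")], na.rm = TRUE)
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}

#' GC content of SSR loci
#'
#' Fraction (G+C)/(A+C+G+T) over the concatenated extracted locus
#' sequences, per group. Empty groups give NA, never 0.
#'
#' @param loci locus table; needs `region_label` for region grouping.
#' @param seqs the genome.
#' @param by grouping columns among `"k"` and `"region_label"`; NULL for a
#'   single overall value.
#' @return data.frame of group columns plus `gc_fraction`, or a single
#'   numeric when `by` is NULL.
#' @export
gc_content <- function(loci, seqs, by = NULL) {
  seqs <- .as_genome(seqs)
  if (is.null(by)) return(.gc_of_loci(loci, seqs))
  stopifnot(all(by %in% names(loci)))
  key <- interaction(loci[by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    rows <- which(key == lv)
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    d <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(d) <- by
    d$gc_fraction <- .gc_of_loci(loci[rows, , drop = FALSE], seqs)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Top motif classes by locus count
#'
#' @param summary_by_class output of
#'   `summarize_landscape(..., level = "by_class")`.
#' @param n number of classes to return.
#' @param k_filter optional motif size to restrict to.
#' @return character vector of canonical classes, most abundant first;
#'   count ties break lexicographically.
#' @export
top_motifs <- function(summary_by_class, n, k_filter = NULL) {
  stopifnot(n >= 1)
  d <- summary_by_class
  if (!nrow(d)) return(character(0))
  if (!is.null(k_filter)) d <- d[nchar(d$group) == k_filter, , drop = FALSE]
  d <- d[order(-d$count, d$group), , drop = FALSE]
  utils::head(d$group, n)
}

#' Ranked-density score matrix
#'
#' Per species, motif classes are ranked by density (descending, ties
#' broken lexicographically by canonical motif). Ranks 1-5 score 3, 6-20
#' score 2, 21-35 score 1; remaining classes with density > 1 score 0,
#' those with density in (0, 1] score -1, and classes absent from the
#' genome (density 0) score -2. Zero-density classes never receive a
#' rank-based score, so each row carries at most five 3s, fifteen 2s and
#' fifteen 1s.
#'
#' @param densities numeric matrix or data.frame, species x motif classes;
#'   all 501 canonical classes must be present as columns (absent classes
#'   as explicit zeros).
#' @return integer matrix (species x 501) with values in
#'   \{-2, -1, 0, 1, 2, 3\}, columns in the fixed
#'   [enumerate_motif_classes()] order.
#' @export
rank_score_matrix <- function(densities) {
  classes <- enumerate_motif_classes("all")
  densities <- as.matrix(densities)
  missing <- setdiff(classes, colnames(densities))
  if (length(missing))
    stop("density table is missing ", length(missing),
         " motif class column(s), e.g. ", missing[1],
         "; absent classes must be explicit zeros")
  densities <- densities[, classes, drop = FALSE]
  score_row <- function(d) {
    s <- integer(length(d))
    pos <- which(d > 0)
    ord <- pos[order(-d[pos], classes[pos])]
    s[utils::head(ord, 5L)] <- 3L
    if (length(ord) > 5L) s[ord[6:min(20L, length(ord))]] <- 2L
    if (length(ord) > 20L) s[ord[21:min(35L, length(ord))]] <- 1L
    rest <- if (length(ord) > 35L) ord[-(1:35)] else integer(0)
    s[rest[d[rest] > 1]] <- 0L
    s[rest[d[rest] <= 1]] <- -1L
    s[d == 0] <- -2L
    s
  }
  out <- t(apply(densities, 1L, score_row))
  dimnames(out) <- list(rownames(densities), classes)
  storage.mode(out) <- "integer"
  out
}

#' Pearson correlation with significance test
#'
#' Sample Pearson r with a two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return data.frame with columns `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
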