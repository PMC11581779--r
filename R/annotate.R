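# Assignment of SSR loci to genic regions. A base is CDS if it is CDS in
# any transcript (union semantics); the region classes are queried in the
# priority order CDS > exon > intron, requiring full containment of the
# locus in the class union; loci straddling a boundary are assigned the
# class containing their start position; everything else is intergenic.

#' Build an interval index of genic regions
#'
#' Reduces exon/CDS features (introns derived per transcript when absent)
#' to per-sequence unions for containment queries.
#'
#' @param features data.frame from [read_gff3()] (gene/exon/CDS rows;
#'   intron rows are honored when present, otherwise derived via
#'   [derive_introns()]).
#' @return an object of class `ssr_region_index`.
#' @export
build_region_index <- function(features) {
  if (is.null(features) || !nrow(features)) {
    idx <- list(seqs = character(0), by_class = list(), tx = NULL)
    class(idx) <- "ssr_region_index"
    return(idx)
  }
  if (!any(features$kind == "intron")) {
    intr <- derive_introns(features)
    if (nrow(intr)) features <- rbind(features, intr)
  }
  classes <- c("CDS", "exon", "intron")
  by_class <- list()
  for (cl in classes) {
    f <- features[features$kind == cl, , drop = FALSE]
    by_class[[cl]] <- lapply(split(f, f$seq_id), function(d)
      IRanges::reduce(IRanges::IRanges(d$start, d$end)))
  }
  tx <- features[features$kind %in% classes, c("seq_id", "start", "end",
                                               "kind", "parent_id")]
  idx <- list(seqs = unique(features$seq_id), by_class = by_class, tx = tx)
  class(idx) <- "ssr_region_index"
  idx
}

#' Assign genic-region labels to SSR loci
#'
#' @param loci data.frame of loci with `seq_id`, `start`, `end`.
#' @param index an `ssr_region_index` from [build_region_index()], or a
#'   raw feature data.frame, or NULL (everything intergenic).
#' @return `loci` with added columns `region_label` (CDS/exon/intron/
#'   intergenic) and `transcript_id` (a transcript whose feature of that
#'   class covers the locus start; empty for intergenic).
#' @export
assign_regions <- function(loci, index = NULL) {
  if (!inherits(index, "ssr_region_index")) index <- build_region_index(index)
  n <- nrow(loci)
  loci$region_label <- rep("intergenic", n)
  loci$transcript_id <- rep("", n)
  if (!n || !length(index$seqs)) {
    if (n && length(setdiff(unique(loci$seq_id), index$seqs)) ==
        length(unique(loci$seq_id)) && length(index$seqs) == 0L) {
      # no annotation at all: silently intergenic
    }
    return(loci)
  }
  unknown <- setdiff(unique(loci$seq_id), index$seqs)
  if (length(unknown))
    warning("sequence(s) absent from annotation, loci set intergenic: ",
            paste(unknown, collapse = ", "))
  classes <- c("CDS", "exon", "intron")
  for (id in intersect(unique(loci$seq_id), index$seqs)) {
    rows <- which(loci$seq_id == id)
    q <- IRanges::IRanges(loci$start[rows], loci$end[rows])
    assigned <- rep(NA_character_, length(rows))
    for (cl in classes) {
      ir <- index$by_class[[cl]][[id]]
      if (is.null(ir) || !length(ir)) next
      hit <- IRanges::overlapsAny(q, ir, type = "within")
      assigned[is.na(assigned) & hit] <- cl
    }
    # straddlers: class containing the start position, same priority
    open <- is.na(assigned)
    if (any(open)) {
      qs <- IRanges::IRanges(loci$start[rows][open], width = 1L)
      for (cl in classes) {
        ir <- index$by_class[[cl]][[id]]
        if (is.null(ir) || !length(ir)) next
        hit <- IRanges::overlapsAny(qs, ir)
        sel <- which(open)[is.na(assigned[open]) & hit]
        assigned[sel] <- cl
      }
    }
    assigned[is.na(assigned)] <- "intergenic"
    loci$region_label[rows] <- assigned
    # transcript attribution: first feature of the assigned class
    # covering the locus start
    tx <- index$tx[index$tx$seq_id == id, , drop = FALSE]
    if (nrow(tx)) {
      for (j in seq_along(rows)) {
        if (assigned[j] == "intergenic") next
        cand <- tx[tx$kind == assigned[j] &
                   tx$start <= loci$start[rows[j]] &
                   tx$end >= loci$start[rows[j]], , drop = FALSE]
        if (nrow(cand)) loci$transcript_id[rows[j]] <- cand$parent_id[1]
      }
    }
  }
  loci
}
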