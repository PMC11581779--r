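# FASTA / GFF3 input and the valid-length (non-N) bookkeeping used by all
# normalized statistics. Coordinates are 1-based inclusive throughout,
# matching GFF3.

#' Read a FASTA file of DNA sequences
#'
#' Residues are uppercased and every IUPAC ambiguity code other than
#' A/C/G/T is collapsed to N: downstream repeat statistics consider only
#' unambiguous bases, and N bases are excluded from the valid length used
#' as the normalization denominator.
#'
#' @param path path to a (multi-)FASTA file.
#' @return a named character vector of sequences (names are record IDs, in
#'   file order) of class `ssr_genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA record ID(s): ", paste(unique(dup), collapse = ", "))
  seqs <- normalize_dna(as.character(set))
  names(seqs) <- ids
  class(seqs) <- "ssr_genome"
  seqs
}

#' Normalize DNA strings to the A/C/G/T/N alphabet
#'
#' @param x character vector of raw sequences.
#' @return uppercase sequences with all non-A/C/G/T characters mapped to N.
#' @export
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Sequence lengths excluding unknown bases
#'
#' @param seqs named character vector of normalized sequences.
#' @return integer vector: per-record count of non-N residues.
#' @export
valid_length <- function(seqs) {
  nchar(seqs) - vapply(gregexpr("N", unclass(seqs), fixed = TRUE),
                       function(m) if (m[1] == -1L) 0L else length(m),
                       integer(1))
}

#' Read gene/exon/CDS features from GFF3
#'
#' Keeps `gene`, `mRNA`/`transcript`, `exon` and `CDS` features. Exons and
#' CDS are attached to their transcript via the `Parent` attribute;
#' features lacking one are dropped with a message. Lines that do not have
#' nine tab-separated columns are skipped with a warning. Exons extending
#' beyond their gene span are clamped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `kind` (gene/exon/CDS), `parent_id` (transcript ID for
#'   exon/CDS, empty for gene) and `feature_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    warning(sum(nf != 9L), " malformed GFF3 line(s) skipped")
    body <- body[nf == 9L]
  }
  if (!length(body)) stop("no feature lines in GFF3: ", path)
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3", body), tmp)
  g <- rtracklayer::readGFF(tmp,
    columns = c("seqid", "type", "start", "end"),
    tags = c("ID", "Parent"))
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g$type <- as.character(g$type)
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  keep <- g$type %in% c("gene", "mRNA", "transcript", "exon", "CDS")
  g <- g[keep, , drop = FALSE]

  # map transcript -> gene so exon spans can be checked against gene spans
  tx <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  genes <- g[g$type == "gene", , drop = FALSE]
  sub <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  no_parent <- is.na(sub$Parent)
  if (any(no_parent)) {
    message(sum(no_parent), " exon/CDS feature(s) without Parent skipped")
    sub <- sub[!no_parent, , drop = FALSE]
  }
  gene_of_tx <- stats::setNames(tx$Parent, tx$ID)
  if (nrow(genes) && nrow(sub)) {
    gene_start <- stats::setNames(genes$start, genes$ID)
    gene_end <- stats::setNames(genes$end, genes$ID)
    gid <- gene_of_tx[sub$Parent]
    has <- !is.na(gid) & gid %in% genes$ID
    clip_lo <- has & sub$start < gene_start[gid]
    clip_hi <- has & sub$end > gene_end[gid]
    if (any(clip_lo | clip_hi, na.rm = TRUE)) {
      warning(sum(clip_lo | clip_hi, na.rm = TRUE),
              " exon/CDS feature(s) clamped to their gene span")
      sub$start[which(clip_lo)] <- gene_start[gid[which(clip_lo)]]
      sub$end[which(clip_hi)] <- gene_end[gid[which(clip_hi)]]
    }
  }

  out <- rbind(
    if (nrow(genes)) data.frame(
      seq_id = as.character(genes$seqid), start = genes$start,
      end = genes$end, kind = "gene",
      parent_id = "", feature_id = ifelse(is.na(genes$ID), "", genes$ID),
      stringsAsFactors = FALSE),
    if (nrow(sub)) data.frame(
      seq_id = as.character(sub$seqid), start = sub$start, end = sub$end,
      kind = sub$type, parent_id = sub$Parent,
      feature_id = ifelse(is.na(sub$ID), "", sub$ID),
      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Derive intron intervals from exons
#'
#' For each transcript, introns are the gaps between consecutive sorted
#' exons; single-exon transcripts yield none, and abutting exons yield no
#' zero-length intron.
#'
#' @param features data.frame as returned by [read_gff3()].
#' @return data.frame of intron intervals in the same layout
#'   (`kind == "intron"`).
#' @export
derive_introns <- function(features) {
  ex <- features[features$kind == "exon", , drop = FALSE]
  if (!nrow(ex)) return(features[0, , drop = FALSE])
  out <- lapply(split(ex, ex$parent_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", e$parent_id[1])
    if (nrow(e) < 2L) return(NULL)
    gs <- e$end[-nrow(e)] + 1L
    ge <- e$start[-1] - 1L
    keep <- ge >= gs
    if (!any(keep)) return(NULL)
    data.frame(seq_id = e$seq_id[1], start = gs[keep], end = ge[keep],
               kind = "intron", parent_id = e$parent_id[1],
               feature_id = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(features[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write features to a GFF3 file
#'
#' @param features data.frame in the layout of [read_gff3()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "ssrscape") {
  attr_col <- ifelse(
    nzchar(features$feature_id) & nzchar(features$parent_id),
    paste0("ID=", features$feature_id, ";Parent=", features$parent_id),
    ifelse(nzchar(features$feature_id), paste0("ID=", features$feature_id),
           ifelse(nzchar(features$parent_id),
                  paste0("Parent=", features$parent_id), ".")))
  lines <- paste(features$seq_id, source, features$kind, features$start,
                 features$end, ".", "+", ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
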