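# Canonical motif classes: a repeat unit and all of its cyclic rotations,
# together with the rotations of its reverse complement, name one class.
# The class label is the lexicographically smallest member.

.ssrscape_env <- new.env(parent = emptyenv())

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @examples
#' revcomp_dna("GAT")   # "ATC"
#' @export
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.rotations <- function(s) {
  n <- nchar(s)
  if (n == 1L) return(s)
  vapply(0:(n - 1L), function(i) {
    paste0(substr(s, i + 1L, n), substr(s, 1L, i))
  }, character(1))
}

#' Test whether a motif is primitive
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter unit ("ACAC" is two copies of "AC" and therefore not primitive).
#'
#' @param motif character vector of DNA motifs.
#' @return logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(s) {
    n <- nchar(s)
    if (n <= 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          s == strrep(substr(s, 1L, d), n %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical motif class of a repeat unit
#'
#' Groups repeat units that are cyclic rotations and/or reverse complements
#' of one another into a single class, named by the lexicographically
#' smallest member. "TG", "GT", "CA" and "AC" all map to "AC".
#'
#' @param motif character vector of primitive DNA motifs, 1-6 bp, over
#'   A/C/G/T.
#' @return character vector of canonical class names.
#' @examples
#' canonical_motif("TG")   # "AC"
#' canonical_motif("GAT")  # "ATC"
#' @export
canonical_motif <- function(motif) {
  lut <- .motif_lut()
  out <- unname(lut[motif])
  bad <- is.na(out)
  if (any(bad)) {
    m <- unique(motif[bad])
    if (any(nchar(m) < 1L | nchar(m) > 6L | grepl("[^ACGT]", m)))
      stop("motifs must be 1-6 bp over A/C/G/T: ",
           paste(m, collapse = ", "))
    stop("reducible motif (whole-number repetition of a shorter unit): ",
         paste(m[!is_primitive_motif(m)], collapse = ", "))
  }
  out
}

# lookup table motif -> canonical class over all primitive 1-6-mers
.motif_lut <- function() {
  if (!is.null(.ssrscape_env$motif_lut)) return(.ssrscape_env$motif_lut)
  bases <- c("A", "C", "G", "T")
  lut <- character(0)
  for (k in 1:6) {
    m <- do.call(paste0, expand.grid(rep(list(bases), k),
                                     stringsAsFactors = FALSE))
    m <- m[is_primitive_motif(m)]
    canon <- vapply(m, function(s) {
      min(c(.rotations(s), .rotations(revcomp_dna(s))))
    }, character(1))
    lut[m] <- canon
  }
  .ssrscape_env$motif_lut <- lut
  lut
}

#' Enumerate canonical motif classes
#'
#' All canonical classes of primitive motifs of a given size; motif sizes
#' 1-6 yield 2, 4, 10, 33, 102 and 350 classes, 501 in total.
#'
#' @param k motif size 1-6, or "all" for the union over sizes 1-6.
#' @return character vector of canonical class names, sorted by motif size
#'   then lexicographically (the fixed column order used by
#'   [rank_score_matrix()]).
#' @examples
#' enumerate_motif_classes(2)        # "AC" "AG" "AT" "CG"
#' length(enumerate_motif_classes("all"))  # 501
#' @export
enumerate_motif_classes <- function(k = "all") {
  lut <- .motif_lut()
  classes <- sort(unique(unname(lut)))
  sizes <- nchar(classes)
  classes <- classes[order(sizes, classes)]
  if (identical(k, "all")) return(classes)
  if (!is.numeric(k) || length(k) != 1L || !(k %in% 1:6))
    stop("k must be an integer in 1-6 or \"all\"")
  classes[nchar(classes) == k]
}
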