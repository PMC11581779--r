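# SSR detection: perfect runs by backreference scanning (smallest motif
# size first, with masking so a (AC)n run is not re-reported as (ACAC)n),
# imperfect runs by seed-and-extend alignment against the ideal repeat,
# compound runs by chaining nearby perfect loci.

#' Default minimum repeat-count thresholds
#'
#' Minimum number of complete repeat units for a perfect SSR to be
#' reported, by motif size: 12 for mononucleotides, 7 for dinucleotides
#' and 5 for tri- to hexanucleotides.
#'
#' @return named integer vector indexed by motif size "1".."6".
#' @export
ssr_thresholds <- function() {
  c("1" = 12L, "2" = 7L, "3" = 5L, "4" = 5L, "5" = 5L, "6" = 5L)
}

#' Default imperfect-SSR search parameters
#'
#' Seed-and-extend scoring: +1 match, -1 mismatch, -2 gap; seeds are
#' perfect runs of at least `seed_min_repeats` units; extension stops when
#' the running score falls more than `2 * |gap|` below its maximum or when
#' more than `max_consecutive_edits` consecutive edited positions occur;
#' loci scoring below `min_score` are discarded.
#'
#' @param seed_min_repeats minimum perfect units to seed an extension.
#' @param max_consecutive_edits longest tolerated run of edited positions.
#' @param match,mismatch,gap alignment scores.
#' @param min_score minimum reported alignment score.
#' @return list of parameters.
#' @export
issr_params <- function(seed_min_repeats = 3L, max_consecutive_edits = 2L,
                        match = 1L, mismatch = -1L, gap = -2L,
                        min_score = 10L) {
  if (min_score < 0) stop("min_score must be non-negative")
  if (match <= 0 || mismatch >= 0 || gap >= 0)
    stop("expect match > 0, mismatch < 0, gap < 0")
  list(seed_min_repeats = as.integer(seed_min_repeats),
       max_consecutive_edits = as.integer(max_consecutive_edits),
       match = as.integer(match), mismatch = as.integer(mismatch),
       gap = as.integer(gap), min_score = as.integer(min_score))
}

.empty_perfect <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             type = character(), motif = character(),
             motif_class = character(), k = integer(), repeats = integer(),
             length = integer(), stringsAsFactors = FALSE)
}

# perfect maximal runs in one string; smallest k first with masking
.scan_perfect_one <- function(seq, seq_id, thresholds) {
  masked <- seq
  rows <- list()
  for (k in 1:6) {
    thr <- thresholds[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1+", k)
    m <- gregexpr(pat, masked, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    reps <- len %/% k
    keep <- reps >= thr
    if (!any(keep)) next
    st <- m[keep]; rp <- reps[keep]
    unit <- substr(rep(masked, length(st)), st, st + k - 1L)
    prim <- is_primitive_motif(unit)
    st <- st[prim]; rp <- rp[prim]; unit <- unit[prim]
    if (!length(st)) next
    en <- st + rp * k - 1L
    if (length(st)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = st, end = en, type = "P", motif = unit,
        motif_class = canonical_motif(unit), k = k, repeats = rp,
        length = rp * k, stringsAsFactors = FALSE)
      # mask emitted loci so larger motif sizes do not re-report them
      for (i in seq_along(st))
        substr(masked, st[i], en[i]) <- strrep("N", en[i] - st[i] + 1L)
    }
  }
  if (!length(rows)) return(.empty_perfect())
  out <- do.call(rbind, rows)
  out[order(out$start, out$k), , drop = FALSE]
}

#' Find perfect SSRs
#'
#' Scans each sequence for maximal uninterrupted tandem repeats of
#' primitive 1-6 bp motifs meeting the repeat-count thresholds. Runs never
#' span an N; partial trailing units count toward neither `repeats` nor
#' `length` (so `length == repeats * k` always). Motif sizes are scanned
#' smallest first and emitted loci are masked, so a dinucleotide run is
#' not additionally reported under a non-primitive tetranucleotide unit.
#'
#' @param seqs named character vector of normalized sequences
#'   (see [read_fasta()]), or a single unnamed string.
#' @param thresholds named vector of per-motif-size minimum repeat counts;
#'   default [ssr_thresholds()].
#' @return data.frame with columns `seq_id`, `start`, `end`, `type` ("P"),
#'   `motif` (observed unit, leftmost phase), `motif_class` (canonical),
#'   `k`, `repeats`, `length`; sorted by sequence then start.
#' @export
find_perfect_ssrs <- function(seqs, thresholds = ssr_thresholds()) {
  seqs <- .as_genome(seqs)
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  out <- lapply(names(seqs), function(id)
    .scan_perfect_one(seqs[[id]], id, as.list(thresholds)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.as_genome <- function(seqs) {
  if (inherits(seqs, "ssr_genome")) return(unclass(seqs))
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- if (length(seqs) == 1L) "seq1"
        else paste0("seq", seq_along(seqs))
    return(normalize_dna(seqs))
  }
  stop("seqs must be a named character vector or ssr_genome")
}

# seed-and-extend for one seed; returns best extent and edit count
.extend_issr <- function(chars, seed_start, seed_end, motif, params) {
  k <- nchar(motif)
  mot <- strsplit(motif, "")[[1]]
  n <- length(chars)
  stop_drop <- 2L * abs(params$gap)

  walk <- function(dir) {
    # dir +1: rightward from seed_end; dir -1: leftward from seed_start
    score <- 0L; best <- 0L
    best_pos <- if (dir > 0L) seed_end else seed_start
    best_edits <- 0L; edits <- 0L; consec <- 0L
    i <- if (dir > 0L) seed_end + 1L else seed_start - 1L
    phase <- if (dir > 0L) 0L else k - 1L  # 0-based index into motif
    repeat {
      if (i < 1L || i > n) break
      ch <- chars[i]
      if (ch == "N") break
      exp_ch <- mot[phase + 1L]
      if (ch == exp_ch) {
        score <- score + params$match
        consec <- 0L
        i <- i + dir
        phase <- (phase + dir) %% k
      } else {
        nxt <- if (dir > 0L) i + 1L else i - 1L
        nxt_phase <- (phase + dir) %% k
        nxt_ch <- if (nxt >= 1L && nxt <= n) chars[nxt] else ""
        if (nxt_ch == mot[nxt_phase + 1L]) {
          # substitution: consume base and phase
          score <- score + params$mismatch
          edits <- edits + 1L; consec <- consec + 1L
          i <- i + dir
          phase <- nxt_phase
        } else if (nxt_ch == exp_ch) {
          # insertion in the sequence: consume base, keep phase
          score <- score + params$gap
          edits <- edits + 1L; consec <- consec + 1L
          i <- i + dir
        } else if (ch == mot[nxt_phase + 1L]) {
          # deletion from the ideal repeat: keep base, advance phase
          score <- score + params$gap
          edits <- edits + 1L; consec <- consec + 1L
          phase <- nxt_phase
        } else {
          score <- score + params$mismatch
          edits <- edits + 1L; consec <- consec + 1L
          i <- i + dir
          phase <- nxt_phase
        }
      }
      if (consec > params$max_consecutive_edits) break
      if (score < best - stop_drop) break
      if (score > best) {
        best <- score
        best_pos <- i - dir  # last consumed position
        best_edits <- edits
      }
    }
    list(score = best, pos = best_pos, edits = best_edits)
  }

  r <- walk(1L)
  l <- walk(-1L)
  seed_score <- (seed_end - seed_start + 1L) * params$match
  list(start = l$pos, end = r$pos,
       score = seed_score + l$score + r$score,
       edits = l$edits + r$edits)
}

#' Find imperfect SSRs
#'
#' Seed-and-extend search: every perfect run of at least
#' `params$seed_min_repeats` units seeds a bidirectional unit-wise
#' extension scored against the ideal repeat (+1 match, -1 mismatch,
#' -2 indel by default); the reported locus is the score-maximal extent.
#' Loci with no edits are perfect and are not reported here; overlapping
#' imperfect loci of the same motif class are resolved to the
#' higher-scoring one.
#'
#' @inheritParams find_perfect_ssrs
#' @param params list from [issr_params()].
#' @return data.frame with the columns of [find_perfect_ssrs()] (type
#'   "I") plus `edits` and `score`.
#' @export
find_imperfect_ssrs <- function(seqs, params = issr_params()) {
  seqs <- .as_genome(seqs)
  thr_seed <- stats::setNames(rep(params$seed_min_repeats, 6L),
                              as.character(1:6))
  out <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    seeds <- .scan_perfect_one(s, id, as.list(thr_seed))
    if (!nrow(seeds)) return(NULL)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    res <- lapply(seq_len(nrow(seeds)), function(i) {
      ext <- .extend_issr(chars, seeds$start[i], seeds$end[i],
                          seeds$motif[i], params)
      if (ext$edits == 0L || ext$score < params$min_score) return(NULL)
      data.frame(seq_id = id, start = ext$start, end = ext$end,
                 type = "I", motif = seeds$motif[i],
                 motif_class = seeds$motif_class[i], k = seeds$k[i],
                 repeats = (ext$end - ext$start + 1L) %/% seeds$k[i],
                 length = ext$end - ext$start + 1L,
                 edits = ext$edits, score = ext$score,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || !nrow(res)) return(NULL)
    # same-class overlaps: keep the higher-scoring locus
    res <- res[order(-res$score, res$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(res))
    for (cl in unique(res$motif_class)) {
      idx <- which(res$motif_class == cl)
      taken_s <- integer(0); taken_e <- integer(0)
      for (j in idx) {
        if (any(res$start[j] <= taken_e & res$end[j] >= taken_s)) {
          keep[j] <- FALSE
        } else {
          taken_s <- c(taken_s, res$start[j])
          taken_e <- c(taken_e, res$end[j])
        }
      }
    }
    res <- res[keep, , drop = FALSE]
    res[order(res$start), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(.empty_perfect(),
                 data.frame(edits = integer(), score = integer()))
  }
  rownames(out) <- NULL
  out
}

#' Find compound SSRs
#'
#' Chains perfect loci on the same sequence whose inter-locus gaps are at
#' most `d_max` bp into maximal compound loci of two or more components.
#'
#' @param loci data.frame of perfect loci from [find_perfect_ssrs()],
#'   sorted by `seq_id` then `start` (an error otherwise).
#' @param d_max maximum gap, in bp, between consecutive components.
#' @return data.frame with columns `seq_id`, `start`, `end`, `type` ("C"),
#'   `motif` (component classes joined by "+"), `motif_class` (idem),
#'   `k` (NA), `repeats` (number of components), `length`, plus a list
#'   column `component_rows` holding the row indices of `loci` making up
#'   each compound.
#' @export
find_compound_ssrs <- function(loci, d_max = 10L) {
  if (!nrow(loci)) {
    out <- .empty_perfect()
    out$component_rows <- list()
    return(out)
  }
  for (id in unique(loci$seq_id)) {
    st <- loci$start[loci$seq_id == id]
    if (is.unsorted(st)) stop("loci must be sorted by start within ", id)
  }
  out <- lapply(split(seq_len(nrow(loci)), loci$seq_id), function(idx) {
    st <- loci$start[idx]; en <- loci$end[idx]
    if (length(idx) < 2L) return(NULL)
    gap <- st[-1] - en[-length(en)] - 1L
    brk <- c(0L, which(gap > d_max), length(idx))
    chains <- list()
    for (b in seq_len(length(brk) - 1L)) {
      members <- idx[(brk[b] + 1L):brk[b + 1L]]
      if (length(members) < 2L) next
      lab <- paste(loci$motif_class[members], collapse = "+")
      chains[[length(chains) + 1L]] <- data.frame(
        seq_id = loci$seq_id[members[1]], start = loci$start[members[1]],
        end = loci$end[members[length(members)]], type = "C",
        motif = lab, motif_class = lab, k = NA_integer_,
        repeats = length(members),
        length = loci$end[members[length(members)]] -
          loci$start[members[1]] + 1L,
        stringsAsFactors = FALSE)
      chains[[length(chains)]]$component_rows <- list(members)
    }
    if (length(chains)) do.call(rbind, chains) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- .empty_perfect()
    out$component_rows <- list()
    return(out)
  }
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Detect all SSR types in a genome
#'
#' Convenience wrapper running perfect, imperfect and compound detection
#' and returning a single table in a fixed column order. Perfect loci that
#' are members of a compound chain are flagged in `compound_member`;
#' whether they are kept in perfect-only statistics is a downstream choice
#' (they are counted by default).
#'
#' @inheritParams find_perfect_ssrs
#' @param params imperfect-search parameters, [issr_params()].
#' @param d_max compound chaining distance, bp.
#' @param types subset of c("P","I","C") to report.
#' @return data.frame with columns `seq_id`, `start`, `end`, `type`,
#'   `motif`, `motif_class`, `k`, `repeats`, `length`, `edits`, `score`,
#'   `compound_member`.
#' @export
detect_ssrs <- function(seqs, thresholds = ssr_thresholds(),
                        params = issr_params(), d_max = 10L,
                        types = c("P", "I", "C")) {
  seqs <- .as_genome(seqs)
  p <- find_perfect_ssrs(seqs, thresholds)
  p$edits <- 0L; p$score <- p$length
  p$compound_member <- FALSE
  comp <- find_compound_ssrs(p[, 1:9], d_max)
  if (nrow(comp)) {
    members <- unlist(comp$component_rows)
    p$compound_member[members] <- TRUE
  }
  out <- if ("P" %in% types) p else p[0, , drop = FALSE]
  if ("I" %in% types) {
    i <- find_imperfect_ssrs(seqs, params)
    if (nrow(i)) {
      i$compound_member <- FALSE
      out <- rbind(out, i[, names(out)])
    }
  }
  if ("C" %in% types && nrow(comp)) {
    comp$edits <- NA_integer_; comp$score <- NA_integer_
    comp$compound_member <- FALSE
    out <- rbind(out, comp[, names(out)])
  }
  out <- out[order(out$seq_id, out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
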