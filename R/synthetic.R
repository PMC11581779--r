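# Synthetic test data: genomes with planted perfect/imperfect/compound
# repeats, gene structure placing loci in chosen genic regions, optional
# N-runs, and continuous traits simulated under single- or multi-rate
# Brownian motion on random time trees. Planted-locus recovery is made
# exact by construction: spacers are rejection-sampled to be repeat-free,
# guard bases prevent runs from extending or phase-shifting into the
# flanks, and the assembled genome is verified against the detector (and
# rebuilt if necessary).

#' Specify loci to plant in a synthetic genome
#'
#' @param motif repeat unit (primitive, 1-6 bp).
#' @param repeats total number of repeat units.
#' @param type "P" (perfect), "I" (imperfect) or "C" (compound).
#' @param edits for type I: number of single-base insertions interrupting
#'   the run (the run is split into `edits + 1` perfect blocks, each of
#'   which must stay below the perfect-detection threshold).
#' @param gap for type C: bp between the two perfect components.
#' @param region target genic region: CDS, exon, intron or intergenic.
#' @return data.frame of plant specifications (rows can be rbind-ed).
#' @export
plant_spec <- function(motif, repeats, type = "P", edits = 1L, gap = 5L,
                       region = "intergenic") {
  stopifnot(type %in% c("P", "I", "C"),
            region %in% c("CDS", "exon", "intron", "intergenic"))
  data.frame(motif = toupper(motif), repeats = as.integer(repeats),
             type = type, edits = as.integer(edits), gap = as.integer(gap),
             region = region, stringsAsFactors = FALSE)
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# repeat-free spacer under the detection thresholds
.spacer <- function(n, gc, thresholds) {
  repeat {
    s <- .random_dna(n, gc)
    if (!nrow(.scan_perfect_one(s, "sp", as.list(thresholds)))) return(s)
  }
}

.other_base <- function(avoid) {
  setdiff(c("A", "C", "G", "T"), avoid)[1]
}

# build the literal sequence of one planted locus; returns the string and
# the truth rows relative to a start offset of 1
.plant_seq <- function(spec, thresholds) {
  k <- nchar(spec$motif)
  first <- substr(spec$motif, 1, 1)
  last <- substr(spec$motif, k, k)
  if (spec$type == "P") {
    s <- strrep(spec$motif, spec$repeats)
    truth <- data.frame(rel_start = 1L, rel_end = nchar(s), type = "P",
                        motif = spec$motif,
                        motif_class = canonical_motif(spec$motif),
                        k = k, repeats = spec$repeats,
                        stringsAsFactors = FALSE)
  } else if (spec$type == "I") {
    nb <- spec$edits + 1L
    per <- diff(round(seq(0, spec$repeats, length.out = nb + 1L)))
    thr <- thresholds[[as.character(k)]]
    if (any(per >= thr) || any(per < 3L))
      stop("imperfect plant blocks must have 3 <= repeats < ", thr,
           " (motif ", spec$motif, ": blocks ",
           paste(per, collapse = "/"), ")")
    ins <- .other_base(c(first, last))
    s <- paste(vapply(per, function(r) strrep(spec$motif, r), character(1)),
               collapse = ins)
    truth <- data.frame(rel_start = 1L, rel_end = nchar(s), type = "I",
                        motif = spec$motif,
                        motif_class = canonical_motif(spec$motif),
                        k = k, repeats = spec$repeats,
                        stringsAsFactors = FALSE)
  } else {
    # compound: the motif plus a different class of the same size
    cls <- enumerate_motif_classes(k)
    mate <- setdiff(cls, canonical_motif(spec$motif))[1]
    blk1 <- strrep(spec$motif, spec$repeats)
    blk2 <- strrep(mate, spec$repeats)
    gseq <- if (spec$gap > 0) {
      g <- character(spec$gap)
      # break periodicity at both junctions: the first gap base must not
      # continue blk1 rightward (!= motif first base), the last must not
      # let blk2 extend leftward (!= mate last base)
      g[1] <- if (spec$gap == 1L)
        .other_base(c(first, substr(mate, k, k))) else
        .other_base(c(first, last))
      if (spec$gap > 2)
        for (i in 2:(spec$gap - 1)) g[i] <- .other_base(g[i - 1])
      if (spec$gap > 1)
        g[spec$gap] <- .other_base(c(substr(mate, k, k),
                                     g[spec$gap - 1]))
      paste(g, collapse = "")
    } else ""
    s <- paste0(blk1, gseq, blk2)
    truth <- rbind(
      data.frame(rel_start = 1L, rel_end = nchar(blk1), type = "P",
                 motif = spec$motif,
                 motif_class = canonical_motif(spec$motif), k = k,
                 repeats = spec$repeats, stringsAsFactors = FALSE),
      data.frame(rel_start = nchar(blk1) + spec$gap + 1L,
                 rel_end = nchar(s), type = "P", motif = mate,
                 motif_class = mate, k = k, repeats = spec$repeats,
                 stringsAsFactors = FALSE),
      data.frame(rel_start = 1L, rel_end = nchar(s), type = "C",
                 motif = paste(canonical_motif(spec$motif), mate, sep = "+"),
                 motif_class = paste(canonical_motif(spec$motif), mate,
                                     sep = "+"),
                 k = NA_integer_, repeats = 2L, stringsAsFactors = FALSE))
  }
  list(seq = s, truth = truth)
}

.assemble_genome <- function(plants, thresholds, spacer_len, gc, seq_id) {
  pieces <- character(0)
  cursor <- 0L
  truth <- NULL
  anchors <- integer(nrow(plants))
  for (i in seq_len(nrow(plants))) {
    sp <- .spacer(spacer_len, gc, thresholds)
    ps <- .plant_seq(plants[i, ], thresholds)
    mot <- plants$motif[i]
    k <- nchar(mot)
    # guard bases: left flank must not extend/phase-shift the run, nor may
    # the right flank
    substr(sp, spacer_len, spacer_len) <-
      .other_base(c(substr(mot, k, k), substr(sp, spacer_len - 1L,
                                              spacer_len - 1L)))
    pieces <- c(pieces, sp)
    cursor <- cursor + spacer_len
    t <- ps$truth
    t$seq_id <- seq_id
    t$start <- cursor + t$rel_start
    t$end <- cursor + t$rel_end
    t$region <- plants$region[i]
    t$plant <- i
    anchors[i] <- cursor + 1L
    truth <- rbind(truth, t[, c("seq_id", "start", "end", "type", "motif",
                                "motif_class", "k", "repeats", "region",
                                "plant")])
    pieces <- c(pieces, ps$seq)
    cursor <- cursor + nchar(ps$seq)
  }
  pieces <- c(pieces, .spacer(spacer_len, gc, thresholds))
  # right guards: the first spacer base after each locus must not extend
  # the terminal repeat block (base k positions back == motif first base)
  seq <- paste(pieces, collapse = "")
  for (i in seq_len(nrow(plants))) {
    rows <- which(truth$plant == i & truth$type == "P" |
                  truth$plant == i & truth$type == "I")
    locus_end <- max(truth$end[truth$plant == i])
    last_mot <- truth$motif[rows][which.max(truth$end[rows])]
    g <- .other_base(c(substr(last_mot, 1, 1),
                       substr(seq, locus_end + 2L, locus_end + 2L)))
    substr(seq, locus_end + 1L, locus_end + 1L) <- g
  }
  list(seq = seq, truth = truth)
}

#' Generate a synthetic genome with planted SSRs
#'
#' Builds a single-sequence genome in which the requested loci are
#' embedded in repeat-free spacer sequence, emits a gene annotation that
#' realizes each locus's target genic region, optionally inserts N-runs
#' into spacers (never overlapping planted loci), and returns the exact
#' coordinates of everything planted. The assembled sequence is verified
#' against [find_perfect_ssrs()]: the set of detected perfect loci equals
#' the planted perfect loci (including compound components) exactly.
#'
#' @param plants data.frame from [plant_spec()] rows.
#' @param seed integer seed (reproducible: same seed, same genome).
#' @param genome_length optional total length; the tail spacer is grown
#'   to reach it (error if smaller than the required layout).
#' @param n_run_rate expected number of N-runs per bp (each run 30 bp).
#' @param gc_background background GC fraction.
#' @param spacer_len spacer length between consecutive planted loci.
#' @param thresholds detection thresholds the genome is validated
#'   against.
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `genes.gff3` and `truth.tsv` there.
#' @return list with `seqs` (named character, class ssr_genome),
#'   `features` (gene annotation data.frame), `truth` (planted-locus
#'   table with exact coordinates).
#' @export
generate_genome <- function(plants, seed, genome_length = NULL,
                            n_run_rate = 0, gc_background = 0.4,
                            spacer_len = 100L,
                            thresholds = ssr_thresholds(), dir = NULL) {
  stopifnot(spacer_len >= 50L)
  set.seed(seed)
  seq_id <- "chr1"
  if (nrow(plants) == 0L) {
    len <- if (is.null(genome_length)) 1000L else genome_length
    seqs <- stats::setNames(.spacer(len, gc_background, thresholds), seq_id)
    class(seqs) <- "ssr_genome"
    truth <- data.frame(seq_id = character(), start = integer(),
                        end = integer(), type = character(),
                        motif = character(), motif_class = character(),
                        k = integer(), repeats = integer(),
                        region = character(), stringsAsFactors = FALSE)
    return(list(seqs = seqs, features = read_gff3_empty(), truth = truth))
  }
  for (attempt in 1:20) {
    asm <- .assemble_genome(plants, thresholds, spacer_len,
                            gc_background, seq_id)
    det <- find_perfect_ssrs(stats::setNames(asm$seq, seq_id), thresholds)
    want <- asm$truth[asm$truth$type == "P", , drop = FALSE]
    ok <- nrow(det) == nrow(want) &&
      all(det$start == want$start & det$end == want$end &
          det$motif_class == want$motif_class)
    if (ok) break
  }
  if (!ok) stop("could not assemble a genome with exact recovery")
  seq <- asm$seq
  truth <- asm$truth

  if (!is.null(genome_length)) {
    if (genome_length < nchar(seq))
      stop("genome_length ", genome_length, " smaller than required ",
           nchar(seq))
    extra <- genome_length - nchar(seq)
    if (extra > 0)
      seq <- paste0(seq, .spacer(extra, gc_background, thresholds))
  }

  # gene structure realizing each target region
  pad <- 20L
  feats <- NULL
  gi <- 0L
  for (i in unique(truth$plant)) {
    region <- truth$region[truth$plant == i][1]
    if (region == "intergenic") next
    gi <- gi + 1L
    ls <- min(truth$start[truth$plant == i])
    le <- max(truth$end[truth$plant == i])
    gs <- ls - pad; ge <- le + pad
    gid <- sprintf("gene%02d", gi); tid <- sprintf("mRNA%02d", gi)
    base <- data.frame(seq_id = seq_id, start = c(gs, gs),
                       end = c(ge, ge), kind = c("gene", "mRNA"),
                       parent_id = c("", gid), feature_id = c(gid, tid),
                       stringsAsFactors = FALSE)
    sub <- switch(region,
      CDS = data.frame(seq_id = seq_id, start = c(gs, gs), end = c(ge, ge),
                       kind = c("exon", "CDS"), parent_id = tid,
                       feature_id = "", stringsAsFactors = FALSE),
      exon = data.frame(seq_id = seq_id, start = c(gs, le + 10L),
                        end = c(ge, ge), kind = c("exon", "CDS"),
                        parent_id = tid, feature_id = "",
                        stringsAsFactors = FALSE),
      intron = data.frame(seq_id = seq_id,
                          start = c(gs, le + 5L, gs),
                          end = c(ls - 5L, ge, ls - 5L),
                          kind = c("exon", "exon", "CDS"),
                          parent_id = tid, feature_id = "",
                          stringsAsFactors = FALSE))
    feats <- rbind(feats, base, sub)
  }
  if (is.null(feats)) feats <- read_gff3_empty()

  # N-runs in spacer interiors, never touching planted loci or gene pads
  if (n_run_rate > 0) {
    n_runs <- stats::rpois(1, n_run_rate * nchar(seq))
    if (n_runs > 0) {
      gaps <- .free_spacer_windows(truth, nchar(seq), spacer_len, pad)
      if (nrow(gaps)) {
        pick <- gaps[sample(nrow(gaps), min(n_runs, nrow(gaps))), ,
                     drop = FALSE]
        for (j in seq_len(nrow(pick))) {
          w <- min(30L, pick$end[j] - pick$start[j] + 1L)
          substr(seq, pick$start[j], pick$start[j] + w - 1L) <- strrep("N", w)
        }
      }
    }
  }

  seqs <- stats::setNames(seq, seq_id)
  class(seqs) <- "ssr_genome"
  truth$plant <- NULL
  out <- list(seqs = seqs, features = feats, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(seqs, file.path(dir, "genome.fa"))
    if (nrow(feats)) write_gff3(feats, file.path(dir, "genes.gff3"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

read_gff3_empty <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             kind = character(), parent_id = character(),
             feature_id = character(), stringsAsFactors = FALSE)
}

# mid-spacer windows clear of loci and gene pads
.free_spacer_windows <- function(truth, total_len, spacer_len, pad) {
  bounds <- sort(c(1L, truth$start, truth$end, total_len))
  locus_iv <- unique(truth[truth$type != "C", c("start", "end")])
  locus_iv <- locus_iv[order(locus_iv$start), , drop = FALSE]
  starts <- c(1L, locus_iv$end + 1L)
  ends <- c(locus_iv$start - 1L, total_len)
  w <- data.frame(start = starts + pad + 5L, end = ends - pad - 5L)
  w[w$end - w$start + 1L >= 30L, , drop = FALSE]
}

#' Generate a tree with a planted rate shift and simulated traits
#'
#' Random coalescent tree rescaled to unit depth; one internal clade of
#' roughly `shift_clade_fraction` of the tips carries branch rates
#' `sigma2_base * rate_ratio` (stem branch included); tip traits are
#' simulated under Brownian motion with those branch rates.
#'
#' @param n_tips number of tips.
#' @param shift_clade_fraction target fraction of tips inside the shifted
#'   clade.
#' @param rate_ratio rate multiplier for the shifted clade, >= 1.
#' @param seed integer seed.
#' @param sigma2_base background rate.
#' @param root_state trait value at the root.
#' @return list with `tree` (phylo), `traits` (data.frame species/value),
#'   `truth` (list: `clade_tips`, `rate_ratio`, `sigma2_edge`).
#' @export
generate_rate_shift_tree <- function(n_tips, shift_clade_fraction = 0.25,
                                     rate_ratio = 1, seed = 1,
                                     sigma2_base = 1, root_state = 0) {
  if (rate_ratio < 1) stop("rate_ratio must be >= 1")
  set.seed(seed)
  tree <- ape::rcoal(n_tips)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  n <- n_tips
  # tip counts below each node
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    pa <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[chd]])
  }
  sizes <- lengths(desc)
  target <- shift_clade_fraction * n
  cand <- which(seq_along(sizes) > n & sizes >= 2L & sizes < n)
  if (!length(cand)) stop("no internal clade with at least 2 tips")
  node <- cand[which.min(abs(sizes[cand] - target))]
  if (sizes[node] < 2L) stop("shift clade smaller than 2 tips")
  clade_tips <- tree$tip.label[desc[[node]]]
  in_clade <- vapply(seq_len(nrow(tree$edge)), function(e)
    tree$edge[e, 2] == node || all(desc[[tree$edge[e, 2]]] %in% desc[[node]]),
    logical(1))
  sigma2_edge <- rep(sigma2_base, nrow(tree$edge))
  sigma2_edge[in_clade] <- sigma2_base * rate_ratio
  traits <- simulate_bm(tree, sigma2_edge, root_state)
  list(tree = tree,
       traits = data.frame(species = names(traits), value = unname(traits),
                           stringsAsFactors = FALSE),
       truth = list(clade_tips = clade_tips, rate_ratio = rate_ratio,
                    sigma2_edge = sigma2_edge))
}
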