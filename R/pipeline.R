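# Orchestration: one call from FASTA/GFF3 to an annotated detection
# table, and one call from per-species summaries plus a tree to the
# comparative outputs (score matrix, genome-size correlations, rate
# fits). Every output directory receives a manifest recording the full
# configuration so a rerun reproduces byte-identical tables.

#' Pipeline configuration
#'
#' All tunables in one list: detection thresholds, imperfect-search
#' parameters, compound chaining distance, score-matrix metric, penalty
#' weight for the multirate fit, enrichment p cutoff, and whether perfect
#' loci that are members of compound chains count in perfect-only
#' statistics (they do by default).
#'
#' @param thresholds per-motif-size minimum repeat counts.
#' @param issr imperfect-search parameters ([issr_params()]).
#' @param d_max compound chaining distance, bp.
#' @param density_metric "rel_density" (bp/Mbp) or "rel_abundance"
#'   (loci/Mbp) for the ranked score matrix.
#' @param lambda multirate penalty weight.
#' @param p_cutoff raw-p cutoff for reported enrichment rows.
#' @param count_compound_members logical.
#' @return named list of class `ssr_config`.
#' @export
ssr_config <- function(thresholds = ssr_thresholds(),
                       issr = issr_params(), d_max = 10L,
                       density_metric = c("rel_density", "rel_abundance"),
                       lambda = 1, p_cutoff = 0.05,
                       count_compound_members = TRUE) {
  structure(list(thresholds = thresholds, issr = issr, d_max = d_max,
                 density_metric = match.arg(density_metric),
                 lambda = lambda, p_cutoff = p_cutoff,
                 count_compound_members = count_compound_members),
            class = "ssr_config")
}

.write_manifest <- function(dir, config, inputs) {
  manifest <- list(package = "ssrscape",
                   version = as.character(utils::packageVersion("ssrscape")),
                   inputs = inputs,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.write_tsv <- function(d, path) {
  d <- d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect and annotate SSRs in one genome
#'
#' @param fasta path to the genome FASTA.
#' @param gff optional path to a GFF3 annotation; when missing, all loci
#'   are intergenic (with a warning).
#' @param out_dir optional output directory for `detection.tsv` and
#'   `manifest.json`.
#' @param config an [ssr_config()].
#' @return the annotated detection table (invisibly when `out_dir` is
#'   given).
#' @export
run_detect <- function(fasta, gff = NULL, out_dir = NULL,
                       config = ssr_config()) {
  seqs <- read_fasta(fasta)
  loci <- detect_ssrs(seqs, thresholds = config$thresholds,
                      params = config$issr, d_max = config$d_max)
  if (is.null(gff)) {
    warning("no annotation provided: all loci labeled intergenic")
    index <- build_region_index(NULL)
  } else {
    index <- build_region_index(read_gff3(gff))
  }
  loci <- assign_regions(loci, index)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(loci, file.path(out_dir, "detection.tsv"))
    .write_manifest(out_dir, config,
                    list(fasta = fasta, gff = if (is.null(gff)) "" else gff))
    return(invisible(loci))
  }
  loci
}

#' Compare SSR landscapes across species
#'
#' Takes per-species summary attributes and per-species class densities,
#' emits the ranked-density score matrix, Pearson correlations of each
#' attribute with genome size, and single- plus multirate Brownian-motion
#' fits of total repeat abundance on the supplied time tree.
#'
#' @param species_summary data.frame with one row per species: columns
#'   `species`, `genome_size`, and attribute columns to correlate with
#'   genome size (e.g. `count`, `total_length`, `rel_abundance`,
#'   `rel_density`).
#' @param class_density numeric matrix, species x canonical motif class
#'   (all 501 columns; absent classes as zeros).
#' @param tree rooted time tree (`phylo`) whose tip labels are the
#'   species names; NULL skips the rate fits.
#' @param out_dir optional output directory (`score_matrix.tsv`,
#'   `correlations.json`, `rate_fit.json`, `manifest.json`).
#' @param config an [ssr_config()].
#' @return list with `score_matrix`, `correlations` (data.frame),
#'   `single_rate`, `multirate` (NULL without a tree).
#' @export
run_compare <- function(species_summary, class_density, tree = NULL,
                        out_dir = NULL, config = ssr_config()) {
  stopifnot(is.data.frame(species_summary),
            "species" %in% names(species_summary),
            "genome_size" %in% names(species_summary))
  score <- rank_score_matrix(class_density)

  attrs <- setdiff(names(species_summary)[vapply(species_summary,
                                                 is.numeric, logical(1))],
                   "genome_size")
  correlations <- do.call(rbind, lapply(attrs, function(a) {
    r <- pearson_cor(species_summary$genome_size, species_summary[[a]])
    cbind(data.frame(pair = paste0(a, "~genome_size"),
                     stringsAsFactors = FALSE), r)
  }))

  single <- multi <- NULL
  if (!is.null(tree)) {
    missing_tips <- setdiff(tree$tip.label, species_summary$species)
    extra <- setdiff(species_summary$species, tree$tip.label)
    if (length(missing_tips) || length(extra))
      stop("species/tree mismatch; missing from summary: ",
           paste(missing_tips, collapse = ", "),
           "; absent from tree: ", paste(extra, collapse = ", "))
    trait_col <- if ("rel_abundance" %in% names(species_summary))
      "rel_abundance" else attrs[1]
    trait <- stats::setNames(species_summary[[trait_col]],
                             species_summary$species)
    single <- fit_single_rate(tree, trait)
    multi <- fit_multirate(tree, trait, lambda = config$lambda)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sm <- data.frame(species = rownames(score), score,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(sm, file.path(out_dir, "score_matrix.tsv"))
    jsonlite::write_json(correlations,
                         file.path(out_dir, "correlations.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    if (!is.null(multi))
      jsonlite::write_json(
        list(lambda = multi$lambda,
             loglik = multi$loglik, objective = multi$objective,
             root_state = multi$root_state,
             log_rates = unclass(multi$log_rates),
             sigma2_edge = multi$sigma2_edge,
             single_rate_sigma2 = single$sigma2,
             single_rate_loglik = single$loglik),
        file.path(out_dir, "rate_fit.json"), auto_unbox = TRUE,
        digits = NA)
    .write_manifest(out_dir, config, list())
  }
  list(score_matrix = score, correlations = correlations,
       single_rate = single, multirate = multi)
}
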