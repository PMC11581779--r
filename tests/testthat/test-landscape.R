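toy_genome <- function(len = 2e6, n_tail = 0) {
  s <- paste0(strrep("ACGT", len / 4), strrep("N", n_tail))
  structure(c(chr1 = s), class = "ssr_genome")
}

toy_loci <- function(n, len_each = 100L) {
  st <- as.integer(seq(1, by = 200, length.out = n))
  data.frame(seq_id = rep("chr1", n), start = st,
             end = st + len_each - 1L,
             type = rep("P", n), motif = rep("AC", n),
             motif_class = rep("AC", n), k = rep(2L, n),
             repeats = rep(len_each %/% 2L, n),
             length = rep(len_each, n), stringsAsFactors = FALSE)
}

test_that("relative abundance and density normalize by valid length", {
  g <- toy_genome(2e6)
  s <- summarize_landscape(toy_loci(500), g)
  expect_equal(s$rel_abundance, 250)
  s2 <- summarize_landscape(toy_loci(500, 100L), g)
  expect_equal(s2$rel_density, 25000)
  expect_equal(s2$total_length, 50000L)
  expect_equal(s2$pct_genome, 100 * 50000 / 2e6)
})

test_that("N bases count toward pct_genome but not toward valid length", {
  g <- toy_genome(1e6, n_tail = 1e6)
  s <- summarize_landscape(toy_loci(100), g)
  expect_equal(s$rel_abundance, 100)            # per Mbp valid
  expect_equal(s$pct_genome, 100 * 100 * 100 / 2e6)
  expect_error(summarize_landscape(toy_loci(1),
                                   structure(c(c1 = "NNNN"),
                                             class = "ssr_genome")),
               "valid")
})

test_that("an empty locus set summarizes to zeros", {
  s <- summarize_landscape(toy_loci(0), toy_genome())
  expect_identical(s$count, 0L)
  expect_equal(s$rel_abundance, 0)
  expect_equal(s$pct_genome, 0)
})

test_that("group counts sum to the total across grouping levels", {
  plants <- rbind(plant_spec("AC", 7, region = "CDS"),
                  plant_spec("A", 12, region = "intron"),
                  plant_spec("GAT", 6, region = "exon"),
                  plant_spec("AAAT", 5), plant_spec("AT", 9))
  g <- generate_genome(plants, seed = 31)
  loci <- assign_regions(find_perfect_ssrs(g$seqs), g$features)
  loci$type <- "P"
  total <- summarize_landscape(loci, g$seqs)$count
  for (lvl in c("by_k", "by_class", "by_region")) {
    s <- summarize_landscape(loci, g$seqs, level = lvl)
    expect_identical(sum(s$count), total)
    expect_equal(sum(s$rel_abundance),
                 summarize_landscape(loci, g$seqs)$rel_abundance)
  }
})

test_that("normalized statistics are invariant under genome duplication", {
  plants <- rbind(plant_spec("AC", 7), plant_spec("A", 12))
  g <- generate_genome(plants, seed = 41)
  one <- summarize_landscape(find_perfect_ssrs(g$seqs), g$seqs)
  dup <- c(g$seqs[[1]], g$seqs[[1]])
  names(dup) <- c("c1", "c2")
  loci2 <- find_perfect_ssrs(dup)
  two <- summarize_landscape(loci2, dup)
  expect_equal(two$rel_abundance, one$rel_abundance)
  expect_equal(two$rel_density, one$rel_density)
  expect_equal(two$pct_genome, one$pct_genome)
})

test_that("GC content is computed over extracted locus sequence", {
  g <- structure(c(chr1 = "ACACACAAAATTTTTTTTTTTT"), class = "ssr_genome")
  loci <- data.frame(seq_id = "chr1", start = c(1L, 7L), end = c(6L, 10L))
  expect_equal(gc_content(loci, g), 3 / 10)
  expect_equal(gc_content(data.frame(seq_id = "chr1", start = 1L,
                                     end = 6L), g), 0.5)
  cc <- structure(c(chr1 = strrep("C", 12)), class = "ssr_genome")
  expect_equal(gc_content(data.frame(seq_id = "chr1", start = 1L,
                                     end = 12L), cc), 1.0)
  at <- structure(c(chr1 = strrep("AT", 7)), class = "ssr_genome")
  expect_equal(gc_content(data.frame(seq_id = "chr1", start = 1L,
                                     end = 14L), at), 0.0)
})

test_that("GC of an empty group is missing, not zero", {
  g <- toy_genome(400)
  expect_true(is.na(gc_content(toy_loci(0), g)))
  loci <- toy_loci(2)
  loci$region_label <- c("CDS", "CDS")
  by_r <- gc_content(loci, g, by = "region_label")
  expect_identical(nrow(by_r), 1L)
})

test_that("top_motifs ranks by count with lexicographic ties", {
  s <- data.frame(species = "x", group = c("A", "AC", "AAT"),
                  count = c(10L, 8L, 8L), stringsAsFactors = FALSE)
  expect_identical(top_motifs(s, 2), c("A", "AAT"))
  expect_identical(top_motifs(s, 10), c("A", "AAT", "AC"))
  expect_identical(top_motifs(s[0, ], 3), character(0))
  expect_identical(top_motifs(s, 1, k_filter = 2), "AC")
})

test_that("rank scores follow the 3/2/1/0/-1/-2 binning", {
  classes <- enumerate_motif_classes("all")
  d <- matrix(0, 1, 501, dimnames = list("sp", classes))
  d[1, 1:40] <- seq(400, 10, length.out = 40)   # ranks 1-40, all > 1
  d[1, 41:60] <- 0.5                            # in (0, 1]
  m <- rank_score_matrix(d)
  expect_identical(unname(m[1, 1:5]), rep(3L, 5))
  expect_identical(unname(m[1, 6:20]), rep(2L, 15))
  expect_identical(unname(m[1, 21:35]), rep(1L, 15))
  expect_identical(unname(m[1, 36:40]), rep(0L, 5))
  expect_identical(unname(m[1, 41:60]), rep(-1L, 20))
  expect_identical(unname(m[1, 61:501]), rep(-2L, 441))
})

test_that("density ties at the rank-5 boundary break lexicographically", {
  classes <- enumerate_motif_classes("all")
  d <- matrix(0, 1, 501, dimnames = list("sp", classes))
  d[1, 1:10] <- 100   # ten-way tie across ranks 1-10
  m <- rank_score_matrix(d)
  expect_identical(sum(m == 3L), 5L)
  # lexicographically smallest five of the tied class names win
  expect_identical(sort(colnames(m)[m[1, ] == 3L]),
                   sort(sort(classes[1:10])[1:5]))
})

test_that("score rows obey caps and the 6-value alphabet on random tables", {
  classes <- enumerate_motif_classes("all")
  set.seed(13)
  d <- matrix(stats::rexp(5 * 501) * sample(c(0, 0.5, 40), 5 * 501,
                                            replace = TRUE),
              5, 501, dimnames = list(paste0("sp", 1:5), classes))
  m <- rank_score_matrix(d)
  expect_true(all(m %in% c(-2L, -1L, 0L, 1L, 2L, 3L)))
  expect_true(all(rowSums(m == 3L) <= 5))
  expect_true(all(rowSums(m == 2L) <= 15))
  expect_true(all(rowSums(m == 1L) <= 15))
  expect_identical(unname(rowSums(m == -2L)), unname(rowSums(d == 0)))
})

test_that("missing class columns are an error", {
  d <- matrix(1, 1, 5,
              dimnames = list("sp", enumerate_motif_classes(2)[1:4] |>
                                c("A")))
  expect_error(rank_score_matrix(d), "missing")
})

test_that("pearson_cor matches the sum-formula and t-test closed forms", {
  expect_equal(pearson_cor(1:3, c(6, 4, 2))$r, -1)
  p <- pearson_cor(1:4, c(2, 1, 4, 3))
  expect_equal(p$r, 0.6)
  y <- 2 * (1:10) + 1
  pp <- pearson_cor(1:10, y)
  expect_equal(pp$r, 1)
  expect_lt(pp$p, 1e-12)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x))
    n <- length(x)
    r_ref <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_ref <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
    p_ref <- 2 * stats::pt(-abs(t_ref), n - 2)
    got <- pearson_cor(x, y)
    expect_equal(got$r, r_ref, tolerance = 1e-12)
    expect_equal(got$p, p_ref, tolerance = 1e-12)
  }
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})
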