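test_that("two-tip and star-tree likelihoods match closed forms", {
  tr <- make_two_tip_tree()
  expect_equal(bm_loglik(tr, c(a = 0, b = 0), 1, 0),
               2 * dnorm(0, 0, 1, log = TRUE))
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  x <- setNames(c(-1, 0.5, 2, 0, 1, -2), star$tip.label)
  expect_equal(bm_loglik(star, x, 1.5, 0.2),
               sum(dnorm(x, 0.2, sqrt(1.5), log = TRUE)))
})

test_that("likelihood equals the explicit multivariate-normal density", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(4:10, 1)
    tr <- ape::rcoal(n)
    s2 <- stats::rexp(nrow(tr$edge)) + 0.1
    x <- simulate_bm(tr, s2, root_state = 1)
    expect_equal(bm_loglik(tr, x, s2, 1),
                 oracle_bm_loglik(tr, x, s2, 1), tolerance = 1e-8)
  }
})

test_that("missing tips are reported by name", {
  tr <- make_two_tip_tree()
  expect_error(bm_loglik(tr, c(a = 0), 1, 0), "b")
  expect_error(fit_single_rate(tr, c(a = 0)), "b")
})

test_that("single-rate closed forms: REML two-taxon and degenerate data", {
  tr <- make_two_tip_tree()
  f <- fit_single_rate(tr, c(a = 0, b = 2), method = "REML")
  expect_equal(f$sigma2, 2)
  expect_equal(fit_single_rate(tr, c(a = 0, b = 2))$sigma2, 1)
  expect_warning(f0 <- fit_single_rate(tr, c(a = 1, b = 1)), "zero")
  expect_equal(f0$sigma2, 0)
})

test_that("single-rate estimation recovers the simulating rate", {
  set.seed(29)
  tr <- ape::rcoal(200)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  est <- vapply(1:100, function(i)
    fit_single_rate(tr, simulate_bm(tr, 1, 0, seed = 1000 + i))$sigma2,
    numeric(1))
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("fits are invariant to tip-order permutation of the trait table", {
  set.seed(31)
  tr <- ape::rcoal(12)
  x <- simulate_bm(tr, 1, 0)
  shuffled <- x[sample(length(x))]
  expect_equal(fit_single_rate(tr, x)$sigma2,
               fit_single_rate(tr, shuffled)$sigma2)
  f1 <- fit_multirate(tr, x, lambda = 1)
  f2 <- fit_multirate(tr, shuffled, lambda = 1)
  expect_equal(f1$log_rates, f2$log_rates, tolerance = 1e-6)
})

test_that("simulation is seed-deterministic with variance sigma2 x time", {
  tr <- ape::rcoal(16)
  expect_identical(simulate_bm(tr, 1, 0, seed = 4),
                   simulate_bm(tr, 1, 0, seed = 4))
  expect_false(identical(simulate_bm(tr, 1, 0, seed = 4),
                         simulate_bm(tr, 1, 0, seed = 5)))
  star <- ape::stree(4, "star")
  star$edge.length <- rep(2, 4)
  expect_identical(unname(simulate_bm(star, 0, 3)), rep(3, 4))
  set.seed(6)
  tips <- replicate(1000, simulate_bm(star, 1.2, 0)[1])
  expect_lt(abs(var(tips) - 2.4) / 2.4, 0.1)
})

test_that("multirate fit collapses to a single rate when data warrant", {
  set.seed(37)
  tr <- ape::rcoal(24)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  x <- simulate_bm(tr, 1, 0)
  single <- fit_single_rate(tr, x)
  fit <- fit_multirate(tr, x, lambda = 1)
  expect_lt(mean(fit$sigma2_edge) / single$sigma2, 2)
  expect_gt(mean(fit$sigma2_edge) / single$sigma2, 0.5)
  # heavy penalty: per-node rates collapse to a common value and the
  # trait term approaches the single-rate maximum likelihood
  hv <- suppressWarnings(fit_multirate(tr, x, lambda = 1e6))
  expect_lt(diff(range(hv$log_rates)), 1e-3)
  expect_equal(hv$loglik, single$loglik, tolerance = 1e-4)
})

test_that("the penalized objective never ends below its starting point", {
  set.seed(41)
  tr <- ape::rcoal(16)
  x <- simulate_bm(tr, 2, 0)
  single <- fit_single_rate(tr, x)
  lam <- 1
  pa <- tr$edge[, 1]; ch <- tr$edge[, 2]
  start_pen <- sum(dnorm(0, 0, sqrt(tr$edge.length), log = TRUE))
  fit <- fit_multirate(tr, x, lambda = lam)
  expect_gte(fit$objective, single$loglik + lam * start_pen - 1e-6)
})

test_that("a planted 10x clade rate shift is recovered in direction", {
  g <- generate_rate_shift_tree(48, shift_clade_fraction = 0.3,
                                rate_ratio = 10, seed = 5)
  trait <- setNames(g$traits$value, g$traits$species)
  fit <- fit_multirate(g$tree, trait, lambda = 1)
  cs <- clade_rate_summary(fit, list(
    shifted = g$truth$clade_tips,
    background = setdiff(g$tree$tip.label, g$truth$clade_tips)))
  expect_gt(cs$mean_sigma2[cs$clade == "shifted"],
            cs$mean_sigma2[cs$clade == "background"])
})

test_that("multirate fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  g <- generate_rate_shift_tree(16, shift_clade_fraction = 0.3,
                                rate_ratio = 10, seed = 5)
  trait <- setNames(g$traits$value, g$traits$species)
  ours <- fit_multirate(g$tree, trait, lambda = 1)
  ref <- suppressWarnings(phytools::multirateBM(g$tree, trait,
                                                lambda = 1))
  tips <- g$tree$tip.label
  ours_tip <- setNames(ours$log_rates[seq_along(tips)], tips)
  expect_gt(cor(ours_tip[tips], log(ref$sig2[tips])), 0.8)
  inn <- g$truth$clade_tips
  out <- setdiff(tips, inn)
  expect_gt(mean(ours_tip[inn]), mean(ours_tip[out]))
  expect_gt(mean(log(ref$sig2[inn])), mean(log(ref$sig2[out])))
})

test_that("clade summaries degenerate correctly", {
  set.seed(43)
  tr <- ape::rcoal(8)
  x <- simulate_bm(tr, 1, 0)
  single <- fit_single_rate(tr, x)
  cs <- clade_rate_summary(single, list(all = tr$tip.label,
                                        one = tr$tip.label[1]))
  expect_equal(cs$mean_sigma2, rep(single$sigma2, 2))
  expect_equal(cs$sd_sigma2, c(0, 0))
  expect_identical(cs$n_edges[cs$clade == "one"], 1L)
  expect_error(clade_rate_summary(single, list(bad = "nope")), "nope")
})

test_that("rate-shift generator is seed-stable and validates inputs", {
  a <- generate_rate_shift_tree(16, rate_ratio = 4, seed = 9)
  b <- generate_rate_shift_tree(16, rate_ratio = 4, seed = 9)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  expect_error(generate_rate_shift_tree(16, rate_ratio = 0.5, seed = 1),
               ">= 1")
  flat <- generate_rate_shift_tree(16, rate_ratio = 1, seed = 2)
  expect_true(all(flat$truth$sigma2_edge == flat$truth$sigma2_edge[1]))
})
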