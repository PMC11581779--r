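# Independent reference implementations used to cross-check the package:
# an O(n^2) periodicity scanner for perfect repeats and an explicit
# multivariate-normal Brownian-motion density built on ape::vcv.

# Perfect-repeat oracle: direct left-to-right periodicity scanning, one
# motif size at a time (smallest first), consuming each >=2-unit run and
# masking reported loci -- no regular expressions involved.
oracle_perfect <- function(seq, thresholds = ssr_thresholds()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- NULL
  for (k in 1:6) {
    thr <- thresholds[[as.character(k)]]
    i <- 1L
    while (i + 2L * k - 1L <= n) {
      unit <- chars[i:(i + k - 1L)]
      if (any(unit == "N")) { i <- i + 1L; next }
      r <- 1L
      while (i + (r + 1L) * k - 1L <= n &&
             all(chars[(i + r * k):(i + (r + 1L) * k - 1L)] == unit))
        r <- r + 1L
      if (r >= 2L) {
        u <- paste(unit, collapse = "")
        if (r >= thr && is_primitive_motif(u)) {
          out <- rbind(out, data.frame(
            start = i, end = i + r * k - 1L, motif = u,
            motif_class = canonical_motif(u), k = k, repeats = r,
            stringsAsFactors = FALSE))
          chars[i:(i + r * k - 1L)] <- "N"
        }
        i <- i + r * k
      } else {
        i <- i + 1L
      }
    }
  }
  if (is.null(out)) return(out)
  out[order(out$start, out$k), , drop = FALSE]
}

# Brownian-motion log-likelihood via the explicit tip covariance matrix:
# scale branch lengths by their rates, take ape::vcv, and evaluate the
# multivariate normal density directly.
oracle_bm_loglik <- function(tree, trait, sigma2, root_state) {
  tr <- tree
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, nrow(tr$edge))
  tr$edge.length <- tr$edge.length * sigma2
  C <- ape::vcv(tr)
  x <- trait[rownames(C)] - root_state
  n <- length(x)
  as.numeric(-0.5 * (n * log(2 * pi) +
                     determinant(C, logarithm = TRUE)$modulus +
                     t(x) %*% solve(C) %*% x))
}

# random sequences with embedded repeat runs, for oracle-equivalence
# fuzzing (chance repeats allowed -- both sides see the same sequence)
random_repeatish_seq <- function(len, n_runs = 3L) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, len, replace = TRUE)
  for (j in seq_len(n_runs)) {
    k <- sample(1:4, 1)
    unit <- sample(bases, k, replace = TRUE)
    reps <- sample(3:14, 1)
    run <- rep(unit, reps)
    pos <- sample(max(1, len - length(run)), 1)
    s[pos:(pos + length(run) - 1L)] <- run
  }
  paste(utils::head(s, len), collapse = "")
}

make_two_tip_tree <- function(t1 = 1, t2 = 1) {
  ape::read.tree(text = sprintf("(a:%g,b:%g);", t1, t2))
}
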