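# Brownian-motion models of continuous-trait (repeat abundance) evolution
# on a rooted, fully bifurcating or multifurcating time tree with positive
# branch lengths. The multirate model places a log-rate at every node and
# tip, sets each branch rate to exp of the mean of its two incident node
# log-rates, and maximizes the trait log-likelihood plus lambda times the
# log-density of the node log-rates under unit-rate Brownian motion on the
# same tree.

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be > 0")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  tree
}

.check_trait <- function(tree, trait) {
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait values missing for tip(s): ", paste(miss, collapse = ", "))
  trait[tree$tip.label]
}

# n_tips x n_edges incidence: A[i, e] = 1 if edge e lies on the root->tip
# path of tip i; then vcv(tree with edge weights w) = A diag(w) A'.
.path_incidence <- function(tree) {
  n <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  root <- n + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(ne)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  A <- matrix(0, n, ne)
  for (i in seq_len(n)) {
    node <- i
    while (node != root) {
      A[i, parent_edge[node]] <- 1
      node <- parent[node]
    }
  }
  A
}

#' Brownian-motion log-likelihood of tip data
#'
#' Multivariate-normal log-likelihood in which the covariance of two tips
#' is the shared root-to-tip path length, each branch scaled by its rate.
#'
#' @param tree rooted `phylo` tree with positive branch lengths.
#' @param trait named numeric vector of tip values (names = tip labels).
#' @param sigma2 branch rate(s): a single positive value, or one per edge
#'   in `tree$edge` order.
#' @param root_state trait value at the root.
#' @return log-likelihood (numeric scalar).
#' @export
bm_loglik <- function(tree, trait, sigma2, root_state) {
  tree <- .check_tree(tree)
  x <- .check_trait(tree, trait)
  ne <- nrow(tree$edge)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, ne)
  if (length(sigma2) != ne) stop("sigma2 must be scalar or one per edge")
  if (any(sigma2 < 0)) stop("rates must be non-negative")
  A <- .path_incidence(tree)
  C <- A %*% (tree$edge.length * sigma2 * t(A))
  .mvn_loglik(x, rep(root_state, length(x)), C)
}

.mvn_loglik <- function(x, mu, C) {
  R <- chol(C)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

#' Fit a single-rate Brownian-motion model
#'
#' Closed-form generalized-least-squares estimates of the rate and the
#' root state.
#'
#' @inheritParams bm_loglik
#' @param method `"ML"` (divide the quadratic form by n) or `"REML"`
#'   (divide by n - 1).
#' @return object of class `ssr_ratefit`: list with `sigma2` (scalar),
#'   `sigma2_edge` (per edge, all equal), `root_state`, `loglik`,
#'   `lambda` (NA), `model = "single"`.
#' @export
fit_single_rate <- function(tree, trait, method = c("ML", "REML")) {
  method <- match.arg(method)
  tree <- .check_tree(tree)
  x <- .check_trait(tree, trait)
  n <- length(x)
  if (n < 2) stop("need at least 2 tips")
  A <- .path_incidence(tree)
  C <- A %*% (tree$edge.length * t(A))
  Cinv_x <- solve(C, x)
  Cinv_1 <- solve(C, rep(1, n))
  a <- sum(Cinv_x) / sum(Cinv_1)
  q <- sum((x - a) * solve(C, x - a))
  s2 <- q / if (method == "ML") n else n - 1
  if (s2 <= .Machine$double.eps) {
    warning("zero trait variance: sigma2 = 0 boundary fit")
    s2 <- 0
    ll <- Inf
  } else {
    ll <- .mvn_loglik(x, rep(a, n), s2 * C)
  }
  structure(list(sigma2 = s2,
                 sigma2_edge = rep(s2, nrow(tree$edge)),
                 log_rates = stats::setNames(
                   rep(if (s2 > 0) log(s2) else -Inf, max(tree$edge)),
                   seq_len(max(tree$edge))),
                 root_state = a, loglik = ll, lambda = NA_real_,
                 model = "single", method = method,
                 tree = tree),
            class = "ssr_ratefit")
}

#' Fit the multirate Brownian-motion model by penalized likelihood
#'
#' Every node and tip carries a log-rate; the rate of a branch is the
#' exponential of the mean of its two incident node log-rates. The
#' objective is the trait log-likelihood (root state profiled
#' analytically) plus `lambda` times the log-density of the node
#' log-rates under unit-rate Brownian motion on the tree; it is maximized
#' by quasi-Newton iteration starting from the single-rate fit. Large
#' `lambda` collapses the rates to a common value.
#'
#' @inheritParams bm_loglik
#' @param lambda penalty weight, >= 0; default 1.
#' @param max_iter iteration cap for the optimizer.
#' @param tol relative convergence tolerance on the objective.
#' @return object of class `ssr_ratefit`: `sigma2_edge` (per edge rates in
#'   `tree$edge` order), `log_rates` (per node, ape node numbering),
#'   `root_state`, `loglik` (trait term), `penalty`, `objective`,
#'   `lambda`, `convergence`.
#' @export
fit_multirate <- function(tree, trait, lambda = 1, max_iter = 500L,
                          tol = 1e-8) {
  if (lambda < 0) stop("lambda must be >= 0")
  tree <- .check_tree(tree)
  x <- .check_trait(tree, trait)
  n <- length(x)
  A <- .path_incidence(tree)
  el <- tree$edge.length
  pa <- tree$edge[, 1]; ch <- tree$edge[, 2]
  nnode <- max(tree$edge)
  ones <- rep(1, n)

  profile_ll <- function(w) {
    C <- A %*% (w * t(A))
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) return(list(ll = -Inf, a = NA_real_))
    zx <- backsolve(R, x, transpose = TRUE)
    z1 <- backsolve(R, ones, transpose = TRUE)
    a <- sum(zx * z1) / sum(z1 * z1)
    q <- sum((zx - a * z1)^2)
    list(ll = -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + q), a = a)
  }
  penalty_fn <- function(lr) {
    d <- lr[ch] - lr[pa]
    sum(stats::dnorm(d, 0, sqrt(el), log = TRUE))
  }
  objective <- function(lr) {
    w <- el * exp((lr[pa] + lr[ch]) / 2)
    p <- profile_ll(w)
    val <- p$ll + lambda * penalty_fn(lr)
    if (!is.finite(val)) return(1e10)
    -val
  }

  start_fit <- fit_single_rate(tree, trait)
  s2 <- max(start_fit$sigma2, 1e-12)
  lr0 <- rep(log(s2), nnode)
  opt <- stats::nlminb(lr0, objective,
                       control = list(iter.max = max_iter,
                                      eval.max = 20L * max_iter,
                                      rel.tol = tol))
  if (opt$convergence != 0 && !opt$message %in%
        c("relative convergence (4)", "both X-convergence and relative convergence (5)",
          "X-convergence (3)"))
    warning("optimizer stopped without clean convergence: ", opt$message,
            " (objective ", format(-opt$objective), ")")
  lr <- opt$par
  w <- el * exp((lr[pa] + lr[ch]) / 2)
  p <- profile_ll(w)
  structure(list(sigma2 = exp(mean(lr)),
                 sigma2_edge = exp((lr[pa] + lr[ch]) / 2),
                 log_rates = stats::setNames(lr, seq_len(nnode)),
                 root_state = p$a, loglik = p$ll,
                 penalty = penalty_fn(lr),
                 objective = -opt$objective, lambda = lambda,
                 convergence = opt$convergence, model = "multirate",
                 tree = tree),
            class = "ssr_ratefit")
}

#' @export
print.ssr_ratefit <- function(x, ...) {
  cat("Brownian-motion rate fit (", x$model, ")\n", sep = "")
  if (x$model == "single") {
    cat("  sigma2     :", format(x$sigma2), "\n")
  } else {
    cat("  sigma2 span:", format(min(x$sigma2_edge)), "-",
        format(max(x$sigma2_edge)), "\n")
    cat("  lambda     :", x$lambda, "\n")
  }
  cat("  root state :", format(x$root_state), "\n")
  cat("  loglik     :", format(x$loglik), "\n")
  invisible(x)
}

#' Simulate Brownian-motion evolution on a tree
#'
#' Recursive normal increments with variance rate x branch length.
#'
#' @inheritParams bm_loglik
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, root_state = 0, seed = NULL) {
  tree <- .check_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  ne <- nrow(tree$edge)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, ne)
  stopifnot(length(sigma2) == ne)
  n <- length(tree$tip.label)
  states <- numeric(max(tree$edge))
  states[n + 1L] <- root_state
  ord <- rev(ape::postorder(tree))  # parents before children
  for (e in ord) {
    states[tree$edge[e, 2]] <- states[tree$edge[e, 1]] +
      stats::rnorm(1, 0, sqrt(sigma2[e] * tree$edge.length[e]))
  }
  stats::setNames(states[seq_len(n)], tree$tip.label)
}

#' Per-clade summary of fitted branch rates
#'
#' Mean and standard deviation of the fitted per-branch rates over the
#' branches whose descendant tips lie entirely within each clade
#' (pendant branches included).
#'
#' @param fit an `ssr_ratefit` (must carry its tree).
#' @param clades named list of tip-label character vectors.
#' @return data.frame with columns `clade`, `mean_sigma2`, `sd_sigma2`,
#'   `n_edges`.
#' @export
clade_rate_summary <- function(fit, clades) {
  tree <- fit$tree
  unknown <- setdiff(unlist(clades), tree$tip.label)
  if (length(unknown))
    stop("unknown tip name(s): ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  # descendant tip sets per node via postorder accumulation
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    pa <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    desc[[pa]] <- c(desc[[pa]], desc[[chd]])
  }
  out <- lapply(names(clades), function(nm) {
    tips <- clades[[nm]]
    inside <- vapply(seq_len(nrow(tree$edge)), function(e)
      all(desc[[tree$edge[e, 2]]] %in% tips), logical(1))
    r <- fit$sigma2_edge[inside]
    data.frame(clade = nm, mean_sigma2 = mean(r),
               sd_sigma2 = if (length(r) > 1L) stats::sd(r) else 0,
               n_edges = length(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
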