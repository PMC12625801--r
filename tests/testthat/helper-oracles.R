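# Independent oracles, deliberately written without the code paths they check.

# Shared-path covariance by explicit root-to-tip edge traversal of tree$edge.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  elen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  path_nodes <- function(tip) {
    out <- integer(0)
    v <- tip
    while (v != root) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(n), path_nodes)
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n) {
    M[i, j] <- M[j, i] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  }
  M
}

oracle_tip_depths <- function(tree) diag(oracle_vcv(tree))

# GLS by the explicit matrix formulas (direct inverse, no whitening).
oracle_gls <- function(X, y, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  e <- y - X %*% b
  rss <- drop(t(e) %*% Vi %*% e)
  n <- length(y)
  p <- ncol(X)
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) +
                  determinant(V, logarithm = TRUE)$modulus + n)
  list(beta = drop(b), sigma2 = rss / (n - p), loglik = as.numeric(ll),
       cov_beta = rss / (n - p) * solve(XtVi %*% X))
}

# Profile-likelihood grid search over lambda.
oracle_lambda_grid <- function(X, y, C, grid = seq(0, 1, length.out = 1001)) {
  ll <- vapply(grid, function(lam) {
    V <- lam * C
    diag(V) <- diag(C)
    oracle_gls(X, y, V)$loglik
  }, numeric(1))
  grid[which.max(ll)]
}

# small deterministic trait table on a given tree for fitting tests
make_traits <- function(tree, seed = 1, lambda = 0.6, sigma = 0.35,
                        slope = 1.26, intercept = 3.48) {
  simulate_traits(tree, sim_config(
    n_extant = length(tree$tip.label), lambda_true = lambda, sigma = sigma,
    slope = slope, intercept = intercept, seed = seed))
}

extdata <- function(f) system.file("extdata", f, package = "phylomass")
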