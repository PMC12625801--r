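test_that("gls_fit with identity covariance reproduces exact OLS on a noiseless line", {
  x <- 1:6
  X <- cbind(1, x)
  y <- 2 * x + 1
  f <- gls_fit(X, y, diag(6))
  expect_equal(unname(f$beta), c(1, 2), tolerance = 1e-12)
  expect_lt(f$sigma2, 1e-20)
})

test_that("gls_fit matches the direct-inverse oracle on random PD covariances", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) + diag(n)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    f <- gls_fit(X, y, V)
    o <- oracle_gls(X, y, V)
    expect_equal(f$beta, o$beta, tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-8)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
    expect_equal(unname(f$cov_beta), unname(o$cov_beta), tolerance = 1e-8)
  }
})

test_that("gls_fit rejects rank-deficient designs and non-PD covariances", {
  X <- cbind(1, 1:5, 1:5)
  expect_error(gls_fit(X, rnorm(5), diag(5)), "rank deficient")
  V <- diag(5); V[1, 2] <- V[2, 1] <- 2      # not PD
  expect_error(gls_fit(cbind(1, 1:5), rnorm(5), V), "positive definite")
})

test_that("profile_lambda_ml ties a 1001-point grid search", {
  for (i in 1:20) {
    tr <- simulate_tree(20, seed = 900 + i)
    cfg <- sim_config(n_extant = 20, lambda_true = runif(1), seed = 900 + i)
    tt <- simulate_traits(tr, cfg)
    X <- cbind(1, log(tt$fcsa_mm2))
    y <- log(tt$bm_kg * 1000)
    cov <- vcv_from_tree(tr, tt$species)
    opt <- profile_lambda_ml(X, y, cov)
    grid_best <- oracle_lambda_grid(X, y, cov$C)
    expect_lt(abs(opt$lambda - grid_best), 1e-3)
  }
})

test_that("lambda is unidentifiable on a star tree and flagged flat", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  set.seed(2)
  X <- cbind(1, rnorm(12))
  y <- rnorm(12)
  prof <- profile_lambda_ml(X, y, vcv_from_tree(star))
  expect_true(prof$flat)
  expect_equal(prof$lambda, 0)
})

test_that("lambda = 1 data on a large tree is recovered near the boundary", {
  tree <- simulate_tree(200, seed = 77)
  cfg <- sim_config(n_extant = 200, lambda_true = 1, seed = 0)
  hits <- 0L
  for (r in 1:100) {
    tt <- simulate_traits(tree, cfg, seed = 7000 + r)
    f <- fit_model(tt, tree, "fcsa")
    if (f$lambda >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("PGLS with lambda fixed at 0 equals OLS on logged data", {
  tree <- simulate_tree(40, seed = 21)
  tt <- make_traits(tree, seed = 21)
  f <- fit_model(tt, tree, "fcsa", lambda = 0)
  ols <- lm(log(bm_kg * 1000) ~ log(fcsa_mm2), data = tt)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  # adjusted R^2 reduces to the classical OLS value when V is proportional to I
  expect_equal(f$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-8)
})

test_that("PGLS with lambda fixed at 1 matches the independent-contrasts slope", {
  tree <- simulate_tree(40, seed = 22)
  tt <- make_traits(tree, seed = 22, lambda = 1)
  f <- fit_model(tt, tree, "fcsa", lambda = 1)
  px <- ape::pic(setNames(log(tt$fcsa_mm2), tt$species), tree)
  py <- ape::pic(setNames(log(tt$bm_kg * 1000), tt$species), tree)
  pic_slope <- unname(coef(lm(py ~ px - 1)))
  expect_equal(unname(f$coefficients[2]), pic_slope, tolerance = 1e-6)
})

test_that("branch-length rescaling leaves beta and lambda invariant", {
  tree <- simulate_tree(30, seed = 23)
  tt <- make_traits(tree, seed = 23)
  f1 <- fit_model(tt, tree, "fcsa")
  tree3 <- tree
  tree3$edge.length <- tree3$edge.length * 3
  f3 <- fit_model(tt, tree3, "fcsa")
  expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-6)
  expect_equal(f1$lambda, f3$lambda, tolerance = 1e-4)
  expect_equal(f3$sigma2 * 3, f1$sigma2, tolerance = 1e-4)
})

test_that("profile maximum dominates the lambda endpoints", {
  tree <- simulate_tree(40, seed = 24)
  tt <- make_traits(tree, seed = 24)
  X <- cbind(1, log(tt$fcsa_mm2))
  y <- log(tt$bm_kg * 1000)
  cov <- vcv_from_tree(tree, tt$species)
  prof <- profile_lambda_ml(X, y, cov)
  ll_at <- function(lam) gls_fit(X, y, lambda_transform(cov, lam)$V)$loglik
  expect_gte(prof$loglik + 1e-6, ll_at(0))
  expect_gte(prof$loglik + 1e-6, ll_at(1))
})

test_that("fit_model agrees with nlme::gls under a fixed Pagel correlation", {
  skip_if_not_installed("nlme")
  tree <- simulate_tree(35, seed = 25)
  tt <- make_traits(tree, seed = 25)
  f <- fit_model(tt, tree, "fcsa", lambda = 0.64)
  d <- data.frame(y = log(tt$bm_kg * 1000), x = log(tt$fcsa_mm2),
                  species = tt$species)
  g <- nlme::gls(y ~ x, data = d, method = "ML",
                 correlation = ape::corPagel(0.64, tree, form = ~species,
                                             fixed = TRUE))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
  # and the ML lambda estimate agrees when both optimize
  fml <- fit_model(tt, tree, "fcsa")
  gml <- nlme::gls(y ~ x, data = d, method = "ML",
                   correlation = ape::corPagel(0.5, tree, form = ~species))
  expect_equal(fml$lambda, unname(coef(gml$modelStruct$corStruct)),
               tolerance = 2e-3)
})

test_that("whitened-OLS implementation equals direct GLS formulas on tree covariances", {
  set.seed(31)
  for (i in 1:10) {
    tr <- simulate_tree(sample(8:25, 1), seed = 300 + i)
    tt <- make_traits(tr, seed = 300 + i)
    V <- lambda_transform(vcv_from_tree(tr, tt$species), runif(1))$V
    X <- cbind(1, log(tt$fcsa_mm2))
    y <- log(tt$bm_kg * 1000)
    f <- gls_fit(X, y, V)
    o <- oracle_gls(X, y, V)
    expect_equal(f$beta, o$beta, tolerance = 1e-8)
  }
})

test_that("model comparison ranks by AIC with a parsimony tie-break", {
  fake_fit <- function(model, aic, k) {
    structure(list(model = model, aic = aic, k = k, loglik = -(aic - 2 * k) / 2,
                   taxa = letters[1:5], y = 1:5), class = "pgls_fit")
  }
  fits <- list(m1 = fake_fit("fcsa", 18, 4), m2 = fake_fit("fl", 56, 4),
               m3 = fake_fit("fcsa+fl", 20, 5))
  cmp <- compare_models(fits)
  expect_equal(cmp$table$model, c("m1", "m3", "m2"))
  expect_equal(cmp$best, 1L)
  expect_equal(cmp$table$delta_aic, c(0, 2, 38))
  # exact AIC tie: fewer parameters wins
  tie <- compare_models(list(a = fake_fit("fcsa+fl", 10, 5),
                             b = fake_fit("fcsa", 10, 4)))
  expect_equal(tie$best, 2L)
  # single fit: trivial ranking
  single <- compare_models(list(only = fake_fit("fcsa", 18, 4)))
  expect_equal(single$best, 1L)
  expect_equal(single$table$rank, 1L)
  # mismatched taxa rejected
  other <- fake_fit("fl", 12, 4)
  other$taxa <- letters[2:6]
  expect_error(compare_models(list(fits$m1, other)), "taxon set")
})

test_that("fit_model validates inputs", {
  tree <- simulate_tree(10, seed = 1)
  tt <- make_traits(tree, seed = 1)
  tt2 <- tt
  tt2$species[1] <- "not_a_tip"
  expect_error(fit_model(tt2, tree, "fcsa"), "not in tree")
  tt3 <- tt
  tt3$bm_kg[2] <- -1
  expect_error(fit_model(tt3, tree, "fcsa"), "non-positive")
  expect_error(fit_model(tt, tree, "bogus"), "unknown model")
  # formula-style names are accepted
  f <- fit_model(tt, tree, "BM ~ FCSA", lambda = 0.5)
  expect_equal(f$model, "fcsa")
})
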