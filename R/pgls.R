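#' Generalized least squares with a known covariance matrix
#'
#' Solves the GLS normal equations by Cholesky whitening: with `V = R'R`,
#' the model is refit as ordinary least squares on `R'^{-1} X`, `R'^{-1} y`.
#' The log-likelihood is the multivariate-normal likelihood with the
#' residual variance concentrated out at its ML value (denominator `n`);
#' the reported `sigma2` uses the unbiased `n - p` denominator for
#' inference.
#'
#' @param X Design matrix (`n x p`), including the intercept column.
#' @param y Response vector, aligned row-wise with `X` and `V`.
#' @param V Symmetric positive-definite covariance matrix (`n x n`).
#' @return List with `beta`, `sigma2` (n-p denominator), `sigma2_ml`,
#'   `loglik`, `cov_beta`, `rss` (whitened residual sum of squares),
#'   `residuals` (raw scale), `fitted`, `n`, `p`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  V <- as.matrix(V)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || any(dim(V) != n))
    stop("X, y and V must have aligned dimensions")
  if (n <= p) stop("need more observations than coefficients (n = ", n,
                   ", p = ", p, ")")
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite: ", conditionMessage(e)))
  wX <- backsolve(R, X, transpose = TRUE)
  wy <- backsolve(R, y, transpose = TRUE)
  qx <- qr(wX)
  if (qx$rank < p)
    stop("design matrix is rank deficient (rank ", qx$rank, " < ", p, ")")
  beta <- qr.coef(qx, wy)
  wres <- wy - wX %*% beta
  rss <- sum(wres^2)
  sigma2_ml <- rss / n
  sigma2 <- rss / (n - p)
  logdetV <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetV + n)
  XtVX_inv <- chol2inv(qr.R(qx))
  # undo qr column pivoting if any
  piv <- qx$pivot
  XtVX_inv <- XtVX_inv[order(piv), order(piv), drop = FALSE]
  cov_beta <- sigma2 * XtVX_inv
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta)
  list(beta = drop(beta), sigma2 = sigma2, sigma2_ml = sigma2_ml,
       loglik = loglik, cov_beta = cov_beta, rss = rss,
       residuals = y - fitted, fitted = fitted, n = n, p = p)
}

#' Profile maximum-likelihood estimation of Pagel's lambda
#'
#' Maximizes the GLS profile log-likelihood (coefficients and residual
#' variance concentrated out) over `lambda` in `[0, 1]` by bounded scalar
#' optimization, bracketed by a coarse grid so boundary optima are not
#' missed. On a star-tree covariance the profile is flat in `lambda`; by
#' convention `lambda = 0` is returned with `flat = TRUE`.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param cov `phylo_vcv` structure (or bare `C` matrix).
#' @param tol Optimizer tolerance on lambda.
#' @param grid_n Size of the bracketing/validation grid.
#' @return List with `lambda`, `loglik`, `flat`, and the coarse `profile`
#'   (data frame of lambda, loglik).
#' @export
profile_lambda_ml <- function(X, y, cov, tol = 1e-8, grid_n = 21L) {
  C <- if (inherits(cov, "phylo_vcv")) cov$C else as.matrix(cov)
  ll <- function(lam) gls_fit(X, y, lambda_transform(C, lam))$loglik
  grid <- seq(0, 1, length.out = grid_n)
  llg <- vapply(grid, function(l) tryCatch(ll(l), error = function(e) NaN),
                numeric(1))
  if (any(!is.finite(llg)))
    stop("profile log-likelihood is not finite at lambda = ",
         paste(format(grid[!is.finite(llg)]), collapse = ", "),
         "; covariance is numerically ill-conditioned")
  profile <- data.frame(lambda = grid, loglik = llg)
  if (diff(range(llg)) < 1e-9)
    return(list(lambda = 0, loglik = llg[1L], flat = TRUE, profile = profile))
  i <- which.max(llg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1)
  cll <- c(opt$objective, llg[1L], llg[grid_n])
  best <- which.max(cll)
  list(lambda = cand[best], loglik = cll[best], flat = FALSE,
       profile = profile)
}

#' Fit a phylogenetic allometric body-mass model
#'
#' Fits one of three PGLS regressions of natural-log body mass on natural-log
#' femoral predictors under a Pagel's-lambda scaled tree covariance:
#' `bm ~ fcsa`, `bm ~ fl`, or `bm ~ fcsa + fl`. Body mass enters the model in
#' natural-log *grams* (so printed intercepts refer to grams), while all
#' user-facing mass values are kilograms; predictors stay in their measured
#' units (mm^2 for cortical area, mm for length). `lambda` is estimated by
#' profile maximum likelihood unless fixed numerically.
#'
#' @param traits Data frame with columns `species`, `bm_kg`, `fcsa_mm2`, and
#'   (for the length models) `fl_mm`; one row per species, all values > 0.
#' @param tree Rooted `phylo` object containing every species in `traits`.
#' @param model One of `"fcsa"`, `"fl"`, `"fcsa+fl"` (formula strings such as
#'   `"BM ~ FCSA"` are also accepted).
#' @param lambda `"ML"` (default) or a fixed scalar in `[0, 1]`.
#' @return An object of class `pgls_fit`.
#' @export
fit_model <- function(traits, tree, model = c("fcsa", "fl", "fcsa+fl"),
                      lambda = "ML") {
  model <- normalize_model_name(if (is.character(model) && length(model) > 1L)
    model[1L] else model)
  req <- c("species", "bm_kg", "fcsa_mm2",
           if (model != "fcsa") "fl_mm")
  miss <- setdiff(req, names(traits))
  if (length(miss)) stop("traits table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(traits$species))
    stop("traits table has duplicated species")
  not_in_tree <- setdiff(traits$species, tree$tip.label)
  if (length(not_in_tree))
    stop("species not in tree: ", paste(not_in_tree, collapse = ", "))
  used <- c("bm_kg", "fcsa_mm2", if (model != "fcsa") "fl_mm")
  for (v in used) {
    bad <- !is.finite(traits[[v]]) | traits[[v]] <= 0
    if (any(bad))
      stop("non-positive or missing ", v, " for: ",
           paste(traits$species[bad], collapse = ", "))
  }

  spp <- traits$species
  y <- log(traits$bm_kg * 1000)           # ln grams
  X <- switch(model,
    "fcsa"    = cbind("(Intercept)" = 1, "ln_fcsa" = log(traits$fcsa_mm2)),
    "fl"      = cbind("(Intercept)" = 1, "ln_fl"   = log(traits$fl_mm)),
    "fcsa+fl" = cbind("(Intercept)" = 1, "ln_fcsa" = log(traits$fcsa_mm2),
                      "ln_fl" = log(traits$fl_mm)))
  cov <- vcv_from_tree(tree, taxa = spp)

  flat <- FALSE
  if (identical(lambda, "ML")) {
    prof <- profile_lambda_ml(X, y, cov)
    lambda_hat <- prof$lambda
    flat <- prof$flat
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"ML\" or a scalar in [0, 1]")
    lambda_hat <- lambda
  }
  cov <- lambda_transform(cov, lambda_hat)
  fit <- gls_fit(X, y, cov$V)

  n <- fit$n; p <- fit$p
  se <- sqrt(diag(fit$cov_beta))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df = n - p)
  coef_table <- data.frame(
    estimate = fit$beta, se = se, t = tval, p = pval,
    ci_lower = fit$beta - tcrit * se, ci_upper = fit$beta + tcrit * se,
    row.names = colnames(X))

  # intercept-only GLS under the same V(lambda-hat), for R^2 and F
  fit0 <- gls_fit(matrix(1, n, 1), y, cov$V)
  r2 <- 1 - fit$rss / fit0$rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  f_df1 <- p - 1
  f_df2 <- n - p
  fstat <- if (f_df1 > 0)
    ((fit0$rss - fit$rss) / f_df1) / (fit$rss / f_df2) else NA_real_
  f_p <- if (f_df1 > 0)
    stats::pf(fstat, f_df1, f_df2, lower.tail = FALSE) else NA_real_
  # raw-scale (unwhitened) analogue, reported for completeness
  tss_raw <- sum((y - mean(y))^2)
  rss_raw <- sum(fit$residuals^2)
  r2_raw <- 1 - rss_raw / tss_raw
  f_raw <- if (f_df1 > 0)
    (r2_raw / f_df1) / ((1 - r2_raw) / f_df2) else NA_real_

  k <- p + 2                               # coefficients + sigma^2 + lambda
  out <- list(
    model = model, coefficients = fit$beta, coef_table = coef_table,
    lambda = lambda_hat, lambda_flat = flat, lambda_fixed = !identical(lambda, "ML"),
    sigma2 = fit$sigma2, sigma2_ml = fit$sigma2_ml,
    loglik = fit$loglik, k = k, aic = -2 * fit$loglik + 2 * k,
    r2 = r2, adj_r2 = adj_r2,
    fstatistic = c(value = fstat, df1 = f_df1, df2 = f_df2, p = f_p),
    fstatistic_raw = c(value = f_raw, df1 = f_df1, df2 = f_df2),
    n = n, p = p, taxa = spp, X = X, y = y,
    cov_beta = fit$cov_beta, V = cov$V, C = cov$C,
    residuals = fit$residuals, mass_log_unit = "g")
  class(out) <- "pgls_fit"
  out
}

normalize_model_name <- function(model) {
  m <- tolower(gsub("[[:space:]]", "", model))
  m <- sub("^(ln)?\\(?bm\\)?~", "", m)
  m <- gsub("ln\\(|\\)", "", m)
  if (m %in% c("fcsa", "1")) return(if (m == "1") stop("intercept-only model not supported") else "fcsa")
  if (m == "fl") return("fl")
  if (m %in% c("fcsa+fl", "fl+fcsa")) return("fcsa+fl")
  stop("unknown model \"", model,
       "\"; use one of \"fcsa\", \"fl\", \"fcsa+fl\"")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  eqn <- paste0("ln(BM_g) = ",
                paste(sprintf("%.2f x %s", x$coefficients[-1],
                              rownames(x$coef_table)[-1]), collapse = " + "),
                sprintf(" %+.2f", x$coefficients[1]))
  cat("Phylogenetic GLS allometry (", x$model, "), n = ", x$n, "\n", sep = "")
  cat("  ", eqn, "\n", sep = "")
  cat("  Pagel's lambda = ", format(round(x$lambda, digits)),
      if (x$lambda_flat) " (flat profile)",
      if (x$lambda_fixed) " (fixed)", "\n", sep = "")
  print(round(x$coef_table, digits))
  cat(sprintf("  sigma^2 = %.4g, logLik = %.4g, AIC = %.4g, adj R^2 = %.3f\n",
              x$sigma2, x$loglik, x$aic, x$adj_r2))
  if (is.finite(x$fstatistic["value"]))
    cat(sprintf("  F(%d, %d) = %.1f, p = %.3g\n", x$fstatistic["df1"],
                x$fstatistic["df2"], x$fstatistic["value"], x$fstatistic["p"]))
  invisible(x)
}

#' Rank candidate models by AIC
#'
#' Orders fits by ascending AIC and selects the best model; when the AIC
#' difference to the minimum is below `tie_delta` (default 2), the tied model
#' with the fewest parameters wins. All fits must be on the same response
#' data and taxon set.
#'
#' @param fits List of `pgls_fit` objects (optionally named).
#' @param tie_delta AIC difference below which models are treated as tied.
#' @return List with `table` (data frame: model, k, loglik, aic, delta_aic,
#'   rank) and `best` (index into `fits`).
#' @export
compare_models <- function(fits, tie_delta = 2) {
  if (inherits(fits, "pgls_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "pgls_fit")))
  taxa0 <- sort(fits[[1L]]$taxa)
  y0 <- fits[[1L]]$y[order(fits[[1L]]$taxa)]
  for (f in fits[-1L]) {
    if (!identical(sort(f$taxa), taxa0))
      stop("fits are not on the same taxon set")
    if (max(abs(f$y[order(f$taxa)] - y0)) > 1e-12)
      stop("fits are not on the same response data")
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, `[[`, "", "model")
  aic <- vapply(fits, `[[`, 0, "aic")
  k <- vapply(fits, `[[`, 0, "k")
  delta <- aic - min(aic)
  tied <- which(delta < tie_delta)
  best <- unname(tied[order(k[tied], aic[tied])][1L])
  ord <- order(aic, k)
  tab <- data.frame(model = nm, k = k,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    aic = aic, delta_aic = delta,
                    rank = match(seq_along(fits), ord),
                    selected = seq_along(fits) == best)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, best = best)
}
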