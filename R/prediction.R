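#' Point prediction of body mass from cortical area
#'
#' Evaluates the fitted log-log allometry at a new femoral cortical area and
#' back-transforms to kilograms. No log-normal bias correction is applied:
#' the point estimate is the back-transformed conditional median.
#'
#' @param fit A `pgls_fit` from [fit_model()] (single-predictor `fcsa` model),
#'   or a numeric coefficient vector `c(intercept, slope)` on the natural-log
#'   gram scale.
#' @param fcsa Femoral cortical surface area (mm^2), > 0. Vectorized.
#' @return Predicted body mass in kg.
#' @export
predict_point <- function(fit, fcsa) {
  if (any(!is.finite(fcsa) | fcsa <= 0))
    stop("fcsa must be positive")
  b <- prediction_coefs(fit)
  exp(b[1L] + b[2L] * log(fcsa)) / 1000
}

#' Recover allometric coefficients from a published specimen table
#'
#' Published body-mass tables print regression coefficients rounded to two
#' decimals, but every printed specimen estimate lies exactly on the fitted
#' line. An ordinary log-log regression of the printed estimates (gram scale)
#' on the printed cortical areas therefore recovers the underlying intercept
#' and slope at full precision, which is what interval and point-prediction
#' checks against such tables need.
#'
#' @param specimens Data frame with columns `fcsa_mm2` and `estimate_kg`.
#' @return Named numeric vector `c(intercept, slope)` on the natural-log gram
#'   scale.
#' @export
reference_allometry <- function(specimens) {
  stopifnot(all(c("fcsa_mm2", "estimate_kg") %in% names(specimens)))
  co <- stats::coef(stats::lm(log(estimate_kg * 1000) ~ log(fcsa_mm2),
                              data = specimens))
  stats::setNames(as.numeric(co), c("intercept", "slope"))
}

prediction_coefs <- function(fit) {
  if (inherits(fit, "pgls_fit")) {
    if (fit$model != "fcsa")
      stop("prediction requires the single-predictor fcsa model; got \"",
           fit$model, "\"")
    fit$coefficients
  } else if (is.numeric(fit) && length(fit) == 2L) {
    fit
  } else stop("fit must be a pgls_fit or c(intercept, slope)")
}

#' Prediction interval for a new specimen
#'
#' Computes a point estimate and a two-sided prediction interval on the
#' natural-log scale, back-transformed to kg (so the interval is
#' log-symmetric around the estimate). Two modes:
#'
#' * `"independent"` (default): the new specimen is treated as exchangeable
#'   with the reference tips. Log-scale prediction variance is
#'   `sigma2 * d0 + x0' cov(beta) x0`, with `d0` the mean diagonal of the
#'   lambda-scaled reference covariance (the standardized tip depth).
#' * `"blup"`: the specimen's phylogenetic covariance with the reference tips
#'   is exploited. `placement` must give `c_extant`, the shared root-to-MRCA
#'   path lengths to each reference tip (tree units, pre lambda scaling) and
#'   `depth`, the specimen's own root-to-tip depth. The point estimate is
#'   shifted by the BLUP term `c' V^{-1} (y - X beta)` and the variance
#'   reduced by `c' V^{-1} c` (with `c` lambda-scaled).
#'
#' @param fit A `pgls_fit` for the `fcsa` model.
#' @param fcsa Cortical area (mm^2), scalar.
#' @param level Coverage level, default 0.95.
#' @param mode `"independent"` or `"blup"`.
#' @param placement For `mode = "blup"`: list with `c_extant` (named numeric,
#'   aligned to `fit$taxa`) and `depth` (scalar).
#' @return One-row data frame: `fcsa_mm2`, `log_estimate`, `log_se`,
#'   `estimate_kg`, `lower95_kg`, `upper95_kg` (column names carry the
#'   requested level only at 0.95; other levels keep the same names).
#' @export
predict_interval <- function(fit, fcsa, level = 0.95,
                             mode = c("independent", "blup"),
                             placement = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "pgls_fit"), length(fcsa) == 1L)
  if (!is.finite(fcsa) || fcsa <= 0) stop("fcsa must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x0 <- c(1, log(fcsa))
  if (fit$model != "fcsa")
    stop("prediction requires the single-predictor fcsa model")
  mu <- drop(x0 %*% fit$coefficients)
  d0 <- mean(diag(fit$V))
  var_beta <- drop(t(x0) %*% fit$cov_beta %*% x0)

  if (mode == "independent") {
    var_log <- fit$sigma2 * d0 + var_beta
  } else {
    if (is.null(placement))
      stop("mode = \"blup\" requires a `placement` (c_extant and depth)")
    c_raw <- placement$c_extant
    if (is.null(c_raw) || length(c_raw) != fit$n)
      stop("placement$c_extant must align with the ", fit$n, " reference taxa")
    if (!is.null(names(c_raw))) c_raw <- c_raw[fit$taxa]
    depth <- if (is.null(placement$depth)) d0 else placement$depth
    c_lam <- fit$lambda * c_raw
    Vinv_c <- solve(fit$V, c_lam)
    resid <- fit$y - drop(fit$X %*% fit$coefficients)
    mu <- mu + drop(crossprod(c_lam, solve(fit$V, resid)))
    var_log <- fit$sigma2 * (depth - drop(crossprod(c_lam, Vinv_c))) + var_beta
    if (var_log < 0) var_log <- 0
  }
  se <- sqrt(var_log)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - fit$p)
  data.frame(fcsa_mm2 = fcsa,
             log_estimate = mu, log_se = se,
             estimate_kg = exp(mu) / 1000,
             lower95_kg = exp(mu - tq * se) / 1000,
             upper95_kg = exp(mu + tq * se) / 1000)
}

#' Predict body mass for a table of specimens
#'
#' Applies [predict_interval()] to every row of a specimen table, preserving
#' input order. Values are kept at full precision; rounding belongs to report
#' serialization only.
#'
#' @param fit A `pgls_fit` for the `fcsa` model.
#' @param specimens Data frame with columns `specimen_id`, `species`,
#'   `fcsa_mm2` and optionally `dataset`.
#' @param level Coverage level.
#' @param mode,placements Prediction mode as in [predict_interval()];
#'   `placements` is a list keyed by species (or specimen_id) for
#'   `mode = "blup"`.
#' @return Data frame with one prediction row per specimen: `specimen_id`,
#'   `species`, `dataset`, `fcsa_mm2`, `log_estimate`, `log_se`,
#'   `estimate_kg`, `lower95_kg`, `upper95_kg`.
#' @export
predict_specimens <- function(fit, specimens, level = 0.95,
                              mode = c("independent", "blup"),
                              placements = NULL) {
  mode <- match.arg(mode)
  if (is.null(specimens) || nrow(specimens) == 0L)
    stop("specimen table is empty")
  req <- c("specimen_id", "species", "fcsa_mm2")
  miss <- setdiff(req, names(specimens))
  if (length(miss)) stop("specimen table lacks column(s): ",
                         paste(miss, collapse = ", "))
  dup <- unique(specimens$specimen_id[duplicated(specimens$specimen_id)])
  if (length(dup))
    stop("duplicate specimen_id: ", paste(dup, collapse = ", "))
  rows <- lapply(seq_len(nrow(specimens)), function(i) {
    pl <- NULL
    if (mode == "blup") {
      key <- specimens$species[i]
      pl <- placements[[specimens$specimen_id[i]]]
      if (is.null(pl)) pl <- placements[[key]]
      if (is.null(pl)) stop("no placement for specimen ",
                            specimens$specimen_id[i])
    }
    predict_interval(fit, specimens$fcsa_mm2[i], level = level, mode = mode,
                     placement = pl)
  })
  out <- do.call(rbind, rows)
  out <- cbind(specimen_id = specimens$specimen_id,
               species = specimens$species,
               dataset = if ("dataset" %in% names(specimens))
                 specimens$dataset else NA_character_,
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
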