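#' Combine specimen tables from two sources
#'
#' Concatenates two specimen tables, preserving each row's `dataset` tag.
#' Specimen IDs colliding across sources are disambiguated by prefixing the
#' source tag, so the combined table satisfies the uniqueness invariant.
#'
#' @param a,b Data frames with columns `specimen_id`, `species`, `fcsa_mm2`
#'   and optionally `dataset` (filled with `tag_a`/`tag_b` when absent).
#' @param tag_a,tag_b Default source tags.
#' @return Combined data frame.
#' @export
combine_datasets <- function(a, b, tag_a = "A", tag_b = "B") {
  fill_tag <- function(d, tag) {
    if (is.null(d) || nrow(d) == 0L) return(d)
    if (!"dataset" %in% names(d)) d$dataset <- tag
    if (anyDuplicated(d$specimen_id))
      stop("duplicate specimen_id within one source")
    d
  }
  a <- fill_tag(a, tag_a)
  b <- fill_tag(b, tag_b)
  if (is.null(b) || nrow(b) == 0L) return(a)
  if (is.null(a) || nrow(a) == 0L) return(b)
  common <- intersect(names(a), names(b))
  out <- rbind(a[common], b[common])
  clash <- out$specimen_id[duplicated(out$specimen_id)]
  if (length(clash)) {
    hit <- out$specimen_id %in% clash
    out$specimen_id[hit] <- paste(out$dataset[hit], out$specimen_id[hit],
                                  sep = ":")
    if (anyDuplicated(out$specimen_id))
      stop("specimen IDs collide even after source prefixing")
  }
  rownames(out) <- NULL
  out
}

#' Species-level weighted mean body masses
#'
#' Pools specimen-level predictions into per-species arithmetic means of
#' cortical area, estimated mass, and the two prediction limits. Each
#' specimen carries equal weight, which is algebraically identical to
#' weighting per-source means by their specimen counts. Per-source counts are
#' reported as one `n_<tag>` column per dataset tag plus the total `N`.
#'
#' @param predictions Data frame from [predict_specimens()] (needs `species`,
#'   `fcsa_mm2`, `estimate_kg`, `lower95_kg`, `upper95_kg`, and optionally
#'   `dataset`).
#' @return Data frame with one row per species: counts, `mean_fcsa_mm2`,
#'   `mean_bm_kg`, `mean_lower95_kg`, `mean_upper95_kg`, sorted by species.
#' @export
species_weighted_mean <- function(predictions) {
  req <- c("species", "fcsa_mm2", "estimate_kg", "lower95_kg", "upper95_kg")
  miss <- setdiff(req, names(predictions))
  if (length(miss)) stop("prediction table lacks column(s): ",
                         paste(miss, collapse = ", "))
  keep <- !is.na(predictions$species) & nzchar(predictions$species)
  if (any(!keep)) {
    warning(sum(!keep), " prediction(s) without a species label excluded")
    predictions <- predictions[keep, , drop = FALSE]
  }
  if (nrow(predictions) == 0L) stop("no predictions with species labels")
  sp <- sort(unique(predictions$species))
  agg <- function(v) vapply(sp, function(s)
    mean(predictions[[v]][predictions$species == s]), numeric(1))
  out <- data.frame(species = sp,
                    N = vapply(sp, function(s)
                      sum(predictions$species == s), integer(1)),
                    mean_fcsa_mm2 = agg("fcsa_mm2"),
                    mean_bm_kg = agg("estimate_kg"),
                    mean_lower95_kg = agg("lower95_kg"),
                    mean_upper95_kg = agg("upper95_kg"),
                    row.names = NULL)
  if ("dataset" %in% names(predictions) &&
      !all(is.na(predictions$dataset))) {
    tags <- sort(unique(predictions$dataset))
    cnt <- sapply(tags, function(tg) vapply(sp, function(s)
      sum(predictions$species == s & predictions$dataset == tg), integer(1)))
    cnt <- matrix(cnt, nrow = length(sp),
                  dimnames = list(NULL, paste0("n_", tags)))
    out <- cbind(out[1L], as.data.frame(cnt), out[-1L])
  }
  out
}

#' Paired t-test of two estimate sets on the log scale
#'
#' Compares two species-to-mass maps with a paired two-sided t-test on
#' natural-log masses (equivalently, a one-sample t-test on per-species log
#' ratios). Species missing from either map are dropped pairwise.
#'
#' @param current,prior Named numeric vectors mapping species to body mass
#'   (kg). Names are matched after [standardize_labels()].
#' @param synonyms Optional synonym map applied to both name sets.
#' @return Object of class `mass_comparison`: list with `n_pairs`, `t`, `df`,
#'   `p`, `mean_log_ratio`, `species`.
#' @export
paired_log_t_test <- function(current, prior, synonyms = NULL) {
  names(current) <- standardize_labels(names(current), synonyms)
  names(prior) <- standardize_labels(names(prior), synonyms)
  common <- intersect(names(current), names(prior))
  cur <- current[common]
  pri <- prior[common]
  ok <- is.finite(cur) & is.finite(pri) & cur > 0 & pri > 0
  cur <- cur[ok]; pri <- pri[ok]
  if (length(cur) < 2L)
    stop("need at least 2 complete species pairs; got ", length(cur))
  d <- log(cur) - log(pri)
  if (stats::sd(d) < 1e-12) {
    # degenerate: all log ratios equal; t is 0 (identical sets) or signed Inf
    tval <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
    res <- list(n_pairs = length(d), t = tval, df = length(d) - 1L,
                p = if (tval == 0) 1 else 0,
                mean_log_ratio = mean(d), species = names(cur))
    return(structure(res, class = "mass_comparison"))
  }
  tt <- stats::t.test(d)
  structure(list(n_pairs = length(cur),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_log_ratio = unname(tt$estimate),
                 species = names(cur)),
            class = "mass_comparison")
}

#' @export
print.mass_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired t-test on log body mass: t = %.2f, df = %d, p = %.3g\n",
    x$t, x$df, x$p))
  cat(sprintf("  %d species pairs; mean log ratio = %.3f (ratio %.3f)\n",
              x$n_pairs, x$mean_log_ratio, exp(x$mean_log_ratio)))
  invisible(x)
}
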