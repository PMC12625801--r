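#' Read an extant trait table
#'
#' Delimited text with header columns `species`, `bm_kg`, `fcsa_mm2` and
#' optionally `fl_mm` (the length column may be absent when only the
#' cortical-area model is fit).
#'
#' @param path File path (tab- or comma-delimited, auto-detected).
#' @param synonyms Optional synonym map applied to species labels.
#' @return Data frame.
#' @export
read_trait_table <- function(path, synonyms = NULL) {
  df <- read_delim_auto(path)
  req <- c("species", "bm_kg", "fcsa_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trait table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$species <- standardize_labels(df$species, synonyms)
  df
}

#' Read a fossil specimen table
#'
#' Delimited text with header columns `specimen_id`, `species`, `fcsa_mm2`
#' and optionally `dataset`.
#'
#' @inheritParams read_trait_table
#' @return Data frame.
#' @export
read_specimen_table <- function(path, synonyms = NULL) {
  df <- read_delim_auto(path)
  req <- c("specimen_id", "species", "fcsa_mm2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("specimen table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$species <- standardize_labels(df$species, synonyms)
  df
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a pipeline run configuration
#'
#' Plain `key = value` text, `#` comments allowed. Recognized keys: `tree`,
#' `extant`, `fossil`, `priors`, `synonyms`, `out_dir`, `models`
#' (comma-separated subset of `fcsa`, `fl`, `fcsa+fl`), `prediction_mode`
#' (`independent`/`blup`), `level`, `seed`, `rounding`, `lambda`
#' (`ML` or a number).
#'
#' @param path Config file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  cfg <- stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                         vapply(kv, function(m) trimws(m[2L]), ""))
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  defaults <- list(models = "fcsa, fl, fcsa+fl",
                   prediction_mode = "independent",
                   level = "0.95", seed = "1", rounding = "2", lambda = "ML")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg$models <- trimws(strsplit(cfg$models, ",")[[1L]])
  cfg$models <- vapply(cfg$models, normalize_model_name, "")
  cfg$level <- as.numeric(cfg$level)
  if (!is.finite(cfg$level) || cfg$level <= 0 || cfg$level >= 1)
    stop("level must be in (0, 1)")
  cfg$seed <- as.integer(cfg$seed)
  cfg$rounding <- as.integer(cfg$rounding)
  if (!identical(cfg$lambda, "ML")) cfg$lambda <- as.numeric(cfg$lambda)
  if (!cfg$prediction_mode %in% c("independent", "blup"))
    stop("prediction_mode must be \"independent\" or \"blup\"")
  for (k in c("tree", "extant", "fossil"))
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs
#'
#' Report-only checks of the configured inputs: tree/table species
#' concordance after synonym mapping, value positivity, duplicate IDs, and
#' (in BLUP mode) fossil species present on the tree. Nothing is modified.
#'
#' @param config A `run_config` (or path to one).
#' @return Data frame with columns `stage`, `issue`, `detail` (zero rows when
#'   clean).
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- list()
  note <- function(stage, issue, detail)
    issues[[length(issues) + 1L]] <<- data.frame(stage = stage, issue = issue,
                                                 detail = detail)
  syn <- if (!is.null(config$synonyms)) read_synonym_map(config$synonyms)
  tree <- tryCatch(parse_newick(file = config$tree), error = function(e) {
    note("tree", "parse_error", conditionMessage(e)); NULL })
  traits <- tryCatch(read_trait_table(config$extant, syn),
                     error = function(e) {
                       note("extant", "read_error", conditionMessage(e)); NULL })
  fossil <- tryCatch(read_specimen_table(config$fossil, syn),
                     error = function(e) {
                       note("fossil", "read_error", conditionMessage(e)); NULL })
  if (!is.null(tree) && !is.null(traits)) {
    tips <- standardize_labels(tree$tip.label, syn)
    absent <- setdiff(traits$species, tips)
    if (length(absent))
      note("extant", "species_not_in_tree", paste(absent, collapse = ", "))
  }
  if (!is.null(traits)) {
    for (v in intersect(c("bm_kg", "fcsa_mm2", "fl_mm"), names(traits))) {
      bad <- which(!is.finite(traits[[v]]) | traits[[v]] <= 0)
      if (length(bad))
        note("extant", paste0("nonpositive_", v),
             paste(traits$species[bad], collapse = ", "))
    }
    dup <- unique(traits$species[duplicated(traits$species)])
    if (length(dup))
      note("extant", "duplicate_species", paste(dup, collapse = ", "))
  }
  if (!is.null(fossil)) {
    bad <- which(!is.finite(fossil$fcsa_mm2) | fossil$fcsa_mm2 <= 0)
    if (length(bad))
      note("fossil", "nonpositive_fcsa_mm2",
           paste(fossil$specimen_id[bad], collapse = ", "))
    dup <- unique(fossil$specimen_id[duplicated(fossil$specimen_id)])
    if (length(dup))
      note("fossil", "duplicate_specimen_id", paste(dup, collapse = ", "))
    if (config$prediction_mode == "blup" && !is.null(tree)) {
      tips <- standardize_labels(tree$tip.label, syn)
      absent <- setdiff(unique(fossil$species), tips)
      if (length(absent))
        note("fossil", "species_not_in_tree_blup",
             paste(absent, collapse = ", "))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(stage = character(), issue = character(),
                  detail = character())
}

#' Run the full estimation pipeline
#'
#' End-to-end run: fit the requested PGLS models on the extant reference
#' data, write a model report, select the best model by AIC (ties within 2
#' AIC going to the model with fewer predictors), predict all fossil
#' specimens with prediction intervals, aggregate to species-level weighted
#' means, and - when a prior-estimate table is configured - run paired
#' log-scale comparisons. All report values are rounded only at write time.
#'
#' @param config A `run_config` list (or path to a config file).
#' @return Invisibly, a list with `fits`, `selection`, `predictions`,
#'   `summary`, `comparisons`, and the output `paths`.
#' @export
run_estimation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- "setup"
  fail <- function(e) stop("pipeline stage [", stage, "] failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    syn <- if (!is.null(config$synonyms)) read_synonym_map(config$synonyms)
    tree <- parse_newick(file = config$tree)
    tree$tip.label <- standardize_labels(tree$tip.label, syn)
    traits <- read_trait_table(config$extant, syn)
    fossil <- read_specimen_table(config$fossil, syn)
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)

    stage <- "tree preparation"
    tree <- resolve_polytomies(tree, seed = config$seed)
    extra <- setdiff(tree$tip.label, traits$species)
    if (length(extra) && length(extra) < length(tree$tip.label))
      tree <- prune_to_taxa(tree, intersect(tree$tip.label, traits$species))

    stage <- "model fitting"
    fits <- lapply(config$models, function(m)
      fit_model(traits, tree, model = m, lambda = config$lambda))
    names(fits) <- config$models

    stage <- "model selection"
    sel <- compare_models(fits)
    best <- fits[[sel$best]]
    if (best$model != "fcsa" && "fcsa" %in% names(fits)) {
      # prediction uses cortical area only; fall back if selection differs
      best <- fits[["fcsa"]]
    }

    stage <- "prediction"
    preds <- predict_specimens(best, fossil, level = config$level,
                               mode = config$prediction_mode)

    stage <- "aggregation"
    summ <- species_weighted_mean(preds)

    comparisons <- NULL
    if (!is.null(config$priors)) {
      stage <- "comparison"
      pri <- read_delim_auto(config$priors)
      pri$species <- standardize_labels(pri$species, syn)
      cur <- stats::setNames(summ$mean_bm_kg, summ$species)
      pcols <- setdiff(names(pri), "species")
      comparisons <- lapply(pcols, function(cn) {
        v <- stats::setNames(as.numeric(pri[[cn]]), pri$species)
        tryCatch(paired_log_t_test(cur, v, synonyms = syn),
                 error = function(e) NULL)
      })
      names(comparisons) <- pcols
    }

    stage <- "reporting"
    r <- config$rounding
    paths <- list(
      models = file.path(config$out_dir, "model_report.tsv"),
      predictions = file.path(config$out_dir, "specimen_predictions.tsv"),
      summary = file.path(config$out_dir, "species_summary.tsv"),
      manifest = file.path(config$out_dir, "manifest.txt"))
    model_report <- do.call(rbind, lapply(names(fits), function(m) {
      f <- fits[[m]]
      data.frame(model = m,
                 equation = fit_equation(f),
                 lambda = round(f$lambda, r),
                 se = paste(round(f$coef_table$se[-1L], r), collapse = "; "),
                 p = paste(signif(f$coef_table$p[-1L], 3), collapse = "; "),
                 aic = round(f$aic, r), adj_r2 = round(f$adj_r2, r),
                 selected = m == names(fits)[sel$best])
    }))
    utils::write.table(model_report, paths$models, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pr <- preds
    for (cn in c("fcsa_mm2", "estimate_kg", "lower95_kg", "upper95_kg"))
      pr[[cn]] <- round(pr[[cn]], r)
    pr$log_estimate <- NULL; pr$log_se <- NULL
    utils::write.table(pr, paths$predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sm <- summ
    for (cn in grep("^mean_", names(sm), value = TRUE))
      sm[[cn]] <- round(sm[[cn]], r)
    utils::write.table(sm, paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(comparisons)) {
      ct <- do.call(rbind, lapply(names(comparisons), function(cn) {
        x <- comparisons[[cn]]
        if (is.null(x)) return(NULL)
        data.frame(prior = cn, n_pairs = x$n_pairs, t = round(x$t, r),
                   df = x$df, p = signif(x$p, 3),
                   mean_log_ratio = round(x$mean_log_ratio, r))
      }))
      if (!is.null(ct) && nrow(ct)) {
        paths$comparisons <- file.path(config$out_dir, "comparisons.tsv")
        utils::write.table(ct, paths$comparisons, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    manifest <- c(
      paste0("phylomass_version = ",
             as.character(utils::packageVersion("phylomass"))),
      paste0("timestamp = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste0("seed = ", config$seed),
      paste0("models = ", paste(config$models, collapse = ", ")),
      paste0("selected_model = ", names(fits)[sel$best]),
      paste0("prediction_model = ", best$model),
      paste0("lambda_hat = ", format(best$lambda, digits = 10)),
      paste0("coefficients = ",
             paste(sprintf("%s=%.10g", names(best$coefficients),
                           best$coefficients), collapse = ", ")),
      paste0("sigma2 = ", format(best$sigma2, digits = 10)),
      paste0("n_extant = ", best$n),
      paste0("n_specimens = ", nrow(preds)),
      paste0("prediction_mode = ", config$prediction_mode),
      paste0("level = ", config$level))
    writeLines(manifest, paths$manifest)

    invisible(list(fits = fits, selection = sel, predictions = preds,
                   summary = summ, comparisons = comparisons, paths = paths))
  }, error = fail)
}

fit_equation <- function(f) {
  terms <- sprintf("%.2f x ln(%s)", f$coefficients[-1L],
                   sub("^ln_", "", rownames(f$coef_table)[-1L]))
  paste0("ln(BM_g) = ", paste(terms, collapse = " + "),
         sprintf(" %+.2f", f$coefficients[1L]))
}
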