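#' Simulation configuration
#'
#' Bundles the generating parameters for synthetic reference data. Defaults
#' reproduce the structure of the extant-primate reference sample the
#' allometry is calibrated on: 62 reference species, body mass scaling on
#' cortical area with slope 1.26 and intercept 3.48 (natural-log grams on
#' natural-log mm^2), residual SD 0.37 per unit standardized tree depth,
#' phylogenetic signal lambda = 0.64, and femoral-length scaling with slope
#' 2.65 and intercept -5.19. Fossil cortical areas default to 55-710 mm^2,
#' the span observed across subfossil lemur femora, so predictions exercise
#' the upper extrapolation range.
#'
#' @param n_extant Number of extant reference species.
#' @param n_fossil_species Number of fossil species to place on the tree.
#' @param specimens_per_species Integer range (length 2) of specimens drawn
#'   per fossil species.
#' @param slope,intercept Generating allometry, ln grams vs ln mm^2.
#' @param sigma Residual SD per unit standardized depth (> 0).
#' @param lambda_true Phylogenetic signal of the residuals, in `[0, 1]`.
#' @param fcsa_range Extant cortical-area range (mm^2), log-uniform sampling.
#' @param fossil_fcsa_range Fossil species-mean cortical-area range (mm^2).
#' @param fl_slope,fl_intercept,fl_sigma Femoral-length allometry used to
#'   back-generate `fl_mm` (set `fl_slope = NULL` to skip the column).
#' @param specimen_jitter_sd SD of log-normal within-species jitter applied
#'   to fossil specimen cortical areas.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_extant = 62L, n_fossil_species = 15L,
                       specimens_per_species = c(1L, 6L),
                       slope = 1.26, intercept = 3.48, sigma = 0.37,
                       lambda_true = 0.64,
                       fcsa_range = c(5, 1500),
                       fossil_fcsa_range = c(55, 710),
                       fl_slope = 2.65, fl_intercept = -5.19, fl_sigma = 0.25,
                       specimen_jitter_sd = 0.1, seed = 1L) {
  stopifnot(n_extant >= 1, n_fossil_species >= 1,
            length(specimens_per_species) == 2L,
            all(specimens_per_species >= 1L),
            diff(specimens_per_species) >= 0,
            sigma > 0, lambda_true >= 0, lambda_true <= 1,
            length(fcsa_range) == 2L, all(fcsa_range > 0),
            diff(fcsa_range) > 0,
            length(fossil_fcsa_range) == 2L, all(fossil_fcsa_range > 0),
            diff(fossil_fcsa_range) > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule tree with `n` tips, rescaled to unit root-to-tip depth so that
#' residual variances are expressed per unit depth. Deterministic under
#' `seed`.
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed.
#' @param tip_prefix Tip label prefix.
#' @return An ultrametric `phylo` object with depth 1.
#' @export
simulate_tree <- function(n, seed = 1L, tip_prefix = "sp") {
  if (n < 2L) stop("need at least 2 taxa")
  set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("%s%03d", tip_prefix, seq_len(n))
  tree
}

# residuals ~ MVN(0, sigma^2 * V(lambda)) via the Cholesky factor
rmvn_chol <- function(V, sigma) {
  drop(crossprod(chol(V), stats::rnorm(nrow(V)))) * sigma
}

#' Simulate an extant trait table on a tree
#'
#' Draws ln cortical area uniformly over the log of the configured range and
#' generates ln body mass (grams) as `intercept + slope * ln(fcsa) + eps`,
#' with `eps` multivariate normal with covariance `sigma^2 * V(lambda_true)`
#' built from the tree. Femoral length, when requested, is back-generated
#' from mass through its own allometry with independent phylogenetic noise,
#' so the length model holds approximately with the configured slope.
#'
#' @param tree Ultrametric `phylo` whose tips name the species.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Trait data frame (`species`, `bm_kg`, `fcsa_mm2`, `fl_mm`) with
#'   the generating residual vector attached as attribute `"residuals"`.
#' @export
simulate_traits <- function(tree, config = sim_config(), seed = NULL) {
  n <- length(tree$tip.label)
  if (n < config$n_extant)
    stop("tree has fewer tips (", n, ") than n_extant (", config$n_extant, ")")
  set.seed(if (is.null(seed)) config$seed else seed)
  cov <- vcv_from_tree(tree)
  V <- lambda_transform(cov, config$lambda_true)$V
  ln_fcsa <- stats::runif(n, log(config$fcsa_range[1L]),
                          log(config$fcsa_range[2L]))
  eps <- rmvn_chol(V, config$sigma)
  ln_bm_g <- config$intercept + config$slope * ln_fcsa + eps
  out <- data.frame(species = tree$tip.label,
                    bm_kg = exp(ln_bm_g) / 1000,
                    fcsa_mm2 = exp(ln_fcsa))
  if (!is.null(config$fl_slope)) {
    eps_fl <- rmvn_chol(V, config$fl_sigma)
    # invert ln(bm_g) = fl_intercept + fl_slope * ln(fl) + eps_fl
    out$fl_mm <- exp((ln_bm_g - config$fl_intercept - eps_fl) /
                       config$fl_slope)
  }
  attr(out, "residuals") <- eps
  out
}

#' Simulate fossil specimens attached to a reference tree
#'
#' Places fossil species at uniform random points along the branches of the
#' reference tree (edges sampled proportional to length) and extends each to
#' the present, giving every fossil a root-to-tip depth equal to the tree
#' depth. Species-mean cortical areas are log-uniform over the configured
#' fossil range; specimen values are jittered log-normally. True masses are
#' drawn from the same generating process as the extant traits: the fossil
#' residual vector is multivariate normal under the joint (fossil + extant)
#' lambda-scaled covariance, conditioned on the extant residuals when these
#' are supplied.
#'
#' @param tree The extant reference tree used for fitting.
#' @param config A [sim_config()].
#' @param extant_traits Optional trait table from [simulate_traits()] (same
#'   tree); its `"residuals"` attribute conditions the fossil residuals so
#'   BLUP-mode prediction is exercised against data generated coherently.
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return List: `specimens` (data frame `specimen_id`, `species`, `dataset`,
#'   `fcsa_mm2`), `truth` (data frame `specimen_id`, `species`,
#'   `true_bm_kg`), `placements` (per species: `c_extant` shared path-length
#'   vector to extant tips, `depth`).
#' @export
simulate_fossils <- function(tree, config = sim_config(),
                             extant_traits = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  n_f <- config$n_fossil_species
  C <- ape::vcv.phylo(tree)
  taxa <- tree$tip.label
  depth <- max(diag(C))
  node_depth <- ape::node.depth.edgelength(tree)

  # attachment point per fossil: edge sampled by length, point uniform on it
  edges <- tree$edge
  elen <- tree$edge.length
  pick <- sample.int(nrow(edges), n_f, replace = TRUE, prob = elen)
  t_attach <- node_depth[edges[pick, 1L]] + stats::runif(n_f) * elen[pick]
  # representative extant tip below each sampled edge
  rep_tip <- vapply(pick, function(e) {
    child <- edges[e, 2L]
    if (child <= length(taxa)) as.integer(child)
    else match(ape::extract.clade(tree, child)$tip.label[1L], taxa)
  }, integer(1))

  fossil_names <- sprintf("fossil%02d", seq_len(n_f))
  # joint covariance blocks via the representative-tip construction:
  # shared path between a fossil (attached at depth t on an edge) and tip j
  # is min(C[rep, j], t); between two fossils min(C[rep_i, rep_j], t_i, t_j).
  C_fe <- matrix(0, n_f, length(taxa), dimnames = list(fossil_names, taxa))
  for (i in seq_len(n_f))
    C_fe[i, ] <- pmin(C[rep_tip[i], ], t_attach[i])
  C_ff <- matrix(0, n_f, n_f)
  for (i in seq_len(n_f)) for (j in seq_len(n_f)) {
    C_ff[i, j] <- if (i == j) depth else
      min(C[rep_tip[i], rep_tip[j]], t_attach[i], t_attach[j])
  }

  lam <- config$lambda_true
  S_ff <- lambda_transform(C_ff, lam)
  S_fe <- lam * C_fe                      # all cross terms are off-diagonal
  if (!is.null(extant_traits)) {
    eps_e <- attr(extant_traits, "residuals")
    if (is.null(eps_e))
      stop("extant_traits lacks the \"residuals\" attribute from simulate_traits()")
    S_ee <- lambda_transform(C[taxa, taxa], lam)
    A <- S_fe %*% solve(S_ee)
    mu_f <- drop(A %*% eps_e)
    Sigma_c <- S_ff - A %*% t(S_fe)
    Sigma_c <- (Sigma_c + t(Sigma_c)) / 2
    ev <- eigen(Sigma_c, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    L <- ev$vectors %*% diag(sqrt(ev$values), n_f)
    eps_f <- mu_f + drop(L %*% stats::rnorm(n_f)) * config$sigma
  } else {
    eps_f <- rmvn_chol(S_ff, config$sigma)
  }

  fr <- log(config$fossil_fcsa_range)
  sp_fcsa <- exp(stats::runif(n_f, fr[1L], fr[2L]))
  n_spec <- sample(seq(config$specimens_per_species[1L],
                       config$specimens_per_species[2L]), n_f, replace = TRUE)
  rows <- vector("list", n_f)
  for (i in seq_len(n_f)) {
    fcsa_i <- sp_fcsa[i] *
      exp(stats::rnorm(n_spec[i], 0, config$specimen_jitter_sd))
    ln_bm_g <- config$intercept + config$slope * log(fcsa_i) + eps_f[i]
    rows[[i]] <- data.frame(
      specimen_id = sprintf("%s_s%02d", fossil_names[i], seq_len(n_spec[i])),
      species = fossil_names[i], dataset = "synthetic",
      fcsa_mm2 = fcsa_i, true_bm_kg = exp(ln_bm_g) / 1000)
  }
  all <- do.call(rbind, rows)
  placements <- lapply(seq_len(n_f), function(i)
    list(c_extant = stats::setNames(C_fe[i, ], taxa), depth = depth))
  names(placements) <- fossil_names
  list(specimens = all[c("specimen_id", "species", "dataset", "fcsa_mm2")],
       truth = all[c("specimen_id", "species", "true_bm_kg")],
       placements = placements)
}

#' Simulate a complete coherent dataset
#'
#' Convenience wrapper: one pure-birth tree, an extant trait table on it, and
#' fossil specimens whose residuals are conditioned on the extant residuals,
#' so independent- and BLUP-mode predictions can both be evaluated against
#' known truth.
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `traits`, `fossils` (see [simulate_fossils()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_tree(config$n_extant, seed = config$seed)
  traits <- simulate_traits(tree, config)
  fossils <- simulate_fossils(tree, config, extant_traits = traits)
  list(tree = tree, traits = traits, fossils = fossils)
}

#' Write a ready-to-run fixture directory
#'
#' Emits the Newick tree, extant trait table, fossil specimen table and a
#' pipeline config file for a simulated dataset, in the exact formats
#' [run_estimation()] consumes.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, the config-file path.
#' @export
write_fixture_set <- function(dir, config = sim_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_dataset(config)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$traits, file.path(dir, "extant_traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$fossils$specimens,
                     file.path(dir, "fossil_specimens.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- file.path(dir, "run.cfg")
  writeLines(c(
    paste0("tree = ", file.path(dir, "tree.nwk")),
    paste0("extant = ", file.path(dir, "extant_traits.tsv")),
    paste0("fossil = ", file.path(dir, "fossil_specimens.tsv")),
    paste0("out_dir = ", file.path(dir, "out")),
    "models = fcsa, fl, fcsa+fl",
    "prediction_mode = independent",
    "level = 0.95",
    paste0("seed = ", config$seed),
    "rounding = 2"), cfg)
  invisible(cfg)
}
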