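#' Parse a rooted Newick tree
#'
#' Reads a single Newick description into an [ape::read.tree()] `phylo`
#' object after structural validation. Branch lengths are interpreted as
#' time (millions of years) and are never rescaled.
#'
#' @param text Newick string (one tree, terminated by `;`). Exactly one of
#'   `text`/`file` must be supplied.
#' @param file Path to a Newick file.
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:1):0;")
#' tr$tip.label
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')')")
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminal ';'")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree) || is.null(tree$tip.label))
    stop("Newick parse error: could not parse tree text")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("Newick parse error: duplicate tip label(s): ",
         paste(dup, collapse = ", "))
  if (any(!nzchar(tree$tip.label)))
    stop("Newick parse error: empty tip label")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("Newick parse error: negative branch length")
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Resolve polytomies into a bifurcating tree
#'
#' Multichotomies are expanded into arbitrarily ordered dichotomies joined by
#' zero-length branches, so every pairwise shared path length (and hence the
#' phylogenetic covariance matrix) is unchanged. The expansion order is
#' randomized under `seed`; covariance invariance makes the order
#' inconsequential.
#'
#' @param tree A rooted `phylo` object.
#' @param seed Integer seed governing the randomized expansion order.
#' @return A strictly bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ape::multi2di(tree, random = TRUE)
}

#' Prune a tree to a taxon subset
#'
#' Keeps exactly the requested tips; internal degree-2 nodes created by the
#' pruning are suppressed with their branch lengths summed, so root-to-tip
#' depths and pairwise shared path lengths among kept taxa are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance structure from a tree
#'
#' Builds the matrix `C` whose `(i, j)` entry is the summed branch length from
#' the root to the most recent common ancestor of taxa `i` and `j` (the
#' Brownian-motion trait covariance up to a rate constant). The returned
#' structure carries `lambda = NA` until [lambda_transform()] is applied.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param taxa Optional ordered subset of tip labels; defaults to all tips in
#'   tree order.
#' @return An object of class `phylo_vcv`: list with `taxa`, `C`, `lambda`,
#'   `V`.
#' @export
vcv_from_tree <- function(tree, taxa = NULL) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; covariance undefined")
  C <- ape::vcv.phylo(tree)
  if (is.null(taxa)) taxa <- tree$tip.label
  missing <- setdiff(taxa, rownames(C))
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  C <- C[taxa, taxa, drop = FALSE]
  structure(list(taxa = taxa, C = C, lambda = NA_real_, V = NULL),
            class = "phylo_vcv")
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies all off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal (tip depths) unchanged. `lambda = 1` returns the Brownian-motion
#' covariance; `lambda = 0` the star-tree (independence) limit.
#'
#' @param cov A `phylo_vcv` object from [vcv_from_tree()], or a bare
#'   covariance matrix.
#' @param lambda Scalar in `[0, 1]`.
#' @return For a `phylo_vcv` input, the same object with `lambda` and `V`
#'   filled in; for a matrix input, the transformed matrix.
#' @export
lambda_transform <- function(cov, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a scalar in [0, 1], got ", format(lambda))
  C <- if (inherits(cov, "phylo_vcv")) cov$C else as.matrix(cov)
  V <- lambda * C
  diag(V) <- diag(C)
  if (inherits(cov, "phylo_vcv")) {
    cov$lambda <- lambda
    cov$V <- V
    cov
  } else V
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat("Phylogenetic covariance structure:", length(x$taxa), "taxa\n")
  cat("  tip depth range: [", format(min(diag(x$C))), ", ",
      format(max(diag(x$C))), "]\n", sep = "")
  if (is.na(x$lambda)) cat("  lambda: unset\n")
  else cat("  lambda:", format(x$lambda), "\n")
  invisible(x)
}

#' Standardize species labels
#'
#' Trims whitespace, collapses runs of spaces/underscores to a single space,
#' and optionally applies a synonym map (alias -> canonical). Used wherever
#' tree tip labels are matched against trait or specimen tables, since data
#' sources are frequently inconsistent in spelling and separator usage.
#'
#' @param x Character vector of labels.
#' @param synonyms Optional two-column data frame (`alias`, `canonical`) or
#'   named character vector mapping alias to canonical name.
#' @return Character vector of standardized labels.
#' @export
standardize_labels <- function(x, synonyms = NULL) {
  out <- gsub("[ _]+", " ", trimws(x))
  if (!is.null(synonyms)) {
    if (is.data.frame(synonyms)) {
      map <- stats::setNames(as.character(synonyms[[2L]]),
                             gsub("[ _]+", " ", trimws(synonyms[[1L]])))
    } else {
      map <- stats::setNames(as.character(synonyms),
                             gsub("[ _]+", " ", trimws(names(synonyms))))
    }
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
    out <- gsub("[ _]+", " ", trimws(out))
  }
  out
}

#' Read a synonym map
#'
#' @param path Two-column delimited text file (header `alias`, `canonical`).
#' @return Data frame with columns `alias` and `canonical`.
#' @export
read_synonym_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("alias", "canonical") %in% names(df)))
    stop("synonym map must have columns `alias` and `canonical`")
  df
}
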