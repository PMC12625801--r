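test_that("parse_newick reads minimal trees and round-trips", {
  tr <- parse_newick("(A:1,B:1):0;")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(unname(diag(vcv_from_tree(tr)$C)), c(1, 1))
  txt <- write_newick(tr)
  tr2 <- parse_newick(txt)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(vcv_from_tree(tr2)$C, vcv_from_tree(tr)$C)
})

test_that("parse_newick rejects malformed input with informative errors", {
  expect_error(parse_newick("(A:1,(B:1):0.5"), "unbalanced parentheses")
  expect_error(parse_newick("(A:1,B:1)"), "missing terminal")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate tip label.*A")
})

test_that("packaged synthetic 77-taxon tree has unique tips and prunes to 62 extant", {
  tree <- parse_newick(file = extdata("synthetic_primate_tree_77taxa.nwk"))
  expect_length(tree$tip.label, 77)
  expect_false(anyDuplicated(tree$tip.label) > 0)
  syn <- read_synonym_map(extdata("species_synonyms.tsv"))
  fossil <- standardize_labels(
    read.delim(extdata("prior_estimates.tsv"))$species, syn)
  tips_std <- standardize_labels(tree$tip.label)
  expect_true(all(fossil %in% tips_std))
  extant <- tree$tip.label[!tips_std %in% fossil]
  pruned <- prune_to_taxa(tree, extant)
  expect_length(pruned$tip.label, 62)
  # ultrametric: all tip depths equal
  d <- oracle_tip_depths(pruned)
  expect_lt(diff(range(d)), 1e-8)
})

test_that("prune_to_taxa preserves depths and shared paths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pt <- prune_to_taxa(tr, c("A", "C"))
  C <- vcv_from_tree(pt)$C
  expect_equal(unname(diag(C)), c(2, 2))
  expect_equal(unname(C["A", "C"]), 0)
  # keep everything: identical covariance
  expect_equal(vcv_from_tree(prune_to_taxa(tr, tr$tip.label))$C,
               vcv_from_tree(tr)$C)
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("vcv_from_tree matches hand computation and path-sum oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- vcv_from_tree(tr, taxa = c("A", "B", "C"))$C
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  set.seed(7)
  for (i in 1:100) {
    rt <- ape::rtree(sample(4:20, 1))
    C <- vcv_from_tree(rt)$C
    M <- oracle_vcv(rt)
    expect_equal(C, M[rownames(C), colnames(C)], tolerance = 1e-10)
  }
})

test_that("star tree gives a diagonal covariance", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1.5, 6)
  C <- vcv_from_tree(star)$C
  expect_equal(unname(C), diag(1.5, 6))
})

test_that("lambda_transform scales off-diagonals only and validates range", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  cov <- vcv_from_tree(tr)
  expect_equal(lambda_transform(cov, 1)$V, cov$C)
  expect_equal(unname(lambda_transform(cov, 0)$V), diag(diag(cov$C)))
  V <- lambda_transform(cov, 0.64)$V
  expect_equal(unname(V["A", "B"]), 0.64)
  expect_equal(diag(V), diag(cov$C))
  expect_error(lambda_transform(cov, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(cov, -0.1), "\\[0, 1\\]")
})

test_that("polytomy resolution preserves the covariance matrix", {
  tri <- parse_newick("(A:1,B:1,C:1);")
  res <- resolve_polytomies(tri, seed = 1)
  expect_true(ape::is.binary(res))
  expect_equal(vcv_from_tree(res)$C[c("A", "B", "C"), c("A", "B", "C")],
               vcv_from_tree(tri)$C[c("A", "B", "C"), c("A", "B", "C")],
               tolerance = 1e-12)
  # idempotent on binary trees
  bin <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(resolve_polytomies(bin, seed = 5), bin)
  # 5-way polytomy, different seeds: topologies may differ, covariances not
  poly <- parse_newick("(A:2,B:2,C:2,D:2,E:2);")
  taxa <- poly$tip.label
  r1 <- resolve_polytomies(poly, seed = 1)
  r2 <- resolve_polytomies(poly, seed = 2)
  expect_equal(vcv_from_tree(r1)$C[taxa, taxa],
               vcv_from_tree(r2)$C[taxa, taxa], tolerance = 1e-12)
  expect_equal(vcv_from_tree(r1)$C[taxa, taxa],
               vcv_from_tree(poly)$C[taxa, taxa], tolerance = 1e-12)
})

test_that("pruning and polytomy resolution commute on the covariance scale", {
  poly <- parse_newick("((A:1,B:1,C:1,D:1):1,(E:2,F:2):0.5,G:3);")
  keep <- c("A", "C", "E", "G")
  a <- vcv_from_tree(prune_to_taxa(resolve_polytomies(poly, seed = 3), keep))$C
  b <- vcv_from_tree(resolve_polytomies(prune_to_taxa(poly, keep), seed = 8))$C
  expect_equal(a[keep, keep], b[keep, keep], tolerance = 1e-10)
})

test_that("lambda-transformed covariances stay positive definite", {
  for (i in 1:100) {
    tr <- simulate_tree(sample(5:30, 1), seed = 400 + i)
    cov <- vcv_from_tree(tr)
    for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
      V <- lambda_transform(cov, lam)$V
      expect_silent(chol(V))
    }
  }
})

test_that("standardize_labels normalizes separators and applies synonyms", {
  expect_equal(standardize_labels(c(" Lemur_catta ", "Indri__indri")),
               c("Lemur catta", "Indri indri"))
  syn <- data.frame(alias = "Palaeopropithecus ingens",
                    canonical = "Paleopropithecus ingens")
  expect_equal(standardize_labels("Palaeopropithecus_ingens", syn),
               "Paleopropithecus ingens")
})
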