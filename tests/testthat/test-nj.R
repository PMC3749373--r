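randomAdditiveTree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

test_that("NJ exactly recovers topology and lengths from additive matrices", {
  set.seed(61)
  for (i in 1:40) {
    tr <- randomAdditiveTree(sample(4:12, 1))
    D <- ape::cophenetic.phylo(tr)
    my <- njTree(D)
    # an additive metric determines the tree: path-length equality is
    # topology + branch-length recovery in one check
    expect_lt(max(abs(ape::cophenetic.phylo(my)[rownames(D), colnames(D)] - D)),
              1e-9)
  }
})

test_that("NJ agrees with the reference implementation on random trees", {
  set.seed(62)
  for (i in 1:10) {
    tr <- randomAdditiveTree(8)
    D <- ape::cophenetic.phylo(tr)
    expect_equal(ape::dist.topo(ape::unroot(njTree(D)),
                                ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("the four-taxon worked example recovers its generating tree", {
  gen <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):0);")
  D <- ape::cophenetic.phylo(gen)
  my <- njTree(D)
  expect_lt(max(abs(ape::cophenetic.phylo(my)[rownames(D), colnames(D)] - D)),
            1e-9)
})

test_that("three taxa solve the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- njTree(D)
  len <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(len["a"]), 1)   # (3+4-5)/2
  expect_equal(unname(len["b"]), 2)
  expect_equal(unname(len["c"]), 3)
})

test_that("equal distances collapse to a star with zero internal lengths", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  tree <- njTree(D)
  internal <- tree$edge[, 2] > 5
  expect_true(all(tree$edge.length[internal] == 0))
  expect_true(all(tree$edge.length >= 0))
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(njTree(D), "symmetric")
  D2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(njTree(D2), "non-negative")
})

test_that("bootstrap supports are deterministic, bounded, and 0/100 at one replicate", {
  spec <- simulationSpec(events = list(duplicationEvent("ancient", "root", 0.6)),
                         n_families = 1, loss_prob = 0, seed = 63)
  msa <- stackFamily(simulateFamily(spec, 1))
  t1 <- bootstrapSupports(msa, n_replicates = 25, seed = 99)
  t2 <- bootstrapSupports(msa, n_replicates = 25, seed = 99)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  t3 <- bootstrapSupports(msa, n_replicates = 1, seed = 1)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
  expect_error(bootstrapSupports(msa, n_replicates = 0), ">= 1")
})

test_that("well-separated clades receive high support for the separating edge", {
  spec <- simulationSpec(events = list(duplicationEvent("ancient", "root", 0.8)),
                         n_families = 1, loss_prob = 0, seed = 64)
  fam <- simulateFamily(spec, 1)
  msa <- stackFamily(fam)
  tree <- bootstrapSupports(msa, n_replicates = 200, seed = 5)
  part <- splitTwoClusters(tree, species_of = stats::setNames(
    sub("_.*", "", alignmentIds(msa)), alignmentIds(msa)))
  expect_equal(part$n_clusters, 2L)
  expect_gte(part$support, 95)
})

test_that("the two-cluster split matches the simulated duplicate lineages", {
  spec <- simulationSpec(events = list(duplicationEvent("ancient", "root", 0.65)),
                         n_families = 1, loss_prob = 0, seed = 65)
  fam <- simulateFamily(spec, 1)
  msa <- stackFamily(fam)
  sp_of <- stats::setNames(sub("_.*", "", alignmentIds(msa)),
                           alignmentIds(msa))
  tree <- bootstrapSupports(msa, n_replicates = 100, seed = 5)
  part <- splitTwoClusters(tree, sp_of)
  expect_equal(part$n_clusters, 2L)
  # truth: the two clusters are exactly the outparalog sides
  tr <- fam$truth
  outp <- tr[tr$relation == "outparalog", ]
  for (i in seq_len(nrow(outp))) {
    in1 <- outp$id_a[i] %in% part$clusters[[1]]
    in2 <- outp$id_b[i] %in% part$clusters[[1]]
    expect_true(in1 != in2)   # outparalogs straddle the split
  }
  orth <- tr[tr$relation == "ortholog", ]
  for (i in seq_len(nrow(orth))) {
    in1 <- orth$id_a[i] %in% part$clusters[[1]]
    in2 <- orth$id_b[i] %in% part$clusters[[1]]
    expect_true(in1 == in2)   # orthologs stay together
  }
})

test_that("speciation-only families stay one cluster", {
  spec <- simulationSpec(n_families = 1, seed = 66)
  msa <- stackFamily(simulateFamily(spec, 1))
  sp_of <- stats::setNames(sub("_.*", "", alignmentIds(msa)),
                           alignmentIds(msa))
  tree <- bootstrapSupports(msa, n_replicates = 100, seed = 5)
  part <- splitTwoClusters(tree, sp_of)
  expect_equal(part$n_clusters, 1L)
})

test_that("tiny trees cannot be split", {
  D <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tree <- njTree(D)
  tree$node.label <- ""
  part <- splitTwoClusters(tree, min_support = 0)
  expect_equal(part$n_clusters, 1L)
})

test_that("gene trees round-trip through Newick", {
  spec <- simulationSpec(events = defaultEvents(), n_families = 1, seed = 67)
  msa <- stackFamily(simulateFamily(spec, 1))
  tree <- bootstrapSupports(msa, n_replicates = 20, seed = 3)
  f <- tempfile(fileext = ".nwk")
  writeGeneTree(tree, f)
  back <- readGeneTree(f)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_setequal(back$tip.label, tree$tip.label)
  d1 <- ape::cophenetic.phylo(tree); d2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-5)
  # supports survive as internal node labels
  expect_setequal(setdiff(back$node.label, ""),
                  setdiff(tree$node.label, ""))
})
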