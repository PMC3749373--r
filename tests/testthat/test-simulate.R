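test_that("zero divergence returns the parent unchanged for any omega", {
  for (seed in 1:3) {
    s <- randomCds(60, seed = seed)
    for (w in c(0, 0.5, 1.5)) {
      set.seed(seed)
      expect_identical(evolveCodons(s, 0, w), s)
    }
  }
})

test_that("omega zero produces purely synonymous divergence", {
  set.seed(4)
  s <- randomCds(200)
  child <- evolveCodons(s, 0.3, 0)
  r <- ng86(s, child)
  expect_gt(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Nd, 0)
})

test_that("NG86 recovers the simulated synonymous divergence", {
  est <- vapply(1:20, function(i) {
    set.seed(i)
    s <- randomCds(300)
    ng86(s, evolveCodons(s, 0.2, 0.5))$Ks
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.05)
})

test_that("expected estimated Ks is monotone in the simulated divergence", {
  grid <- c(0.05, 0.15, 0.3, 0.5)
  means <- vapply(grid, function(d) {
    mean(vapply(1:8, function(i) {
      set.seed(1000 * d + i)
      s <- randomCds(300)
      ng86(s, evolveCodons(s, d, 0.3))$Ks
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("mean Ka/Ks recovers omega across the selection range", {
  for (w in c(0.2, 0.7, 1.0)) {
    est <- vapply(1:12, function(i) {
      set.seed(2000 * w + i)
      s <- randomCds(300)
      ng86(s, evolveCodons(s, 0.35, w))$ka_ks
    }, numeric(1))
    expect_lt(abs(mean(est) - w), 0.15)
  }
})

test_that("evolveCodons rejects broken inputs and impossible budgets", {
  expect_error(evolveCodons("GGGA", 0.1, 0.2), "multiple of 3")
  expect_error(evolveCodons("GGGTAAGGG", 0.1, 0.2), "stop codon")
  set.seed(1)
  # all-Met sequence has zero synonymous sites: S = 0 so no synonymous
  # budget can arise, but a nonsynonymous-only budget must still work
  met <- strrep("ATG", 40)
  expect_silent(evolveCodons(met, 0.2, 0.5))
})

test_that("a speciation-only history labels every pair ortholog", {
  spec <- simulationSpec(n_families = 1, seed = 10)
  fam <- simulateFamily(spec, 1)
  expect_equal(nrow(fam$truth), 15L)   # C(6,2)
  expect_true(all(fam$truth$relation == "ortholog"))
  expect_false(any(fam$truth$tandem))
})

test_that("a single Gm WGD yields exactly one Gm-Gm inparalog pair at its age", {
  spec <- simulationSpec(events = list(duplicationEvent("wgd", "Gm", 0.1)),
                         n_families = 1, loss_prob = 0, seed = 3)
  fam <- simulateFamily(spec, 1)
  inp <- fam$truth[fam$truth$relation == "inparalog", ]
  expect_equal(nrow(inp), 1L)
  expect_match(inp$id_a, "^Gm_")
  expect_match(inp$id_b, "^Gm_")
  expect_equal(inp$true_ds, 0.1, tolerance = 1e-9)
  # cross-species pairs are never inparalogs
  sp_a <- sub("_.*", "", fam$truth$id_a)
  sp_b <- sub("_.*", "", fam$truth$id_b)
  expect_false(any(sp_a != sp_b & fam$truth$relation == "inparalog"))
})

test_that("an ancient duplication yields same-species outparalogs near its age", {
  spec <- simulationSpec(events = list(duplicationEvent("ancient", "root", 0.65)),
                         n_families = 1, loss_prob = 0, seed = 6)
  fam <- simulateFamily(spec, 1)
  sp_a <- sub("_.*", "", fam$truth$id_a)
  sp_b <- sub("_.*", "", fam$truth$id_b)
  same_sp <- sp_a == sp_b
  expect_true(all(fam$truth$relation[same_sp] == "outparalog"))
  expect_false(any(same_sp & fam$truth$relation == "ortholog"))
  # mean outparalog age matches the event age (per-species depths vary)
  expect_equal(mean(fam$truth$true_ds[same_sp]), 0.65, tolerance = 0.06)
  expect_true(all(abs(fam$truth$true_ds[same_sp] - 0.65) < 0.15))
})

test_that("relation labels partition all pairs and obey the species algebra", {
  spec <- simulationSpec(events = defaultEvents(), n_families = 4, seed = 14)
  for (i in 1:4) {
    fam <- simulateFamily(spec, i)
    tr <- fam$truth
    expect_true(all(tr$relation %in% c("ortholog", "inparalog", "outparalog")))
    expect_equal(nrow(tr), choose(nrow(fam$tips), 2))
    sp_a <- sub("_.*", "", tr$id_a); sp_b <- sub("_.*", "", tr$id_b)
    expect_false(any(sp_a == sp_b & tr$relation == "ortholog"))
    expect_false(any(sp_a != sp_b & tr$relation == "inparalog"))
    expect_true(all(tr$tandem ==
                      (tr$relation == "inparalog" & tr$tandem)))
    expect_equal(tr$true_dn, spec$omega * tr$true_ds)
  }
})

test_that("tandem events place the duplicate at the adjacent order index", {
  spec <- simulationSpec(events = list(duplicationEvent("tandem", "Mt", 0.04)),
                         n_families = 1, loss_prob = 0, seed = 2)
  fam <- simulateFamily(spec, 1)
  td <- fam$truth[fam$truth$tandem, ]
  expect_equal(nrow(td), 1L)
  pos <- fam$tips
  oa <- pos$order_index[match(td$id_a, pos$id)]
  ob <- pos$order_index[match(td$id_b, pos$id)]
  expect_equal(abs(oa - ob), 1L)
  expect_equal(pos$chromosome[match(td$id_a, pos$id)],
               pos$chromosome[match(td$id_b, pos$id)])
})

test_that("unknown event lineages are rejected", {
  expect_error(
    simulationSpec(events = list(duplicationEvent("wgd", "Zz", 0.1))),
    "unknown lineage")
})

test_that("dataset generation is deterministic and bookkeeping-complete", {
  spec <- simulationSpec(events = defaultEvents(), n_families = 3, seed = 8)
  d1 <- file.path(tempdir(), "ksscape_sim1")
  d2 <- file.path(tempdir(), "ksscape_sim2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(spec, d1)
  m2 <- generateDataset(spec, d2)
  fastas <- list.files(d1, pattern = "fasta$")
  expect_length(fastas, 6L)
  # identical manifests and byte-identical FASTA under the same seed
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  for (f in fastas)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # every truth id appears in exactly one FASTA
  truth <- utils::read.table(file.path(d1, "truth_pairs.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  ids <- unique(c(truth$id_a, truth$id_b))
  all_headers <- unlist(lapply(fastas, function(f) {
    x <- readLines(file.path(d1, f)); sub("^>", "", x[startsWith(x, ">")])
  }))
  expect_true(all(ids %in% all_headers))
  expect_false(anyDuplicated(all_headers) > 0)
  unlink(c(d1, d2), recursive = TRUE)
})
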