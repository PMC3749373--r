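makeHit <- function(q = "q", s = "s", pident = 95, evalue = 1e-80,
                    bitscore = 500) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = 300L,
             mismatch = 10L, gapopen = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 300L, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("hit filtering applies inclusive 70% / 1e-50 boundaries", {
  below_id <- makeHit(pident = 69.9, evalue = 1e-80)
  at_id <- makeHit(pident = 70.0, evalue = 1e-50)
  above_e <- makeHit(pident = 95, evalue = 1e-49)
  expect_equal(nrow(filterHits(below_id)), 0L)
  expect_equal(nrow(filterHits(at_id)), 1L)
  expect_equal(nrow(filterHits(above_e)), 0L)
})

test_that("filtering preserves order, is idempotent, and passes exactly the passers", {
  hits <- rbind(makeHit("a", pident = 90, evalue = 1e-60),
                makeHit("b", pident = 60, evalue = 1e-90),
                makeHit("c", pident = 80, evalue = 1e-40),
                makeHit("d", pident = 75, evalue = 1e-55),
                makeHit("e", pident = 69, evalue = 1e-51))
  f1 <- filterHits(hits)
  # independent re-scan of the list
  expect_equal(f1$qseqid, c("a", "d"))
  expect_identical(filterHits(f1), f1)
  expect_equal(nrow(filterHits(hits[0, ])), 0L)
})

test_that("a perfect self-similar query yields a 100% top hit with tiny E", {
  set.seed(31)
  s <- randomCds(167)  # 501 nt
  other <- randomCds(167)
  db <- CdsSet(c(x1 = s, x2 = other), species = c("A", "B"))
  q <- CdsSet(c(q1 = s), species = c("C"))
  hits <- allVsAllSearch(db, q)
  top <- hits[which.min(hits$evalue), ]
  expect_equal(top$sseqid, "x1")
  expect_equal(top$pident, 100)
  expect_lt(top$evalue, 1e-50)
  expect_equal(top$length, 501L)
})

test_that("pairs without a shared 11-mer seed produce no hits", {
  db <- CdsSet(c(a = strrep("A", 300)), species = "A")
  q <- CdsSet(c(b = strrep("C", 300)), species = "B")
  expect_equal(nrow(allVsAllSearch(db, q)), 0L)
})

test_that("10% divergence reports about 90% identity on a full-length alignment", {
  set.seed(17)
  a <- randomCds(100)
  b <- mutateSites(a, 30)
  db <- CdsSet(c(a = a, b = b), species = c("A", "B"))
  hits <- allVsAllSearch(db)
  hit <- hits[hits$qseqid == "a" & hits$sseqid == "b", ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$pident, 87)
  expect_lt(hit$pident, 93)
  expect_gt(hit$length, 270)
})

test_that("internal alignment scores match an exhaustive dynamic-programming oracle", {
  set.seed(23)
  cfg <- searchConfig()
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = cfg$match, mismatch = cfg$mismatch, baseOnly = TRUE)
  for (i in 1:5) {
    a <- randomCds(80)
    b <- mutateSites(a, 30)
    db <- CdsSet(c(a = a, b = b), species = c("A", "B"))
    hits <- allVsAllSearch(db)
    hit <- hits[hits$qseqid == "a" & hits$sseqid == "b", ]
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = submat, gapOpening = cfg$gap_open,
      gapExtension = cfg$gap_extend)
    score <- (hit$bitscore * log(2) + log(cfg$K)) / cfg$lambda
    expect_lt(abs(score - Biostrings::score(oracle)), 0.1)
  }
})

test_that("BBH equals a brute-force reciprocity check on random score matrices", {
  set.seed(41)
  for (rep in 1:20) {
    ids_a <- paste0("a", 1:4); ids_b <- paste0("b", 1:4)
    species_of <- c(stats::setNames(rep("A", 4), ids_a),
                    stats::setNames(rep("B", 4), ids_b))
    bs <- matrix(sample(50:500, 16), 4, 4, dimnames = list(ids_a, ids_b))
    hits <- do.call(rbind, lapply(ids_a, function(qa) {
      do.call(rbind, lapply(ids_b, function(qb) {
        rbind(makeHit(qa, qb, bitscore = bs[qa, qb],
                      evalue = 2^(-bs[qa, qb])),
              makeHit(qb, qa, bitscore = bs[qa, qb],
                      evalue = 2^(-bs[qa, qb])))
      }))
    }))
    got <- bidirectionalBestHits(hits, species_of)
    # brute force over all 16 reciprocity conditions
    want <- list()
    for (qa in ids_a) for (qb in ids_b) {
      if (bs[qa, qb] == max(bs[qa, ]) && bs[qa, qb] == max(bs[, qb]))
        want[[length(want) + 1L]] <- sort(c(qa, qb))
    }
    want <- unique(do.call(rbind, want))
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want) && nrow(want))
      expect_equal(as.matrix(got), want[order(want[, 1]), , drop = FALSE],
                   ignore_attr = TRUE)
  }
})

test_that("reciprocity failure removes the pair", {
  species_of <- c(a = "S1", c = "S1", b = "S2")
  hits <- rbind(makeHit("a", "b", bitscore = 300, evalue = 1e-90),
                makeHit("b", "a", bitscore = 300, evalue = 1e-90),
                makeHit("b", "c", bitscore = 400, evalue = 1e-99),
                makeHit("c", "b", bitscore = 400, evalue = 1e-99))
  got <- bidirectionalBestHits(hits, species_of)
  expect_equal(nrow(got), 1L)
  expect_equal(unlist(got[1, ], use.names = FALSE), c("b", "c"))
  expect_error(bidirectionalBestHits(hits, species_of[-1]), "missing")
})

test_that("family clustering takes transitive closure and keeps singletons", {
  hits <- rbind(makeHit("a", "b"), makeHit("b", "c"))
  fams <- clusterFamilies(c("a", "lonely"), hits)
  fam_a <- fams$id[fams$family == "a"]
  expect_setequal(fam_a, c("a", "b", "c"))
  expect_equal(fams$id[fams$family == "lonely"], "lonely")
  # two anchors in one component merge into one family
  fams2 <- clusterFamilies(c("a", "c"), hits)
  expect_equal(unique(fams2$family), "a+c")
  # every id in at most one family
  expect_false(anyDuplicated(fams$id) > 0)
})

test_that("the four-of-six species rule keeps and drops families", {
  fams <- data.frame(
    family = c(rep("f1", 4), rep("f2", 3)),
    id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3"))
  species_of <- c(a1 = "S1", a2 = "S2", a3 = "S3", a4 = "S4",
                  b1 = "S1", b2 = "S2", b3 = "S3")
  kept <- selectQualifyingGenes(fams, species_of, min_species = 4)
  expect_equal(unique(kept$family), "f1")
  expect_identical(selectQualifyingGenes(fams, species_of, min_species = 0),
                   fams)
  expect_error(selectQualifyingGenes(fams, species_of, min_species = 7),
               "exceeds")
})

test_that("hit tables round-trip through the 12-column tabular format", {
  hits <- rbind(makeHit("a", "b"), makeHit("c", "d", pident = 88.5))
  f <- tempfile(fileext = ".tsv")
  writeHits(hits, f)
  back <- readHits(f)
  expect_equal(back, hits)
})

test_that("GFF3 positions rank genes by start coordinate per seqid", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t5000\t6000\t.\t+\t.\tID=g2;Name=two",
           "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=t1;Parent=g1",
           "chr2\tsrc\tgene\t50\t70\t.\t-\t.\tID=g3")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  pos <- gff3Positions(f, species = "Xx")
  expect_equal(pos$order_index[match(c("g1", "g2", "g3"), pos$id)],
               c(1L, 2L, 1L))
  expect_equal(pos$chromosome[match("g3", pos$id)], "chr2")
  expect_true(all(pos$species == "Xx"))
})
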