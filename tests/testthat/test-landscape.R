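test_that("binning is proportional, normalised, and oracle-exact", {
  d <- buildDistribution(rep(0.05, 12), c("Gm", "Gm"))
  expect_equal(ksProportions(d)[1], 1)
  expect_equal(sum(ksProportions(d)), 1)

  empty <- buildDistribution(numeric(0), c("Gm", "Mt"))
  expect_equal(ksPairCount(empty), 0L)
  expect_true(all(ksProportions(empty) == 0))

  set.seed(81)
  ks <- c(stats::runif(200, 0, 2.4), NA, NA)
  d2 <- buildDistribution(ks, c("Mt", "Gm"), bin_width = 0.1, ks_max = 2)
  ksv <- ks[!is.na(ks)]
  oracle <- vapply(seq_len(20), function(i) {
    sum(ksv >= (i - 1) * 0.1 & ksv < i * 0.1)
  }, numeric(1)) / length(ksv)
  expect_equal(ksProportions(d2), oracle)
  # overflow accounting closes the books
  expect_equal(sum(ksProportions(d2)) + d2@overflow / ksPairCount(d2), 1)
  expect_equal(d2@overflow, sum(ksv >= 2))
  expect_error(buildDistribution(1, c("a", "b"), bin_width = 0), "> 0")
})

test_that("peak detection equals a brute-force local-maximum scan", {
  mk <- function(props) {
    methods::new("KsDistribution", speciesPair = c("A", "B"),
                 breaks = seq(0, by = 0.1, length.out = length(props) + 1),
                 counts = as.integer(props * 1000),
                 proportions = props, nPairs = 1000L, overflow = 0L)
  }
  # constructed unimodal histogram: peak at the second bin centre 0.15
  uni <- mk(c(0.1, 0.6, 0.2, 0.1, 0, 0, 0, 0, 0, 0))
  got <- detectPeaks(uni)
  expect_equal(got$center, 0.15)
  expect_equal(got$proportion, 0.6)
  # flat histogram: no peaks
  expect_equal(nrow(detectPeaks(mk(rep(0.1, 10)))), 0L)
  # tie between adjacent bins resolves toward lower Ks
  tied <- mk(c(0.3, 0.3, 0.05, 0.05, 0.3, 0, 0, 0, 0, 0))
  got2 <- detectPeaks(tied)
  expect_equal(got2$center, c(0.05, 0.45))

  # randomized histograms against an independent plateau-aware scan
  set.seed(82)
  for (rep in 1:25) {
    p <- sample(c(0, 0.05, 0.1, 0.2, 0.3), 8, replace = TRUE)
    if (sum(p) == 0) next
    p <- p / sum(p)
    got <- detectPeaks(mk(p), min_proportion = 0)$center
    want <- c()
    i <- 1
    while (i <= length(p)) {
      j <- i
      while (j < length(p) && abs(p[j + 1] - p[i]) < 1e-12) j <- j + 1
      left <- if (i == 1) -Inf else p[i - 1]
      right <- if (j == length(p)) -Inf else p[j + 1]
      if (!(i == 1 && j == length(p)) && p[i] > left && p[i] > right &&
          p[i] > 0)
        want <- c(want, (i - 0.5) * 0.1)
      i <- j + 1
    }
    expect_equal(got, as.numeric(want))
  }
})

test_that("peak typing follows the dating windows", {
  expect_equal(assignPeakType(0.10), "recent_wgd")
  expect_equal(assignPeakType(0.15), "recent_wgd")
  expect_equal(assignPeakType(0.25), "speciation")   # young Mt-Ca-style peak
  expect_equal(assignPeakType(0.40), "speciation")
  expect_equal(assignPeakType(0.65), "ancient_duplication")
  expect_equal(assignPeakType(0.75), "ancient_duplication")
  expect_equal(assignPeakType(0.95), "unassigned")
  custom <- assignPeakType(0.18, windows = c(recent_wgd = 0.2,
                                             speciation = 0.5,
                                             ancient_duplication = 0.8))
  expect_equal(custom, "recent_wgd")
})

test_that("species-pair summaries match brute-force medians and counting", {
  rates <- data.frame(
    family = c("f1", "f1", "f1", "f2", "f2", "f2"),
    id_a = c("Gm_1", "Gm_1", "Cc_1", "Gm_2", "Gm_2", "Cc_2"),
    id_b = c("Cc_1", "Mt_1", "Mt_1", "Cc_2", "Mt_2", "Mt_2"),
    Ks = c(0.20, 0.42, 0.40, 0.24, 0.38, 0.44),
    ka_ks = c(0.2, 0.3, 0.25, 0.2, 0.3, 0.25))
  cl <- data.frame(id_a = rates$id_a, id_b = rates$id_b,
                   relation = "ortholog", tandem = FALSE)
  sp <- c(Gm_1 = "Gm", Gm_2 = "Gm", Cc_1 = "Cc", Cc_2 = "Cc",
          Mt_1 = "Mt", Mt_2 = "Mt")
  got <- summarizeSpeciesPairs(rates, cl, sp)
  s <- got$summary
  expect_equal(s$ks_median[s$species_pair == "Cc-Gm"], stats::median(c(0.2, 0.24)))
  expect_equal(s$ks_median[s$species_pair == "Gm-Mt"], stats::median(c(0.42, 0.38)))
  expect_equal(s$n_genes_lowest_ks[s$species_pair == "Cc-Gm"], 2L)
  expect_equal(sum(s$n_genes_lowest_ks), 2L)  # one count per family
  expect_equal(got$closest, "Cc-Gm")
  # shuffling the rates table changes nothing
  perm <- sample(nrow(rates))
  got2 <- summarizeSpeciesPairs(rates[perm, ], cl, sp)
  expect_equal(got2$summary, got$summary)
  solo <- data.frame(family = "f1", id_a = "Gm_1", id_b = "Gm_2",
                     Ks = 0.1, ka_ks = 0.2)
  expect_error(summarizeSpeciesPairs(solo, cl, sp), "at least 2 species")
})

test_that("tandem pairs are excluded from medians and distributions", {
  rates <- data.frame(
    family = "f1",
    id_a = c("Gm_1", "Gm_1", "Gm_2"),
    id_b = c("Gm_2", "Gm_3", "Gm_3"),
    Ks = c(0.02, 0.5, 0.5),
    ka_ks = 0.2)
  cl <- data.frame(id_a = rates$id_a, id_b = rates$id_b,
                   relation = c("inparalog", "outparalog", "outparalog"),
                   tandem = c(TRUE, FALSE, FALSE))
  sp <- c(Gm_1 = "Gm", Gm_2 = "Gm", Gm_3 = "Gm", Mt_1 = "Mt")
  dists <- ksDistributions(rates, cl, sp)
  expect_equal(ksPairCount(dists[["Gm-Gm"]]), 2L)  # tandem pair dropped
  dists2 <- ksDistributions(rates, cl, sp, exclude_tandem = FALSE)
  expect_equal(ksPairCount(dists2[["Gm-Gm"]]), 3L)
})

test_that("selection summary categorises genes and averages per gene", {
  rates <- data.frame(family = c("g1", "g1", "g2", "g3"),
                      ka_ks = c(0, 0, 0.8, 1.461))
  got <- selectionPressureSummary(rates)
  pg <- got$per_gene
  expect_equal(pg$category[pg$family == "g1"], "strong_negative")
  expect_equal(pg$category[pg$family == "g2"], "negative")
  expect_equal(pg$category[pg$family == "g3"], "positive")
  expect_equal(got$global_mean, mean(c(0, 0.8, 1.461)))
  expect_error(selectionPressureSummary(data.frame(family = "x", ka_ks = NA)),
               "no defined")
})
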