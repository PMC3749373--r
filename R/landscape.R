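## Ks landscapes: per-species-pair proportional distributions, peak
## detection and typing (recent WGD / speciation / ancient duplication),
## species-pair Ks-median summaries and the selection-pressure summary.

#' Bin Ks values into a proportional distribution
#'
#' @param ks Numeric Ks values (undefined/saturated values, `NA`, are
#'   dropped before binning).
#' @param species_pair Character vector of length 2 (use equal entries
#'   for a within-species distribution).
#' @param bin_width Bin width (default 0.1).
#' @param ks_max Upper limit; values `>= ks_max` go to the overflow count
#'   (default 2.0).
#' @return A [KsDistribution-class].
#' @export
buildDistribution <- function(ks, species_pair, bin_width = 0.1,
                              ks_max = 2.0) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  ks <- ks[!is.na(ks)]
  breaks <- seq(0, ks_max, by = bin_width)
  if (abs(breaks[length(breaks)] - ks_max) > 1e-12)
    breaks <- c(breaks, ks_max)
  overflow <- sum(ks >= ks_max)
  inside <- ks[ks < ks_max & ks >= 0]
  counts <- as.integer(table(cut(inside, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  n <- length(ks)
  methods::new("KsDistribution",
               speciesPair = sort(as.character(species_pair)),
               breaks = breaks, counts = counts,
               proportions = if (n > 0) counts / n else counts * 0,
               nPairs = as.integer(n), overflow = as.integer(overflow))
}

#' Build Ks distributions for every species pair
#'
#' Within-species distributions pool all paralog pairs of that species;
#' cross-species distributions pool all pairs between the two species
#' (orthologs and outparalogs), mirroring a proportional Ks plot.
#' Tandem-flagged pairs are excluded by default, as are undefined Ks.
#'
#' @param rates Rate table with `id_a`, `id_b`, `Ks`.
#' @param classified Classification table ([classifyFamilyPairs()]) used
#'   for the tandem flags; `NULL` disables tandem exclusion.
#' @param species_of Named id-to-species map.
#' @param exclude_tandem Drop tandem-flagged pairs (default `TRUE`).
#' @param bin_width,ks_max Passed to [buildDistribution()].
#' @return Named list of [KsDistribution-class] objects
#'   (`"spA-spB"`, sorted species names).
#' @export
ksDistributions <- function(rates, classified = NULL, species_of,
                            exclude_tandem = TRUE, bin_width = 0.1,
                            ks_max = 2.0) {
  sp_a <- species_of[rates$id_a]; sp_b <- species_of[rates$id_b]
  drop <- rep(FALSE, nrow(rates))
  if (exclude_tandem && !is.null(classified)) {
    kt <- .pairKey(classified$id_a, classified$id_b)
    kr <- .pairKey(rates$id_a, rates$id_b)
    td <- classified$tandem[match(kr, kt)]
    drop <- !is.na(td) & td
  }
  pair_name <- paste(pmin(sp_a, sp_b), pmax(sp_a, sp_b), sep = "-")
  out <- list()
  for (pn in sort(unique(pair_name))) {
    sel <- pair_name == pn & !drop
    sp <- strsplit(pn, "-", fixed = TRUE)[[1L]]
    out[[pn]] <- buildDistribution(rates$Ks[sel], sp,
                                   bin_width = bin_width, ks_max = ks_max)
  }
  out
}

#' Detect peaks in a Ks distribution
#'
#' A peak is a bin strictly greater than both neighbouring bins; a run of
#' tied bins (a plateau) counts as a single candidate, strictly greater
#' than the bins flanking the run, and the tie is resolved toward the
#' lower-Ks bin of the run. Boundary bins/runs are compared to their
#' single flanking bin; a completely flat histogram has no peaks. Peaks
#' below `min_proportion` are discarded. Results are sorted by bin
#' centre.
#'
#' @param dist A [KsDistribution-class].
#' @param min_proportion Minimum peak height (default 0.10).
#' @return `data.frame`: `center`, `proportion`, `type` (filled by
#'   [assignPeakType()], here `"unassigned"`).
#' @export
detectPeaks <- function(dist, min_proportion = 0.10) {
  p <- ksProportions(dist)
  br <- ksBreaks(dist)
  nb <- length(p)
  ## maximal runs of equal proportion
  run_id <- cumsum(c(1L, as.integer(abs(diff(p)) > 1e-12)))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1L] - 1L, nb)
  is_peak <- logical(nb)
  for (r in seq_along(starts)) {
    s <- starts[r]; e <- ends[r]
    if (s == 1L && e == nb) next           # flat histogram
    left <- if (s == 1L) -Inf else p[s - 1L]
    right <- if (e == nb) -Inf else p[e + 1L]
    if (p[s] > left && p[s] > right && p[s] > 0)
      is_peak[s] <- TRUE                   # tie resolved toward lower Ks
  }
  centers <- (br[-length(br)] + br[-1L]) / 2
  keep <- is_peak & p >= min_proportion
  data.frame(center = centers[keep], proportion = p[keep],
             type = rep("unassigned", sum(keep)),
             stringsAsFactors = FALSE)
}

#' Type a Ks peak by its position
#'
#' Peak centres at or below 0.15 are typed `recent_wgd`; centres in
#' (0.15, 0.50] are `speciation` (the window reaches below 0.4 because
#' the youngest speciation, Mt-Ca, peaks between Ks 0.2 and 0.3);
#' centres in (0.50, 0.80] are `ancient_duplication`; anything beyond is
#' `unassigned`.
#'
#' @param peaks `data.frame` from [detectPeaks()] (or a numeric vector of
#'   centres).
#' @param windows Named numeric upper bounds
#'   `c(recent_wgd=, speciation=, ancient_duplication=)`.
#' @return The peaks table with `type` filled (or a character vector when
#'   `peaks` was numeric).
#' @export
assignPeakType <- function(peaks,
                           windows = c(recent_wgd = 0.15,
                                       speciation = 0.50,
                                       ancient_duplication = 0.80)) {
  centers <- if (is.numeric(peaks)) peaks else peaks$center
  type <- ifelse(centers <= windows[["recent_wgd"]], "recent_wgd",
          ifelse(centers <= windows[["speciation"]], "speciation",
          ifelse(centers <= windows[["ancient_duplication"]],
                 "ancient_duplication", "unassigned")))
  if (is.numeric(peaks)) return(type)
  peaks$type <- type
  peaks
}

#' Species-pair Ks summaries and the closest/farthest report
#'
#' For every cross-species pair: the median ortholog Ks (tandem-derived
#' pairs excluded), the mean defined Ka/Ks, and the number of gene
#' families for which this species pair attains the lowest (and highest)
#' ortholog Ks. The closest pair maximises the lowest-Ks gene count
#' (ties to the lower median); the farthest maximises the highest-Ks
#' count (ties to the higher median). Within-species medians are
#' reported but excluded from the closest/farthest ranking.
#'
#' @param rates Rate table with `family`, `id_a`, `id_b`, `Ks`, `ka_ks`.
#' @param classified Classification table with `relation` and `tandem`.
#' @param species_of Named id-to-species map.
#' @return List: `summary` (`data.frame` per species pair), `closest`,
#'   `farthest` (species-pair strings).
#' @export
summarizeSpeciesPairs <- function(rates, classified, species_of) {
  sp_a <- species_of[rates$id_a]; sp_b <- species_of[rates$id_b]
  if (length(unique(c(sp_a, sp_b))) < 2L)
    stop("need at least 2 species")
  kcl <- .pairKey(classified$id_a, classified$id_b)
  kr <- .pairKey(rates$id_a, rates$id_b)
  m <- match(kr, kcl)
  relation <- classified$relation[m]
  tandem <- classified$tandem[m]
  tandem[is.na(tandem)] <- FALSE
  pair_name <- paste(pmin(sp_a, sp_b), pmax(sp_a, sp_b), sep = "-")
  cross <- sp_a != sp_b

  ## medians: ortholog pairs for cross-species, non-tandem paralogs within
  usable <- !is.na(rates$Ks) & !tandem &
    ifelse(cross, !is.na(relation) & relation == "ortholog", TRUE)
  med <- tapply(rates$Ks[usable], pair_name[usable], stats::median)
  mean_kaks <- tapply(rates$ka_ks[!is.na(rates$ka_ks)],
                      pair_name[!is.na(rates$ka_ks)], mean)

  ## per-family lowest/highest ortholog Ks among cross-species pairs
  ok <- usable & cross & !is.na(rates$family)
  low_counts <- high_counts <- stats::setNames(
    integer(length(unique(pair_name))), sort(unique(pair_name)))
  for (f in unique(rates$family[ok])) {
    sel <- ok & rates$family == f
    if (!any(sel)) next
    pmins <- tapply(rates$Ks[sel], pair_name[sel], min)
    lo <- names(pmins)[order(pmins, names(pmins))][1L]
    hi <- names(pmins)[order(-pmins, names(pmins))][1L]
    low_counts[lo] <- low_counts[lo] + 1L
    high_counts[hi] <- high_counts[hi] + 1L
  }

  pairs <- sort(unique(pair_name))
  summary <- data.frame(
    species_pair = pairs,
    ks_median = as.numeric(med[pairs]),
    mean_ka_ks = as.numeric(mean_kaks[pairs]),
    n_genes_lowest_ks = as.integer(low_counts[pairs]),
    n_genes_highest_ks = as.integer(high_counts[pairs]),
    within_species = vapply(strsplit(pairs, "-", fixed = TRUE),
                            function(x) x[1L] == x[2L], logical(1)),
    stringsAsFactors = FALSE)
  cr <- summary[!summary$within_species & !is.na(summary$ks_median), ]
  closest <- cr$species_pair[order(-cr$n_genes_lowest_ks, cr$ks_median)][1L]
  farthest <- cr$species_pair[order(-cr$n_genes_highest_ks, -cr$ks_median)][1L]
  list(summary = summary, closest = closest, farthest = farthest)
}

#' Per-gene and global selection-pressure summary
#'
#' Mean defined Ka/Ks per gene family, categorised as `strong_negative`
#' (mean < 0.3), `negative` (< 1... i.e. in `[0.3, 1]`) or `positive`
#' (> 1); the global mean averages the per-gene means.
#'
#' @param rates Rate table with `family` and `ka_ks`.
#' @return List: `per_gene` (`data.frame`: family, mean_ka_ks, n_pairs,
#'   category), `global_mean`.
#' @export
selectionPressureSummary <- function(rates) {
  ok <- !is.na(rates$ka_ks)
  if (!any(ok)) stop("no defined Ka/Ks ratios")
  fam <- rates$family[ok]
  mu <- tapply(rates$ka_ks[ok], fam, mean)
  n <- tapply(rates$ka_ks[ok], fam, length)
  category <- ifelse(mu < 0.3, "strong_negative",
                     ifelse(mu > 1, "positive", "negative"))
  per_gene <- data.frame(family = names(mu), mean_ka_ks = as.numeric(mu),
                         n_pairs = as.integer(n),
                         category = as.character(category),
                         stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene, global_mean = mean(mu))
}

#' Plot a Ks proportional distribution
#'
#' Simple proportional line plot (base graphics) of one or more
#' [KsDistribution-class] objects.
#'
#' @param dists A `KsDistribution` or list of them.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted proportions.
#' @export
plotKsDistributions <- function(dists, ...) {
  if (methods::is(dists, "KsDistribution")) dists <- list(dists)
  br <- ksBreaks(dists[[1L]])
  centers <- (br[-length(br)] + br[-1L]) / 2
  mat <- vapply(dists, ksProportions, numeric(length(centers)))
  labs <- vapply(dists, function(d) paste(ksSpeciesPair(d), collapse = "-"),
                 character(1))
  graphics::matplot(centers, mat, type = "l", lty = 1,
                    xlab = "Ks", ylab = "proportion of pairs", ...)
  graphics::legend("topright", legend = labs, lty = 1,
                   col = seq_along(dists), cex = 0.8, bty = "n")
  invisible(mat)
}
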