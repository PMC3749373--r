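## End-to-end pipeline: simulate -> search -> families -> align -> rates
## -> trees -> classify -> landscape, with a single configuration object,
## per-stage logging and a reproducible run manifest.

#' Pipeline configuration
#'
#' @param sim_spec A [simulationSpec()] providing the input dataset, or
#'   `NULL` when `cds` is given.
#' @param cds Optional [CdsSet-class] of real input sequences (overrides
#'   `sim_spec`); positional metadata enables tandem detection.
#' @param truth Optional truth-pair table for accuracy scoring.
#' @param min_identity,max_e Homology filter thresholds (70, 1e-50).
#' @param min_species Minimum species per qualifying family (4).
#' @param total_species Species surveyed (6).
#' @param bootstrap Bootstrap replicates per family tree (1000).
#' @param min_support Bootstrap gate for the two-cluster split (50).
#' @param ks_outparalog_threshold Same-species Ks cut for one-cluster
#'   families (0.40).
#' @param bin_width,ks_max Landscape binning (0.1, 2.0).
#' @param min_peak_proportion Peak height floor (0.10).
#' @param seed Seed for bootstrap resampling (the simulation uses
#'   `sim_spec$seed`).
#' @return List of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(sim_spec = NULL, cds = NULL, truth = NULL,
                           min_identity = 70, max_e = 1e-50,
                           min_species = 4L, total_species = 6L,
                           bootstrap = 1000L, min_support = 50,
                           ks_outparalog_threshold = 0.40,
                           bin_width = 0.1, ks_max = 2.0,
                           min_peak_proportion = 0.10, seed = 1L) {
  if (is.null(sim_spec) && is.null(cds))
    stop("provide a simulation spec or a CdsSet")
  if (min_identity < 0 || min_identity > 100) stop("min_identity out of range")
  if (bootstrap < 1L) stop("bootstrap must be >= 1")
  structure(list(sim_spec = sim_spec, cds = cds, truth = truth,
                 min_identity = min_identity, max_e = max_e,
                 min_species = as.integer(min_species),
                 total_species = as.integer(total_species),
                 bootstrap = as.integer(bootstrap),
                 min_support = min_support,
                 ks_outparalog_threshold = ks_outparalog_threshold,
                 bin_width = bin_width, ks_max = ks_max,
                 min_peak_proportion = min_peak_proportion,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Default pipeline configuration over the bundled simulator
#'
#' Twenty families of 300 codons across the six-legume species tree with
#' the default duplication scenario ([defaultEvents()]), omega 0.2 and
#' loss probability 0.25.
#'
#' @param seed Integer seed driving both simulation and bootstrap.
#' @param n_families,bootstrap Size knobs (defaults 20, 1000).
#' @return A `"PipelineConfig"`.
#' @export
defaultPipelineConfig <- function(seed = 1L, n_families = 20L,
                                  bootstrap = 1000L) {
  spec <- simulationSpec(events = defaultEvents(), n_families = n_families,
                         seed = seed)
  pipelineConfig(sim_spec = spec, bootstrap = bootstrap, seed = seed)
}

.stageLog <- function(run, name, t0, ...) {
  info <- list(...)
  elapsed <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] done in %.1fs (%s)", name, elapsed,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = ", ")))
  run$stages[[length(run$stages) + 1L]] <- c(list(stage = name), info)
  run
}

#' Run the full comparative pipeline
#'
#' Executes the eight stages -- simulate, search, families, align, rates,
#' trees, classify, landscape -- and writes every intermediate table plus
#' a JSON run manifest to `out_dir`. Identical configuration and seed
#' reproduce identical tables.
#'
#' @param config A [pipelineConfig()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `cds`, `hits`, `bbh`, `families`, `alignments`,
#'   `rates`, `trees`, `partitions`, `classified`, `evaluation` (when
#'   truth is available), `distributions`, `peaks`, `species_summary`,
#'   `selection`, `manifest`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  run <- list(stages = list())
  res <- list()

  ## 1. simulate (or ingest) -------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (is.null(config$cds)) {
    ds <- simulateDataset(config$sim_spec)
    cds <- ds$cds
    truth <- ds$truth
  } else {
    cds <- config$cds
    truth <- config$truth
  }
  species_of <- cdsSpecies(cds)
  run <- .stageLog(run, "simulate", t0, n_sequences = length(cds))

  ## 2. search ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  hits <- allVsAllSearch(cds)
  fhits <- filterHits(hits, config$min_identity, config$max_e)
  bbh <- bidirectionalBestHits(fhits, species_of)
  run <- .stageLog(run, "search", t0, n_hits = nrow(hits),
                   n_pass = nrow(fhits), n_bbh = nrow(bbh))

  ## 3. families --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  fams <- clusterFamilies(cdsIds(cds), fhits)
  fams <- selectQualifyingGenes(fams, species_of, config$min_species,
                                config$total_species)
  fam_ids <- split(fams$id, fams$family)
  fam_ids <- fam_ids[vapply(fam_ids, length, integer(1)) >= 2L]
  run <- .stageLog(run, "families", t0, n_families = length(fam_ids))

  ## 4. align -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  seqs_chr <- stats::setNames(as.character(cdsSeqs(cds)), cdsIds(cds))
  alignments <- lapply(fam_ids, function(ids) {
    completeDeletion(progressiveMsa(seqs_chr[ids]))
  })
  run <- .stageLog(run, "align", t0, n_alignments = length(alignments))

  ## 5. rates -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  rates <- do.call(rbind, lapply(names(alignments), function(f) {
    cbind(family = f, computeAllPairs(alignments[[f]]))
  }))
  rates$species_a <- unname(species_of[rates$id_a])
  rates$species_b <- unname(species_of[rates$id_b])
  rownames(rates) <- NULL
  run <- .stageLog(run, "rates", t0, n_pairs = nrow(rates))

  ## 6. trees -----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  trees <- list(); partitions <- list()
  for (f in names(alignments)) {
    msa <- alignments[[f]]
    if (length(alignmentIds(msa)) < 3L) {
      partitions[[f]] <- list(n_clusters = 1L,
                              clusters = list(alignmentIds(msa)),
                              edge_length = NA_real_, support = NA_real_)
      next
    }
    tr <- bootstrapSupports(msa, n_replicates = config$bootstrap,
                            seed = config$seed)
    trees[[f]] <- tr
    partitions[[f]] <- splitTwoClusters(tr, species_of,
                                        config$min_support)
  }
  run <- .stageLog(run, "trees", t0, n_trees = length(trees),
                   bootstrap = config$bootstrap)

  ## 7. classify --------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  positions <- cdsInfo(cds)
  classified <- do.call(rbind, lapply(names(alignments), function(f) {
    fr <- rates[rates$family == f, , drop = FALSE]
    cbind(family = f,
          classifyFamilyPairs(fr, partitions[[f]], species_of, positions,
                              config$ks_outparalog_threshold))
  }))
  rownames(classified) <- NULL
  evaluation <- NULL
  if (!is.null(truth) && nrow(truth) > 0L)
    evaluation <- evaluateAgainstTruth(classified, truth)
  run <- .stageLog(run, "classify", t0, n_pairs = nrow(classified),
                   accuracy = if (is.null(evaluation)) NA else
                     round(evaluation$accuracy, 4))

  ## 8. landscape -------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  dists <- ksDistributions(rates, classified, species_of,
                           bin_width = config$bin_width,
                           ks_max = config$ks_max)
  peaks <- do.call(rbind, lapply(names(dists), function(pn) {
    pk <- assignPeakType(detectPeaks(dists[[pn]],
                                     config$min_peak_proportion))
    if (nrow(pk)) cbind(species_pair = pn, pk)
    else cbind(species_pair = character(0), pk)
  }))
  species_summary <- summarizeSpeciesPairs(rates, classified, species_of)
  selection <- selectionPressureSummary(rates)
  run <- .stageLog(run, "landscape", t0, n_distributions = length(dists),
                   n_peaks = nrow(peaks))

  manifest <- list(
    package = as.character(utils::packageVersion("KsScape")),
    seed = config$seed,
    thresholds = config[c("min_identity", "max_e", "min_species",
                          "bootstrap", "min_support",
                          "ks_outparalog_threshold", "bin_width",
                          "ks_max", "min_peak_proportion")],
    stages = run$stages)

  res <- list(cds = cds, truth = truth, hits = hits, filtered_hits = fhits,
              bbh = bbh, families = fams, alignments = alignments,
              rates = rates, trees = trees, partitions = partitions,
              classified = classified, evaluation = evaluation,
              distributions = dists, peaks = peaks,
              species_summary = species_summary, selection = selection,
              manifest = manifest)

  if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
  invisible(res)
}

.writePipelineOutputs <- function(res, out_dir) {
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cdsInfo(res$cds), "positions.tsv")
  writeHits(res$hits, file.path(out_dir, "hits.tsv"))
  wt(res$bbh, "bbh_pairs.tsv")
  wt(res$families, "families.tsv")
  wt(res$rates, "rates.tsv")
  wt(res$classified, "classification.tsv")
  if (length(res$trees)) {
    nwk <- vapply(names(res$trees), function(f) {
      tr <- res$trees[[f]]
      tr$edge.length <- round(tr$edge.length, 6)
      ape::write.tree(tr)
    }, character(1))
    writeLines(paste0(names(res$trees), "\t", nwk),
               file.path(out_dir, "trees.nwk.tsv"))
  }
  dist_df <- do.call(rbind, lapply(names(res$distributions), function(pn) {
    d <- res$distributions[[pn]]
    br <- ksBreaks(d)
    data.frame(species_pair = pn, bin_start = br[-length(br)],
               bin_end = br[-1L], proportion = ksProportions(d),
               n = ksPairCount(d))
  }))
  wt(dist_df, "ks_distributions.tsv")
  wt(res$peaks, "ks_peaks.tsv")
  wt(res$species_summary$summary, "species_pair_summary.tsv")
  wt(res$selection$per_gene, "selection_summary.tsv")
  report <- list(
    closest = res$species_summary$closest,
    farthest = res$species_summary$farthest,
    global_mean_ka_ks = res$selection$global_mean,
    accuracy = if (is.null(res$evaluation)) NULL else
      res$evaluation$accuracy,
    tandem_accuracy = if (is.null(res$evaluation)) NULL else
      res$evaluation$tandem_accuracy)
  jsonlite::write_json(c(report, res$manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' The bundled nitrogen-fixation gene identifier table
#'
#' Twenty curated nitrogen-fixation-related genes with their annotated
#' gene identifiers in each of the six legume genomes (first-listed
#' identifier per species has rank 1).
#'
#' @return `data.frame` with columns `gene`, `species`, `gene_id`,
#'   `rank`.
#' @export
nfGeneTable <- function() {
  f <- system.file("extdata", "nf_gene_table.tsv", package = "KsScape")
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Parse the chromosome from a gene identifier
#'
#' Understands the Medicago (`Medtr5g...` -> `"5"`), Glycine
#' (`Glyma12g...` -> `"12"`) and Lotus (`Lj2....` -> `"2"`) prefix
#' conventions; anything else is `NA`.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of chromosome labels (`NA` if unparseable).
#' @export
chromosomeFromId <- function(ids) {
  out <- rep(NA_character_, length(ids))
  m <- regmatches(ids, regexec("^Medtr(\\d+)g", ids))
  mt <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
               character(1))
  g <- regmatches(ids, regexec("^Glyma(\\d+)g", ids))
  gm <- vapply(g, function(x) if (length(x) == 2L) x[2L] else NA_character_,
               character(1))
  l <- regmatches(ids, regexec("^Lj(\\d+)\\.", ids))
  lj <- vapply(l, function(x) if (length(x) == 2L) x[2L] else NA_character_,
               character(1))
  out[!is.na(mt)] <- sub("^0+", "", mt[!is.na(mt)])
  out[!is.na(gm)] <- sub("^0+", "", gm[!is.na(gm)])
  out[!is.na(lj)] <- lj[!is.na(lj)]
  out
}

#' Count genes located on one chromosome of one species
#'
#' Counts the distinct genes of `gene_table` whose identifier for
#' `species` parses to `chromosome` (see [chromosomeFromId()]).
#' Identifiers that cannot be parsed are excluded with a warning.
#'
#' @param gene_table Table like [nfGeneTable()] (`gene`, `species`,
#'   `gene_id`, optional `rank`).
#' @param species Species code, e.g. `"Mt"`.
#' @param chromosome Chromosome label, e.g. `"5"`.
#' @param primary_only Use only the first-listed (rank 1) identifier per
#'   gene and species (default `TRUE`).
#' @return Integer count of distinct genes.
#' @export
countGenesOnChromosome <- function(gene_table, species, chromosome,
                                   primary_only = TRUE) {
  tb <- gene_table[gene_table$species == species, , drop = FALSE]
  if (primary_only && !is.null(tb$rank))
    tb <- tb[tb$rank == 1L, , drop = FALSE]
  if (nrow(tb) == 0L) return(0L)
  chr <- chromosomeFromId(tb$gene_id)
  if (anyNA(chr))
    warning(sum(is.na(chr)), " identifier(s) could not be parsed; excluded")
  length(unique(tb$gene[!is.na(chr) & chr == as.character(chromosome)]))
}
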