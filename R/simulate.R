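## Codon sequence-evolution simulator with known duplication histories.
##
## Six-species gene families are evolved along a calibrated legume species
## tree (Phaseoloid Gm/Pv/Cc vs Hologalegina Lj/(Mt,Ca)) whose branch
## lengths are in expected synonymous substitutions per synonymous site
## (dS units). Duplication events -- an ancient pre-speciation duplication,
## a whole-genome duplication confined to one lineage, and tandem
## duplications with adjacent gene-order placement -- are layered on top,
## and every pairwise relation (ortholog / inparalog / outparalog, tandem
## flag, true dS/dN) is recorded so that downstream stages can be scored
## against simulated truth.

#' Default six-legume species tree in dS units
#'
#' Branch lengths are calibrated so that the additive tip-to-tip path
#' lengths reproduce the observed ortholog Ks medians between the six
#' legumes (e.g. Gm-Cc 0.212, Gm-Mt 0.398, Mt-Ca 0.282). The three
#' Phaseoloid species join in a polytomy; Lotus is sister to the
#' Medicago/Cicer pair within Hologalegina.
#'
#' @return A nested-list tree; each node is
#'   `list(name =, length =, children = list(...))`.
#' @export
defaultSpeciesTree <- function() {
  tip <- function(name, len) list(name = name, length = len, children = list())
  node <- function(name, len, ...) list(name = name, length = len,
                                        children = list(...))
  node("root", 0,
       node("Phaseoloid", 0.0500,
            tip("Gm", 0.1025), tip("Pv", 0.1045), tip("Cc", 0.1095)),
       node("Hologalegina", 0.0535,
            tip("Lj", 0.1250),
            node("MtCa", 0.0200, tip("Mt", 0.1720), tip("Ca", 0.1100))))
}

treeTipNames <- function(node) {
  if (length(node$children) == 0L) return(node$name)
  unlist(lapply(node$children, treeTipNames))
}

treeNodeNames <- function(node) {
  c(node$name, unlist(lapply(node$children, treeNodeNames)))
}

treeTipDepths <- function(node, acc = 0) {
  if (length(node$children) == 0L)
    return(stats::setNames(acc + node$length, node$name))
  unlist(lapply(node$children, treeTipDepths, acc = acc + node$length))
}

treeNewick <- function(node) {
  lab <- function(n) {
    if (length(n$children) == 0L)
      return(sprintf("%s:%g", n$name, n$length))
    inner <- paste(vapply(n$children, lab, character(1)), collapse = ",")
    sprintf("(%s)%s:%g", inner, n$name, n$length)
  }
  paste0(lab(node), ";")
}

#' Describe one duplication event
#'
#' @param kind `"ancient"` (pre-speciation, on the root stem), `"wgd"` or
#'   `"tandem"` (on a single named lineage; tandem places the duplicate at
#'   the adjacent gene-order index).
#' @param lineage `"root"` for ancient events, otherwise the name of a
#'   species-tree node (usually a tip) on whose subtending branch the
#'   duplication happens.
#' @param age_dS Expected dS separating the two duplicate lineages at the
#'   end of the simulation (must be `>= 0`).
#' @return A `list` of class `"DuplicationEvent"`.
#' @export
duplicationEvent <- function(kind = c("ancient", "wgd", "tandem"),
                             lineage = "root", age_dS) {
  kind <- match.arg(kind)
  if (!is.numeric(age_dS) || age_dS < 0) stop("age_dS must be >= 0")
  if (kind == "ancient" && lineage != "root")
    stop("ancient events occur on the root stem; use lineage = \"root\"")
  structure(list(kind = kind, lineage = lineage, age_dS = age_dS),
            class = "DuplicationEvent")
}

#' Default duplication scenario
#'
#' One ancient pre-speciation duplication (duplicate lineages separated by
#' about 0.65 dS), a recent whole-genome duplication confined to the
#' Glycine max lineage (dS 0.10), and one tandem duplication on the
#' Medicago lineage (dS 0.04, adjacent placement).
#'
#' @return List of [duplicationEvent()]s.
#' @export
defaultEvents <- function() {
  list(duplicationEvent("ancient", "root", 0.65),
       duplicationEvent("wgd", "Gm", 0.10),
       duplicationEvent("tandem", "Mt", 0.04))
}

#' Specify a gene-family simulation
#'
#' @param species_tree Nested-list species tree (see
#'   [defaultSpeciesTree()]), branch lengths in dS units.
#' @param events List of [duplicationEvent()]s applied to every family.
#' @param n_families Number of independent families to simulate.
#' @param codon_length Codons per gene (>= 30).
#' @param omega Nonsynonymous/synonymous rate ratio (Ka/Ks) used to scale
#'   nonsynonymous change; `>= 0`.
#' @param loss_prob Probability that a duplicate-descended gene copy is
#'   lost in any given terminal lineage (in `[0, 1]`).
#' @param seed Integer RNG seed; family `i` uses stream `seed + i`.
#' @return A `list` of class `"SimulationSpec"`.
#' @export
simulationSpec <- function(species_tree = defaultSpeciesTree(),
                           events = list(), n_families = 20L,
                           codon_length = 300L, omega = 0.2,
                           loss_prob = 0.25, seed = 1L) {
  tips <- treeTipNames(species_tree)
  if (anyDuplicated(tips)) stop("species-tree tip names must be unique")
  if (codon_length < 30L) stop("codon_length must be >= 30")
  if (omega < 0) stop("omega must be >= 0")
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must be in [0, 1]")
  nodes <- treeNodeNames(species_tree)
  for (e in events) {
    if (!inherits(e, "DuplicationEvent"))
      stop("events must be built with duplicationEvent()")
    if (e$kind != "ancient" && !(e$lineage %in% nodes))
      stop("event names unknown lineage: ", e$lineage)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed + n_families >= .Machine$integer.max)
    stop("seed must be a (small) integer")
  structure(list(species_tree = species_tree, events = events,
                 n_families = as.integer(n_families),
                 codon_length = as.integer(codon_length),
                 omega = omega, loss_prob = loss_prob, seed = seed),
            class = "SimulationSpec")
}

## random stop-free coding sequence (uniform over sense codons)
randomCodingSequence <- function(n_codons) {
  tab <- codonTables()
  sense <- tab$codons[tab$aa != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Evolve a coding sequence by a target synonymous divergence
#'
#' Applies `round(target_dS * S)` synonymous and
#' `round(omega * target_dS * N)` nonsynonymous single-nucleotide
#' substitutions (S, N: NG86 site counts of the input sequence) at
#' uniformly chosen eligible positions, rejecting any change that would
#' create a stop codon. Substitution types are applied in random
#' interleaved order; repeated hits at a site are allowed.
#'
#' @param parent Coding sequence string (length divisible by 3, no stop
#'   codons).
#' @param target_dS Expected synonymous substitutions per synonymous site
#'   along this branch (>= 0).
#' @param omega Ka/Ks scaling for nonsynonymous change.
#' @return The child sequence (same length as `parent`).
#' @export
evolveCodons <- function(parent, target_dS, omega) {
  if (target_dS < 0) stop("target_dS must be >= 0")
  codons <- splitCodons(parent)
  idx <- codonIndex(codons)
  if (anyNA(idx)) stop("parent contains non-ACGT characters")
  tab <- codonTables()
  stops <- which(tab$aa[idx] == "*")
  if (length(stops))
    stop("parent has internal stop codon at codon ", stops[1L])
  sn <- c(S = sum(tab$site_s[idx]), N = sum(tab$site_n[idx]))
  n_syn <- round(target_dS * sn[["S"]])
  n_non <- round(omega * target_dS * sn[["N"]])
  if (n_syn + n_non == 0) return(parent)

  chars <- strsplit(toupper(parent), "")[[1L]]
  kinds <- sample(c(rep("s", n_syn), rep("n", n_non)))
  L <- length(chars)
  for (kind in kinds) {
    done <- FALSE
    for (attempt in seq_len(2000L)) {
      pos <- sample.int(L, 1L)
      cur <- chars[pos]
      alt <- sample(.nucs[.nucs != cur], 1L)
      cstart <- pos - (pos - 1L) %% 3L
      old_codon <- paste(chars[cstart:(cstart + 2L)], collapse = "")
      new <- chars[cstart:(cstart + 2L)]
      new[pos - cstart + 1L] <- alt
      new_codon <- paste(new, collapse = "")
      old_aa <- tab$aa[match(old_codon, tab$codons)]
      new_aa <- tab$aa[match(new_codon, tab$codons)]
      if (is.na(new_aa) || new_aa == "*") next
      syn <- identical(old_aa, new_aa)
      if ((kind == "s") != syn) next
      chars[pos] <- alt
      done <- TRUE
      break
    }
    if (!done)
      stop("impossible substitution budget: could not place a ",
           if (kind == "s") "synonymous" else "nonsynonymous",
           " substitution (sequence too short or without eligible sites)")
  }
  paste(chars, collapse = "")
}

## --- gene-tree bookkeeping -------------------------------------------

.newGeneTree <- function() {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(); env$brlen <- numeric()
  env$type <- character(); env$kind <- character()
  env$reloc_counter <- 0L
  env
}

.addGtNode <- function(gt, parent, brlen, type, kind = NA_character_) {
  gt$parent <- c(gt$parent, parent)
  gt$brlen <- c(gt$brlen, brlen)
  gt$type <- c(gt$type, type)
  gt$kind <- c(gt$kind, kind)
  length(gt$parent)
}

.gtDepths <- function(gt) {
  n <- length(gt$parent)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    p <- gt$parent[i]
    depth[i] <- gt$brlen[i] + if (p > 0L) depth[p] else 0
  }
  depth
}

.gtAncestors <- function(gt, i) {
  out <- integer(0)
  while (i > 0L) { out <- c(out, i); i <- gt$parent[i] }
  out
}

## duplicate one copy record at its current point; returns list(original, new).
## Non-tandem duplicates relocate to a chromosome token unique to the
## duplication event, so unrelated copies can never become spuriously
## adjacent; tandem duplicates stay on the parent chromosome at the next
## gene-order slot.
.duplicateCopy <- function(gt, copy, kind) {
  d <- .addGtNode(gt, copy$anchor, copy$pending, "duplication", kind)
  orig <- copy; orig$anchor <- d; orig$pending <- 0
  dup <- orig
  dup$ndup <- dup$ndup + 1L
  if (kind == "tandem") {
    dup$ntan <- dup$ntan + 1L
  } else {
    gt$reloc_counter <- gt$reloc_counter + 1L
    dup$reloc <- gt$reloc_counter
  }
  list(orig, dup)
}

#' Simulate one gene family with full truth labels
#'
#' Walks the species tree from a random stop-free root sequence, applying
#' ancient duplications on the root stem (duplicate lineages become
#' outparalogs of each other), whole-genome and tandem duplications on
#' their named lineages (inparalogs), and per-lineage loss of
#' duplicate-descended copies. Deterministic given `(spec$seed,
#' family_index)`.
#'
#' @param spec A [simulationSpec()].
#' @param family_index 1-based family number (also the RNG stream offset).
#' @return A list of class `"SimulatedFamily"` with elements `tips`
#'   (`data.frame`: id, species, chromosome, order_index), `sequences`
#'   (named character vector) and `truth` (`data.frame`: id_a, id_b,
#'   relation, tandem, true_ds, true_dn).
#' @export
simulateFamily <- function(spec, family_index) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed + as.integer(family_index))
  omega <- spec$omega
  gt <- .newGeneTree()
  root <- .addGtNode(gt, 0L, 0, "root")
  copies <- list(list(anchor = root, pending = 0,
                      seq = randomCodingSequence(spec$codon_length),
                      ndup = 0L, ntan = 0L, reloc = 0L))

  ## ancient events on the root stem ------------------------------------
  mean_depth <- mean(treeTipDepths(spec$species_tree))
  anc <- Filter(function(e) e$kind == "ancient", spec$events)
  if (length(anc)) {
    us <- vapply(anc, function(e) max(0, (e$age_dS - 2 * mean_depth) / 2),
                 numeric(1))
    ord <- order(us, decreasing = TRUE)
    t_now <- max(us)
    for (k in ord) {
      dt <- t_now - us[k]
      if (dt > 0)
        copies <- lapply(copies, function(cp) {
          cp$seq <- evolveCodons(cp$seq, dt, omega)
          cp$pending <- cp$pending + dt
          cp
        })
      t_now <- us[k]
      copies <- do.call(c, lapply(copies, .duplicateCopy, gt = gt,
                                  kind = "ancient"))
    }
    if (t_now > 0)
      copies <- lapply(copies, function(cp) {
        cp$seq <- evolveCodons(cp$seq, t_now, omega)
        cp$pending <- cp$pending + t_now
        cp
      })
  }

  lineage_events <- Filter(function(e) e$kind != "ancient", spec$events)
  tips <- list()

  walkBranch <- function(node, copies) {
    ev <- Filter(function(e) e$lineage == node$name, lineage_events)
    len <- node$length
    times <- vapply(ev, function(e) len - e$age_dS / 2, numeric(1))
    if (any(times < 0))
      stop("age_dS of a ", paste(vapply(ev, `[[`, character(1), "kind")[times < 0],
                                 collapse = "/"),
           " event exceeds twice the branch length of lineage ", node$name)
    ord <- order(times)
    t_cur <- 0
    evolveAll <- function(cps, dt) {
      if (dt <= 0) return(cps)
      lapply(cps, function(cp) {
        cp$seq <- evolveCodons(cp$seq, dt, omega)
        cp$pending <- cp$pending + dt
        cp
      })
    }
    for (k in ord) {
      copies <- evolveAll(copies, times[k] - t_cur)
      t_cur <- times[k]
      if (ev[[k]]$kind == "wgd") {
        copies <- do.call(c, lapply(copies, .duplicateCopy, gt = gt,
                                    kind = "wgd"))
      } else {
        pick <- sample.int(length(copies), 1L)
        copies <- c(copies[-pick],
                    .duplicateCopy(gt, copies[[pick]], "tandem"))
      }
    }
    copies <- evolveAll(copies, len - t_cur)
    if (length(node$children) == 0L) {
      for (cp in copies) {
        tipnode <- .addGtNode(gt, cp$anchor, cp$pending, "tip")
        tips[[length(tips) + 1L]] <<- list(
          species = node$name, node = tipnode, seq = cp$seq,
          ndup = cp$ndup, ntan = cp$ntan, reloc = cp$reloc)
      }
    } else {
      recommitted <- lapply(copies, function(cp) {
        s <- .addGtNode(gt, cp$anchor, cp$pending, "speciation")
        cp$anchor <- s; cp$pending <- 0
        cp
      })
      for (child in node$children) walkBranch(child, recommitted)
    }
  }

  ## the species-tree root is itself the first speciation point
  rooted <- lapply(copies, function(cp) {
    s <- .addGtNode(gt, cp$anchor, cp$pending, "speciation")
    cp$anchor <- s; cp$pending <- 0
    cp
  })
  for (child in spec$species_tree$children) walkBranch(child, rooted)

  ## loss of duplicate-descended copies, independently per lineage ------
  keep <- vapply(tips, function(tp) {
    tp$ndup == 0L || stats::runif(1) >= spec$loss_prob
  }, logical(1))
  tips <- tips[keep]

  ## identifiers and positions ------------------------------------------
  species <- vapply(tips, `[[`, character(1), "species")
  ids <- character(length(tips))
  for (sp in unique(species)) {
    w <- which(species == sp)
    ids[w] <- sprintf("%s_f%02d_c%d", sp, family_index, seq_along(w))
  }
  base_chr <- 1L + (as.integer(family_index) - 1L) %% 6L
  chrom <- vapply(tips, function(tp) {
    if (tp$reloc > 0L) sprintf("chr%d_d%d", base_chr, tp$reloc)
    else sprintf("chr%d", base_chr)
  }, character(1))
  order_index <- vapply(tips, function(tp) 10L * as.integer(family_index) + tp$ntan,
                        integer(1))

  tip_df <- data.frame(id = ids, species = species, chromosome = chrom,
                       order_index = order_index, stringsAsFactors = FALSE)
  seqs <- stats::setNames(vapply(tips, `[[`, character(1), "seq"), ids)

  ## truth table ---------------------------------------------------------
  depth <- .gtDepths(gt)
  n <- length(tips)
  truth <- if (n >= 2L) {
    rows <- vector("list", choose(n, 2L)); m <- 0L
    for (i in seq_len(n - 1L)) {
      anc_i <- .gtAncestors(gt, tips[[i]]$node)
      for (j in seq(i + 1L, n)) {
        anc_j <- .gtAncestors(gt, tips[[j]]$node)
        mrca <- anc_i[match(TRUE, anc_i %in% anc_j)]
        relation <- switch(gt$type[mrca],
          speciation = "ortholog",
          duplication = if (gt$kind[mrca] == "ancient") "outparalog"
                        else "inparalog",
          stop("unexpected MRCA node type: ", gt$type[mrca]))
        ds <- depth[tips[[i]]$node] + depth[tips[[j]]$node] - 2 * depth[mrca]
        pair <- sort(c(ids[i], ids[j]))
        m <- m + 1L
        rows[[m]] <- data.frame(
          id_a = pair[1L], id_b = pair[2L], relation = relation,
          tandem = identical(gt$kind[mrca], "tandem"),
          true_ds = ds, true_dn = omega * ds, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  } else {
    data.frame(id_a = character(0), id_b = character(0),
               relation = character(0), tandem = logical(0),
               true_ds = numeric(0), true_dn = numeric(0))
  }

  structure(list(tips = tip_df, sequences = seqs, truth = truth),
            class = "SimulatedFamily")
}

#' Simulate a full multi-family dataset in memory
#'
#' @param spec A [simulationSpec()].
#' @return List with elements `cds` (a [CdsSet-class] over all families),
#'   `truth` (truth-pair table with a `family` column) and `families`
#'   (id-to-family map).
#' @export
simulateDataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  fams <- lapply(seq_len(spec$n_families), function(i) simulateFamily(spec, i))
  tip_df <- do.call(rbind, lapply(fams, `[[`, "tips"))
  seqs <- do.call(c, lapply(fams, `[[`, "sequences"))
  truth <- do.call(rbind, lapply(seq_along(fams), function(i) {
    tr <- fams[[i]]$truth
    if (nrow(tr)) cbind(family = sprintf("f%02d", i), tr)
    else cbind(family = character(0), tr)
  }))
  fam_map <- do.call(rbind, lapply(seq_along(fams), function(i) {
    data.frame(id = fams[[i]]$tips$id, family = sprintf("f%02d", i),
               stringsAsFactors = FALSE)
  }))
  cds <- CdsSet(Biostrings::DNAStringSet(seqs),
                species = tip_df$species,
                chromosome = tip_df$chromosome,
                order_index = tip_df$order_index)
  list(cds = cds, truth = truth, families = fam_map)
}

#' Write a simulated dataset to disk
#'
#' Writes one CDS FASTA per species, a 4-column gene-position TSV
#' (id, species, chromosome, order_index), the truth-pair TSV and a JSON
#' manifest echoing the specification. Re-running with the same seed
#' reproduces byte-identical files.
#'
#' @param spec A [simulationSpec()].
#' @param out_dir Output directory (created if absent).
#' @return (Invisibly) the manifest list.
#' @export
generateDataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  ds <- simulateDataset(spec)
  info <- cdsInfo(ds$cds)
  fasta_files <- character(0)
  for (sp in sort(unique(info$species))) {
    f <- file.path(out_dir, paste0(sp, ".cds.fasta"))
    sub <- ds$cds[which(info$species == sp)]
    Biostrings::writeXStringSet(cdsSeqs(sub), f, width = 70L)
    fasta_files <- c(fasta_files, f)
  }
  pos_f <- file.path(out_dir, "positions.tsv")
  utils::write.table(info, pos_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_f <- file.path(out_dir, "truth_pairs.tsv")
  utils::write.table(ds$truth, truth_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    generator = "KsScape::generateDataset",
    seed = spec$seed, n_families = spec$n_families,
    codon_length = spec$codon_length, omega = spec$omega,
    loss_prob = spec$loss_prob,
    species_tree = treeNewick(spec$species_tree),
    events = lapply(spec$events, unclass),
    n_sequences = nrow(info),
    files = c(basename(fasta_files), basename(pos_f), basename(truth_f))
  )
  man_f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
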