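## Homolog discovery: BLAST-like nucleotide search, hit filtering,
## bidirectional best hits, family clustering and the gene-selection rule.
##
## The search engine screens sequence pairs for a shared exact 11-mer seed
## and scores survivors with a full Smith-Waterman local alignment
## (match +2, mismatch -3, affine gaps 5/2); E-values follow the
## Karlin-Altschul formula E = K * m * n * exp(-lambda * score) with the
## query length as m and the summed CDS length of the subject's species
## database as n. A 12-column tabular reader/writer lets precomputed hits
## from a real BLAST run be substituted.

#' Search configuration
#'
#' @param match,mismatch Match / mismatch scores.
#' @param gap_open,gap_extend Positive affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters for the configured scoring.
#' @param seed_length Exact-match word length required before a pair is
#'   aligned at all.
#' @return A list of class `"SearchConfig"`.
#' @export
searchConfig <- function(match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2, lambda = 0.625, K = 0.41,
                         seed_length = 11L) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 seed_length = as.integer(seed_length)),
            class = "SearchConfig")
}

.hitColumns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

## candidate unordered pairs sharing at least one exact k-mer
.seedPairs <- function(seqs, k) {
  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  idx <- rep.int(seq_along(seqs), lengths(words))
  by_word <- split(idx, unlist(words))
  pairs <- lapply(by_word, function(v) {
    if (length(v) < 2L) return(NULL)
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(pairs)
}

#' All-vs-all local similarity search
#'
#' For every query, finds local alignments against all database sequences
#' that share an exact seed word, and reports them in standard 12-column
#' tabular form. Self-hits (identical ids) are excluded by default.
#'
#' @param db A [CdsSet-class] (the database; species-wise lengths set the
#'   E-value search space).
#' @param queries A [CdsSet-class]; defaults to `db` (all-vs-all).
#' @param config A [searchConfig()].
#' @param self_hits Keep hits of a sequence against itself?
#' @return `data.frame` with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
allVsAllSearch <- function(db, queries = db, config = searchConfig(),
                           self_hits = FALSE) {
  stopifnot(methods::is(db, "CdsSet"), methods::is(queries, "CdsSet"))
  if (length(queries) == 0L) stop("empty query set")
  if (length(db) == 0L) stop("empty database")
  same <- identical(cdsIds(db), cdsIds(queries))
  db_chr <- as.character(cdsSeqs(db))
  q_chr <- if (same) db_chr else as.character(cdsSeqs(queries))
  db_sp <- cdsSpecies(db)
  db_len_by_sp <- tapply(nchar(db_chr), db_sp[cdsIds(db)], sum)

  ## candidate ordered (query, subject) index pairs via seed sharing;
  ## for the symmetric all-vs-all case each unordered pair is aligned
  ## once and reported in both directions
  if (same) {
    up <- .seedPairs(db_chr, config$seed_length)
    cand <- up
    if (self_hits)
      cand <- rbind(cand, cbind(seq_along(db_chr), seq_along(db_chr)))
  } else {
    all_seqs <- c(q_chr, db_chr)
    up <- .seedPairs(all_seqs, config$seed_length)
    nq <- length(q_chr)
    keep <- (up[, 1L] <= nq) != (up[, 2L] <= nq)
    up <- up[keep, , drop = FALSE]
    qi <- ifelse(up[, 1L] <= nq, up[, 1L], up[, 2L])
    si <- ifelse(up[, 1L] <= nq, up[, 2L], up[, 1L]) - nq
    cand <- cbind(qi, si)
    if (!self_hits) {
      drop <- cdsIds(queries)[cand[, 1L]] == cdsIds(db)[cand[, 2L]]
      cand <- cand[!drop, , drop = FALSE]
    }
  }
  if (nrow(cand) == 0L)
    return(stats::setNames(data.frame(character(0), character(0), numeric(0),
                                      integer(0), integer(0), integer(0),
                                      integer(0), integer(0), integer(0),
                                      integer(0), numeric(0), numeric(0)),
                           .hitColumns))

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)
  qids <- cdsIds(queries); sids <- cdsIds(db)

  ## align per subject group, vectorised over queries
  out <- vector("list", 0L)
  for (s in unique(cand[, 2L])) {
    qs <- cand[cand[, 2L] == s, 1L]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(q_chr[qs]),
      Biostrings::DNAString(db_chr[s]),
      type = "local", substitutionMatrix = submat,
      gapOpening = config$gap_open, gapExtension = config$gap_extend)
    sc <- Biostrings::score(pa)
    alen <- Biostrings::nchar(pa)
    nmis <- Biostrings::nmismatch(pa)
    nmat <- Biostrings::nmatch(pa)
    ins <- Biostrings::indel(pa)
    gapo <- lengths(ins@insertion) + lengths(ins@deletion)
    n_s <- nchar(db_chr[s])
    sp_s <- db_sp[[sids[s]]]
    bits <- (config$lambda * sc - log(config$K)) / log(2)
    fwd <- data.frame(
      qseqid = qids[qs], sseqid = sids[s],
      pident = round(100 * nmat / alen, 2), length = alen,
      mismatch = nmis, gapopen = gapo,
      qstart = Biostrings::start(Biostrings::pattern(pa)),
      qend = Biostrings::end(Biostrings::pattern(pa)),
      sstart = Biostrings::start(Biostrings::subject(pa)),
      send = Biostrings::end(Biostrings::subject(pa)),
      evalue = config$K * nchar(q_chr[qs]) *
        as.numeric(db_len_by_sp[[sp_s]]) * exp(-config$lambda * sc),
      bitscore = round(bits, 1),
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- fwd
    if (same) {
      ## mirror direction from the same alignment
      not_self <- qs != s
      rev <- fwd[not_self, , drop = FALSE]
      rev[, c("qseqid", "sseqid")] <- fwd[not_self, c("sseqid", "qseqid")]
      rev[, c("qstart", "qend")] <- fwd[not_self, c("sstart", "send")]
      rev[, c("sstart", "send")] <- fwd[not_self, c("qstart", "qend")]
      rev$evalue <- config$K * n_s *
        as.numeric(db_len_by_sp[vapply(qids[qs[not_self]],
                                       function(q) db_sp[[q]],
                                       character(1))]) *
        exp(-config$lambda * sc[not_self])
      out[[length(out) + 1L]] <- rev
    }
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$qseqid, hits$evalue, hits$sseqid), ]
  rownames(hits) <- NULL
  hits
}

#' Filter homology hits on identity and E-value
#'
#' Keeps hits with `pident >= min_identity` and `evalue <= max_e` (both
#' boundaries inclusive), preserving input order.
#'
#' @param hits 12-column hit table ([allVsAllSearch()] or [readHits()]).
#' @param min_identity Minimum percent identity (default 70).
#' @param max_e Maximum E-value (default 1e-50).
#' @return The filtered hit table.
#' @export
filterHits <- function(hits, min_identity = 70, max_e = 1e-50) {
  if (!is.finite(min_identity) || !is.finite(max_e))
    stop("thresholds must be finite")
  hits[hits$pident >= min_identity & hits$evalue <= max_e, , drop = FALSE]
}

#' Bidirectional best hits
#'
#' Reports the pair `(a, b)` iff `b` is `a`'s best hit within `b`'s
#' species and `a` is `b`'s best hit within `a`'s species. Best = highest
#' bit score, ties broken by lower E-value, then higher percent identity,
#' then lexicographically smallest subject id.
#'
#' @param hits A (filtered) hit table.
#' @param species_of Named character vector mapping sequence id to species.
#' @return `data.frame` with columns `id_a`, `id_b` (each row sorted so
#'   `id_a < id_b`), deduplicated and sorted.
#' @export
bidirectionalBestHits <- function(hits, species_of) {
  ids <- unique(c(hits$qseqid, hits$sseqid))
  missing <- ids[!(ids %in% names(species_of))]
  if (length(missing))
    stop("id(s) missing from species mapping: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  h <- hits[species_of[hits$qseqid] != species_of[hits$sseqid], , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0)))
  key <- paste(h$qseqid, species_of[h$sseqid], sep = "\r")
  ord <- order(key, -h$bitscore, h$evalue, -h$pident, h$sseqid)
  h <- h[ord, ]
  best <- h[!duplicated(paste(h$qseqid, species_of[h$sseqid], sep = "\r")), ]
  fwd <- paste(best$qseqid, best$sseqid, sep = "\r")
  rev <- paste(best$sseqid, best$qseqid, sep = "\r")
  rec <- best[fwd %in% rev, ]
  if (nrow(rec) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0)))
  a <- pmin(rec$qseqid, rec$sseqid)
  b <- pmax(rec$qseqid, rec$sseqid)
  out <- unique(data.frame(id_a = a, id_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Assemble gene families as connected components of the hit graph
#'
#' Each anchor's family is the connected component of the undirected
#' filtered-hit graph that contains it (anchors without passing hits form
#' singleton families); anchors falling in one component are merged into a
#' single family carrying all their labels.
#'
#' @param anchor_ids Character vector of anchor sequence ids.
#' @param hits A filtered hit table.
#' @return `data.frame` with columns `family` (id of the family: the
#'   anchor labels joined with `"+"`), `id` (member), one row per member.
#' @export
clusterFamilies <- function(anchor_ids, hits) {
  edges <- unique(data.frame(a = hits$qseqid, b = hits$sseqid,
                             stringsAsFactors = FALSE))
  verts <- unique(c(anchor_ids, edges$a, edges$b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  anchor_comp <- comp[anchor_ids]
  out <- lapply(sort(unique(anchor_comp)), function(cm) {
    members <- sort(names(comp)[comp == cm])
    fam <- paste(sort(anchor_ids[anchor_comp == cm]), collapse = "+")
    data.frame(family = fam, id = members, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep families with homologs in enough species
#'
#' @param families Family table from [clusterFamilies()].
#' @param species_of Named id-to-species map.
#' @param min_species Minimum number of distinct species (default 4).
#' @param total_species Total species surveyed (default 6); `min_species`
#'   may not exceed it.
#' @return The families table restricted to qualifying families.
#' @export
selectQualifyingGenes <- function(families, species_of, min_species = 4L,
                                  total_species = 6L) {
  if (min_species > total_species)
    stop("min_species (", min_species, ") exceeds total_species (",
         total_species, ")")
  sp <- species_of[families$id]
  n_sp <- tapply(sp, families$family, function(x) length(unique(x)))
  keep <- names(n_sp)[n_sp >= min_species]
  out <- families[families$family %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count species represented in each family
#'
#' @param families Family table.
#' @param species_of Named id-to-species map.
#' @return Named integer vector, families to species counts.
#' @export
familySpeciesCounts <- function(families, species_of) {
  sp <- species_of[families$id]
  vapply(split(sp, families$family), function(x) length(unique(x)),
         integer(1))
}
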