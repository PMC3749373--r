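#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib KsScape, .registration = TRUE
NULL

#' CdsSet: a collection of coding sequences with positional metadata
#'
#' Wraps a [Biostrings::DNAStringSet] of CDS together with a per-sequence
#' table carrying species, chromosome and gene-order index (the rank of
#' the gene on its chromosome), the evidence used for tandem detection.
#'
#' @slot seqs A `DNAStringSet`, names are the sequence ids.
#' @slot info A `data.frame` with columns `id`, `species`, `chromosome`
#'   (`NA` when unplaced) and `order_index` (`NA` when unplaced).
#' @export
setClass("CdsSet", representation(seqs = "ANY", info = "data.frame"))

setValidity("CdsSet", function(object) {
  info <- object@info
  msgs <- character(0)
  if (!methods::is(object@seqs, "DNAStringSet"))
    msgs <- c(msgs, "seqs must be a DNAStringSet")
  else {
    if (anyDuplicated(names(object@seqs)))
      msgs <- c(msgs, "sequence ids must be unique")
    if (any(Biostrings::width(object@seqs) == 0L))
      msgs <- c(msgs, "sequences must be non-empty")
    if (!identical(names(object@seqs), info$id))
      msgs <- c(msgs, "info$id must match sequence names in order")
  }
  needed <- c("id", "species", "chromosome", "order_index")
  if (!all(needed %in% names(info)))
    msgs <- c(msgs, paste("info must have columns:", paste(needed, collapse = ", ")))
  else {
    placed <- !is.na(info$chromosome)
    if (any(placed & (is.na(info$order_index) | info$order_index < 1)))
      msgs <- c(msgs, "order_index must be >= 1 where chromosome is known")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CdsSet
#'
#' @param seqs A `DNAStringSet` or named character vector of A/C/G/T CDS.
#' @param species Character vector of species codes, one per sequence.
#' @param chromosome Optional chromosome names (`NA` = unplaced).
#' @param order_index Optional 1-based gene rank on the chromosome.
#' @return A [CdsSet-class] object.
#' @export
CdsSet <- function(seqs, species, chromosome = NA_character_,
                   order_index = NA_integer_) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  info <- data.frame(
    id = names(seqs),
    species = rep_len(as.character(species), length(seqs)),
    chromosome = rep_len(as.character(chromosome), length(seqs)),
    order_index = rep_len(as.integer(order_index), length(seqs)),
    stringsAsFactors = FALSE
  )
  methods::new("CdsSet", seqs = seqs, info = info)
}

#' @describeIn CdsSet Number of sequences.
#' @param x A `CdsSet`.
#' @export
setMethod("length", "CdsSet", function(x) length(x@seqs))

#' Accessors for CdsSet
#'
#' `cdsIds`, `cdsSpecies`, `cdsSeqs` and `cdsInfo` return the ids, the
#' named species vector (usable as an id-to-species map), the underlying
#' `DNAStringSet` and the metadata table.
#'
#' @param x A [CdsSet-class].
#' @name cds-accessors
NULL

#' @rdname cds-accessors
#' @export
cdsIds <- function(x) x@info$id

#' @rdname cds-accessors
#' @export
cdsSpecies <- function(x) stats::setNames(x@info$species, x@info$id)

#' @rdname cds-accessors
#' @export
cdsSeqs <- function(x) x@seqs

#' @rdname cds-accessors
#' @export
cdsInfo <- function(x) x@info

#' @describeIn CdsSet Subset by index, id or logical vector.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "CdsSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@info$id)
  methods::new("CdsSet", seqs = x@seqs[i],
               info = x@info[i, , drop = FALSE])
})

setMethod("show", "CdsSet", function(object) {
  sp <- table(object@info$species)
  cat("CdsSet with", length(object), "coding sequences from",
      length(sp), "species\n")
  cat("  ", paste(sprintf("%s:%d", names(sp), as.integer(sp)),
                  collapse = "  "), "\n")
})

#' CodonAlignment: a codon-aware (multiple) alignment
#'
#' Equal-length gapped rows over `{A,C,G,T,-}` in which every gap run has
#' length divisible by three, plus the complete-deletion column mask used
#' by all downstream distance and rate estimation. `keptColumns` is `NA`
#' until [completeDeletion()] has been applied.
#'
#' @slot ids Ordered sequence ids.
#' @slot rows Named character vector of gapped rows.
#' @slot kept Integer vector of surviving nucleotide-column indices
#'   (grouped in codon triples), or `NA_integer_` before complete deletion.
#' @export
setClass("CodonAlignment",
         representation(ids = "character", rows = "character",
                        kept = "integer"))

setValidity("CodonAlignment", function(object) {
  msgs <- character(0)
  if (!identical(names(object@rows), object@ids))
    msgs <- c(msgs, "row names must equal ids")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L) msgs <- c(msgs, "rows must have equal length")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CodonAlignment-class
#' @param ids,rows,kept See slots.
#' @export
CodonAlignment <- function(ids, rows, kept = NA_integer_) {
  methods::new("CodonAlignment", ids = as.character(ids),
               rows = stats::setNames(toupper(as.character(rows)), ids),
               kept = as.integer(kept))
}

#' Accessors for CodonAlignment
#'
#' @param x A [CodonAlignment-class].
#' @return `alignmentIds`: the ids; `alignmentRows`: named character
#'   vector of gapped rows; `keptColumns`: integer columns surviving
#'   complete deletion (`NA` before [completeDeletion()]);
#'   `alignmentWidth`: number of columns.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
alignmentIds <- function(x) x@ids

#' @rdname alignment-accessors
#' @export
alignmentRows <- function(x) x@rows

#' @rdname alignment-accessors
#' @export
keptColumns <- function(x) x@kept

#' @rdname alignment-accessors
#' @export
alignmentWidth <- function(x) if (length(x@rows)) nchar(x@rows[[1L]]) else 0L

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@ids), "rows x",
      alignmentWidth(object), "columns")
  if (!anyNA(object@kept))
    cat(";", length(object@kept), "columns kept after complete deletion")
  cat("\n")
})

#' Remove alignment gaps from one row
#'
#' @param row A gapped sequence string.
#' @return The ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' KsDistribution: binned proportional Ks histogram for one species pair
#'
#' Proportions are bin counts divided by the number of pairs with a
#' defined Ks; values at or beyond `ks_max` are truncated into the
#' `overflow` count so that `sum(proportions) + overflow/nPairs == 1`.
#'
#' @slot speciesPair Character vector of length 2 (sorted; equal entries
#'   for a within-species distribution).
#' @slot breaks Bin edges from 0 to `ks_max`.
#' @slot counts Integer bin counts.
#' @slot proportions Bin counts / `nPairs`.
#' @slot nPairs Number of contributing pairs (defined, non-excluded Ks).
#' @slot overflow Number of pairs with `Ks >= ks_max`.
#' @export
setClass("KsDistribution",
         representation(speciesPair = "character", breaks = "numeric",
                        counts = "integer", proportions = "numeric",
                        nPairs = "integer", overflow = "integer"))

setValidity("KsDistribution", function(object) {
  msgs <- character(0)
  if (length(object@speciesPair) != 2L)
    msgs <- c(msgs, "speciesPair must have length 2")
  if (any(object@proportions < 0))
    msgs <- c(msgs, "proportions must be non-negative")
  if (object@nPairs > 0L) {
    tot <- sum(object@proportions) + object@overflow / object@nPairs
    if (abs(tot - 1) > 1e-9)
      msgs <- c(msgs, "proportions + overflow share must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "KsDistribution", function(object) {
  cat("KsDistribution", paste(object@speciesPair, collapse = "-"), ":",
      object@nPairs, "pairs in", length(object@counts), "bins (",
      object@overflow, "overflow )\n")
})

#' @rdname KsDistribution-class
#' @param x A `KsDistribution`.
#' @export
ksProportions <- function(x) x@proportions

#' @rdname KsDistribution-class
#' @export
ksBreaks <- function(x) x@breaks

#' @rdname KsDistribution-class
#' @export
ksPairCount <- function(x) x@nPairs

#' @rdname KsDistribution-class
#' @export
ksSpeciesPair <- function(x) x@speciesPair
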