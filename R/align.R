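## Codon-aware pairwise and progressive multiple alignment.
##
## Coding sequences are aligned in amino-acid space (BLOSUM62, affine
## gaps, defaults 10 / 0.5) and back-translated, so every gap run has a
## length divisible by three and codon frames are preserved; rate
## estimation then operates on complete-deletion codon columns only.

.aaAlphabet <- function() {
  ## rows/cols of BLOSUM62 in Biostrings
  rownames(.blosum62())
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Translate a coding sequence, trimming one trailing stop codon
#'
#' @param x Nucleotide string, length divisible by 3.
#' @return List with `aa` (amino-acid string), `codons` (codon vector
#'   after trimming) and `trimmed` (logical).
#' @export
translateCds <- function(x) {
  codons <- splitCodons(x)
  aa <- codonAA(codons)
  if (anyNA(aa))
    stop("non-ACGT codon at codon position ", which(is.na(aa))[1L])
  n <- length(codons)
  trimmed <- FALSE
  if (aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n]; trimmed <- TRUE }
  if (any(aa == "*"))
    stop("internal stop codon at codon position ", which(aa == "*")[1L])
  list(aa = paste(aa, collapse = ""), codons = codons, trimmed = trimmed)
}

## amino-acid string -> 1-based codes into BLOSUM62
.aaCodes <- function(aa) {
  codes <- match(strsplit(aa, "")[[1L]], .aaAlphabet())
  if (anyNA(codes)) stop("amino acid outside the BLOSUM62 alphabet")
  codes
}

## back-translate one profile row (codes with 0 = gap) using its codons
.backTranslate <- function(col_src, codons) {
  out <- character(length(col_src))
  out[col_src == 0L] <- "---"
  out[col_src != 0L] <- codons[col_src[col_src != 0L]]
  paste(out, collapse = "")
}

#' Codon-aware pairwise global alignment
#'
#' Aligns the translations of two coding sequences globally (BLOSUM62,
#' affine gap penalties in amino-acid space) and back-translates, so that
#' gaps come in whole codons.
#'
#' @param a,b Coding sequences (strings, or named length-1 character
#'   vectors; names become row ids). Lengths must be divisible by 3; a
#'   single trailing stop codon is trimmed, internal stops are an error.
#' @param gap_open,gap_ext Positive gap penalties in amino-acid space.
#' @return A [CodonAlignment-class] with two rows (kept columns unset).
#' @export
alignPairCodonAware <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  ids <- c(if (!is.null(names(a))) names(a)[1L] else "seq_a",
           if (!is.null(names(b))) names(b)[1L] else "seq_b")
  ta <- translateCds(as.character(a)); tb <- translateCds(as.character(b))
  pa <- matrix(.aaCodes(ta$aa), nrow = 1L)
  pb <- matrix(.aaCodes(tb$aa), nrow = 1L)
  al <- .cppProfileAlign(pa, pb, .blosum62(), gap_open, gap_ext)
  rows <- c(.backTranslate(al$a, ta$codons), .backTranslate(al$b, tb$codons))
  out <- CodonAlignment(ids, rows)
  attr(out, "aa_score") <- al$score
  out
}

## k-mer sharing distance between amino-acid strings (guide-tree metric)
.kmerDistance <- function(aas, k = 3L) {
  kmers <- lapply(aas, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  n <- length(aas)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- length(intersect(kmers[[i]], kmers[[j]]))
      denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

#' Progressive codon-aware multiple alignment
#'
#' Builds a guide tree from amino-acid k-mer distances (average-linkage
#' clustering) and merges profiles leaf-to-root with codon-aware
#' profile-profile alignment (BLOSUM62 sum-of-pairs scores, affine gaps).
#' Output rows are returned in input order.
#'
#' @param seqs Named character vector of coding sequences, or a
#'   [CdsSet-class].
#' @param gap_open,gap_ext Positive gap penalties in amino-acid space.
#' @return A [CodonAlignment-class] (kept columns unset). A single input
#'   sequence is returned unchanged with a warning.
#' @export
progressiveMsa <- function(seqs, gap_open = 10, gap_ext = 0.5) {
  if (methods::is(seqs, "CdsSet"))
    seqs <- stats::setNames(as.character(cdsSeqs(seqs)), cdsIds(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n < 1L) stop("no sequences")
  if (n == 1L) {
    warning("single sequence: returned unchanged")
    return(CodonAlignment(names(seqs), as.character(seqs)))
  }
  tr <- lapply(seqs, function(s) translateCds(s))
  aas <- vapply(tr, `[[`, character(1), "aa")

  ## leaf profiles: 1-row code matrices + per-row codon stores
  leaves <- lapply(seq_len(n), function(i) {
    list(mat = matrix(.aaCodes(aas[i]), nrow = 1L),
         members = i,
         cols = list(matrix(seq_len(nchar(aas[i])), nrow = 1L)))
  })
  ## cols: per profile a matrix rows x columns of source codon indices
  ## (0 = gap), used for back-translation at the end
  for (i in seq_len(n))
    leaves[[i]]$cols <- matrix(seq_len(ncol(leaves[[i]]$mat)), nrow = 1L)

  if (n == 2L) {
    merges <- matrix(c(-1L, -2L), nrow = 1L)
  } else {
    hc <- stats::hclust(stats::as.dist(.kmerDistance(aas)), method = "average")
    merges <- hc$merge
  }

  blos <- .blosum62()
  mergeProfiles <- function(p1, p2) {
    al <- .cppProfileAlign(p1$mat, p2$mat, blos, gap_open, gap_ext)
    L <- length(al$a)
    expand <- function(p, src) {
      m <- matrix(0L, nrow(p$mat), L)
      cm <- matrix(0L, nrow(p$mat), L)
      nz <- src != 0L
      m[, nz] <- p$mat[, src[nz], drop = FALSE]
      cm[, nz] <- p$cols[, src[nz], drop = FALSE]
      list(m = m, cm = cm)
    }
    e1 <- expand(p1, al$a); e2 <- expand(p2, al$b)
    list(mat = rbind(e1$m, e2$m),
         members = c(p1$members, p2$members),
         cols = rbind(e1$cm, e2$cm))
  }
  nodes <- vector("list", max(1L, nrow(merges)))
  getNode <- function(k) if (k < 0L) leaves[[-k]] else nodes[[k]]
  for (r in seq_len(nrow(merges))) {
    nodes[[r]] <- mergeProfiles(getNode(merges[r, 1L]), getNode(merges[r, 2L]))
  }
  final <- nodes[[nrow(merges)]]

  ord <- order(final$members)
  rows <- vapply(seq_along(ord), function(k) {
    r <- ord[k]
    i <- final$members[r]
    .backTranslate(final$cols[r, ], tr[[i]]$codons)
  }, character(1))
  CodonAlignment(names(seqs)[final$members[ord]], rows)
}

#' Apply the complete-deletion column mask
#'
#' Marks as kept exactly those codon columns (nucleotide triples) in which
#' no row carries a gap or an ambiguous base; all downstream distance and
#' rate estimation uses only these columns. Removal is by whole codons so
#' site counting stays codon-consistent; ambiguity codes (N and friends)
#' are treated as gaps.
#'
#' @param msa A [CodonAlignment-class].
#' @return The alignment with `keptColumns` filled in.
#' @export
completeDeletion <- function(msa) {
  stopifnot(methods::is(msa, "CodonAlignment"))
  rows <- alignmentRows(msa)
  w <- alignmentWidth(msa)
  if (w %% 3L != 0L) stop("alignment width is not a multiple of 3")
  ch <- do.call(rbind, strsplit(rows, ""))
  good <- matrix(ch %in% c("A", "C", "G", "T"), nrow = nrow(ch))
  col_ok <- apply(good, 2L, all)
  codon_ok <- col_ok[seq(1L, w, 3L)] & col_ok[seq(2L, w, 3L)] &
    col_ok[seq(3L, w, 3L)]
  if (!any(codon_ok))
    stop("no codon column survives complete deletion; ",
         "pairwise-deletion estimation is not supported")
  kept <- as.integer(t(outer((which(codon_ok) - 1L) * 3L, 1:3, `+`)))
  methods::initialize(msa, kept = kept)
}
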