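## Pairwise distances and synonymous / nonsynonymous substitution rates.
##
## The estimator is Nei-Gojobori (1986)-style counting: per-codon
## synonymous site fractions (stop-codon alternatives excluded from both
## numerator and denominator), difference counts averaged over all
## stop-free single-step mutational pathways, and the Jukes-Cantor
## proportion-to-distance transform d = -(3/4) log(1 - (4/3) p) applied to
## the synonymous and nonsynonymous proportions separately.

#' Synonymous and nonsynonymous site counts of a coding sequence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites with the NG86
#' convention: at each codon position the synonymous fraction is the number
#' of the three single-nucleotide alternatives that preserve the amino
#' acid, divided by the number of alternatives that are not stop codons;
#' the nonsynonymous fraction is its complement so that S + N equals three
#' times the number of codons.
#'
#' @param x A coding nucleotide string (no gaps), length divisible by 3,
#'   or a character vector of codons.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' countSites("GGGAAATTT")
#' @export
countSites <- function(x) {
  codons <- if (length(x) == 1L && nchar(x[1L]) > 3L) splitCodons(x) else toupper(x)
  idx <- codonIndex(codons)
  if (anyNA(idx))
    stop("non-ACGT codon(s) at position(s): ",
         paste(which(is.na(idx)), collapse = ", "))
  tab <- codonTables()
  if (any(tab$aa[idx] == "*"))
    stop("stop codon at codon position(s): ",
         paste(which(tab$aa[idx] == "*"), collapse = ", "))
  s <- sum(tab$site_s[idx])
  c(S = s, N = 3 * length(codons) - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For codons differing at k positions, the k! orderings of single-step
#' changes are enumerated; pathways passing through a stop codon are
#' excluded, and the synonymous / nonsynonymous step counts are averaged
#' over the remaining pathways. If every pathway is blocked by a stop, the
#' direct differences are counted, all labelled nonsynonymous.
#'
#' @param codon_a,codon_b Single codons (3-letter A/C/G/T strings).
#' @return Named numeric vector `c(sd = ..., nd = ...)`.
#' @examples
#' countDifferences("GGG", "GGA")  # synonymous Gly -> Gly
#' countDifferences("TTT", "TTA")  # nonsynonymous Phe -> Leu
#' @export
countDifferences <- function(codon_a, codon_b) {
  ia <- codonIndex(toupper(codon_a)); ib <- codonIndex(toupper(codon_b))
  if (is.na(ia) || is.na(ib)) stop("codons must be 3-letter A/C/G/T strings")
  tab <- codonTables()
  if (is.na(tab$sd[ia, ib])) stop("stop codons are not comparable")
  c(sd = tab$sd[ia, ib], nd = tab$nd[ia, ib])
}

#' Jukes-Cantor correction of an observed proportion of differences
#'
#' @param p Proportion(s) of differing sites in `[0, 1]`.
#' @return `-(3/4) * log(1 - (4/3) * p)`; `NA` where the log argument is
#'   non-positive (saturation).
#' @export
jukesCantor <- function(p) {
  arg <- 1 - (4 / 3) * p
  ifelse(arg > 0, -0.75 * log(arg), NA_real_)
}

#' Observed proportion of differing sites between two aligned rows
#'
#' @param row_a,row_b Equal-length gapped sequences (strings or character
#'   vectors of single characters).
#' @param kept_columns Integer vector of column indices to compare
#'   (typically the complete-deletion survivors).
#' @return Proportion of compared positions that differ.
#' @export
pDistance <- function(row_a, row_b, kept_columns) {
  a <- if (length(row_a) == 1L) strsplit(toupper(row_a), "")[[1L]] else toupper(row_a)
  b <- if (length(row_b) == 1L) strsplit(toupper(row_b), "")[[1L]] else toupper(row_b)
  if (length(a) != length(b)) stop("rows differ in length")
  if (length(kept_columns) == 0L) stop("no columns to compare")
  sum(a[kept_columns] != b[kept_columns]) / length(kept_columns)
}

## internal: NG86 on two gap-free codon index vectors
.ng86Core <- function(ia, ib) {
  tab <- codonTables()
  s_a <- sum(tab$site_s[ia]); s_b <- sum(tab$site_s[ib])
  L3 <- 3 * length(ia)
  S <- (s_a + s_b) / 2
  N <- L3 - S
  sd <- sum(tab$sd[cbind(ia, ib)])
  nd <- sum(tab$nd[cbind(ia, ib)])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  ks <- jukesCantor(ps)
  ka <- jukesCantor(pn)
  list(S = S, N = N, Sd = sd, Nd = nd, ps = ps, pn = pn,
       Ks = ks, Ka = ka,
       saturated_s = is.na(ks), saturated_n = is.na(ka))
}

#' Nei-Gojobori rates for one pair of aligned coding sequences
#'
#' Computes p-distance, Jukes-Cantor distance, NG86 site and difference
#' counts and the corrected Ka and Ks over the complete-deletion codon
#' columns of a pairwise (or larger) alignment.
#'
#' @param a,b Gapped or gap-free coding sequences (strings). When
#'   `kept_columns` is missing the sequences must be gap-free and of equal
#'   length; otherwise only the kept columns are used.
#' @param kept_columns Integer nucleotide-column indices free of gaps in
#'   both rows, grouped in codon triples (as produced by
#'   [completeDeletion()]).
#' @param min_codons Minimum number of compared codons (default 10);
#'   fewer is an error.
#' @return A one-row `data.frame` with columns `p_dist`, `d`, `S`, `N`,
#'   `Sd`, `Nd`, `Ks`, `Ka`, `ka_ks`, `saturated_s`, `saturated_n`,
#'   `n_codons`. `ka_ks` is `NA` when `Ks` is zero or either rate is
#'   saturated.
#' @examples
#' ng86("GGGAAATTT", "GGAAAATTT", min_codons = 3)
#' @export
ng86 <- function(a, b, kept_columns = NULL, min_codons = 10L) {
  av <- strsplit(toupper(as.character(a)), "")[[1L]]
  bv <- strsplit(toupper(as.character(b)), "")[[1L]]
  if (length(av) != length(bv)) stop("sequences differ in aligned length")
  if (is.null(kept_columns)) {
    if (any(av == "-") || any(bv == "-"))
      stop("gapped input requires kept_columns from completeDeletion()")
    kept_columns <- seq_along(av)
  }
  k <- as.integer(kept_columns)
  if (length(k) %% 3L != 0L)
    stop("kept_columns must cover whole codons (length divisible by 3)")
  n_codons <- length(k) / 3L
  if (n_codons < min_codons)
    stop("only ", n_codons, " compared codons; at least ", min_codons,
         " required (set min_codons to override)")
  ca <- paste0(av[k[seq(1, length(k), 3)]], av[k[seq(2, length(k), 3)]],
               av[k[seq(3, length(k), 3)]])
  cb <- paste0(bv[k[seq(1, length(k), 3)]], bv[k[seq(2, length(k), 3)]],
               bv[k[seq(3, length(k), 3)]])
  ia <- codonIndex(ca); ib <- codonIndex(cb)
  if (anyNA(ia) || anyNA(ib))
    stop("ambiguous or gapped codons among kept columns")
  tab <- codonTables()
  if (any(tab$aa[ia] == "*") || any(tab$aa[ib] == "*"))
    stop("stop codon among compared codons")
  core <- .ng86Core(ia, ib)
  p <- sum(av[k] != bv[k]) / length(k)
  ka_ks <- if (!core$saturated_s && !core$saturated_n && core$Ks > 0)
    core$Ka / core$Ks else NA_real_
  data.frame(
    p_dist = p, d = jukesCantor(p),
    S = core$S, N = core$N, Sd = core$Sd, Nd = core$Nd,
    Ks = core$Ks, Ka = core$Ka, ka_ks = ka_ks,
    saturated_s = core$saturated_s, saturated_n = core$saturated_n,
    n_codons = n_codons
  )
}

#' Pairwise rates for every sequence pair of a family alignment
#'
#' Applies [ng86()] to every unordered pair of rows of a codon alignment,
#' using its complete-deletion columns.
#'
#' @param msa A [CodonAlignment] that has been through [completeDeletion()].
#' @param min_codons Passed to [ng86()].
#' @return A `data.frame` with one row per unordered pair (`id_a`, `id_b`
#'   in lexicographic order) and the [ng86()] columns.
#' @export
computeAllPairs <- function(msa, min_codons = 10L) {
  stopifnot(methods::is(msa, "CodonAlignment"))
  ids <- alignmentIds(msa)
  if (length(ids) < 2L) stop("alignment must have at least 2 rows")
  kept <- keptColumns(msa)
  if (anyNA(kept)) stop("run completeDeletion() before computeAllPairs()")
  rows <- alignmentRows(msa)
  out <- vector("list", choose(length(ids), 2L))
  m <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      m <- m + 1L
      rec <- ng86(rows[[i]], rows[[j]], kept_columns = kept,
                  min_codons = min_codons)
      pair <- sort(c(ids[i], ids[j]))
      out[[m]] <- cbind(data.frame(id_a = pair[1L], id_b = pair[2L]), rec)
    }
  }
  do.call(rbind, out)
}
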