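## Codon-level lookup tables for NG86-style counting.
##
## Tables are derived once per session from the standard genetic code
## (Biostrings::GENETIC_CODE) and cached in a package environment:
##   - per-codon synonymous site counts (stop alternatives excluded from
##     both numerator and denominator of the per-position fraction), and
##   - per-codon-pair synonymous/nonsynonymous difference counts averaged
##     over all single-step mutational pathways that avoid stop codons.

.ksscape_cache <- new.env(parent = emptyenv())

.nucs <- c("A", "C", "G", "T")

#' All 64 codons in a fixed order
#' @noRd
allCodons <- function() {
  g <- expand.grid(p3 = .nucs, p2 = .nucs, p1 = .nucs,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Amino acid of a codon under the standard code ("*" for stop)
#' @noRd
codonAA <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

## all orderings of 1..k (k <= 3); tiny, no dependency needed
.perms <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

## Build and cache all codon tables.
codonTables <- function() {
  if (!is.null(.ksscape_cache$tables)) return(.ksscape_cache$tables)
  codons <- allCodons()
  aa <- codonAA(codons)
  n <- length(codons)
  stopifnot(n == 64L)

  ## synonymous site fraction per codon position ------------------------
  syn_frac <- matrix(NA_real_, n, 3, dimnames = list(codons, NULL))
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    cd <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      alts <- .nucs[.nucs != cd[pos]]
      alt_codons <- vapply(alts, function(nt) {
        x <- cd; x[pos] <- nt; paste(x, collapse = "")
      }, character(1))
      alt_aa <- codonAA(alt_codons)
      nonstop <- alt_aa != "*"
      if (!any(nonstop)) {
        syn_frac[i, pos] <- 0
      } else {
        syn_frac[i, pos] <- sum(alt_aa[nonstop] == aa[i]) / sum(nonstop)
      }
    }
  }
  site_s <- rowSums(syn_frac)          # per-codon synonymous sites
  site_n <- 3 - site_s                 # same-denominator complement

  ## pathway-averaged difference counts per codon pair ------------------
  sd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  nd_mat <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  codon_chars <- strsplit(codons, "")
  for (i in seq_len(n)) {
    if (aa[i] == "*") next
    for (j in seq_len(n)) {
      if (aa[j] == "*") next
      if (i == j) { sd_mat[i, j] <- 0; nd_mat[i, j] <- 0; next }
      a <- codon_chars[[i]]; b <- codon_chars[[j]]
      diffs <- which(a != b)
      k <- length(diffs)
      tot_s <- 0; tot_n <- 0; n_paths <- 0L
      for (ord in .perms(k)) {
        cur <- a
        cur_aa <- aa[i]
        path_s <- 0; path_n <- 0
        ok <- TRUE
        for (pos in diffs[ord]) {
          nxt <- cur; nxt[pos] <- b[pos]
          nxt_codon <- paste(nxt, collapse = "")
          nxt_aa <- codonAA(nxt_codon)
          if (nxt_aa == "*") { ok <- FALSE; break }
          if (nxt_aa == cur_aa) path_s <- path_s + 1 else path_n <- path_n + 1
          cur <- nxt; cur_aa <- nxt_aa
        }
        if (ok) {
          tot_s <- tot_s + path_s; tot_n <- tot_n + path_n
          n_paths <- n_paths + 1L
        }
      }
      if (n_paths > 0L) {
        sd_mat[i, j] <- tot_s / n_paths
        nd_mat[i, j] <- tot_n / n_paths
      } else {
        ## every pathway runs through a stop: count the direct
        ## differences, all labelled nonsynonymous
        sd_mat[i, j] <- 0
        nd_mat[i, j] <- k
      }
    }
  }

  .ksscape_cache$tables <- list(
    codons = codons, aa = aa,
    syn_frac = syn_frac, site_s = site_s, site_n = site_n,
    sd = sd_mat, nd = nd_mat
  )
  .ksscape_cache$tables
}

#' Split a coding sequence into codons
#'
#' @param x A single nucleotide string (A/C/G/T), length divisible by 3.
#' @return Character vector of codons.
#' @noRd
splitCodons <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (n == 0L || n %% 3L != 0L)
    stop("sequence length (", n, ") is not a positive multiple of 3")
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

## index of codons into the 64-codon tables; NA for anything non-ACGT
codonIndex <- function(codons) {
  match(codons, codonTables()$codons)
}

#' Positions (1-based codon index) of stop codons in a codon vector
#' @noRd
stopPositions <- function(codons) {
  which(codonAA(codons) == "*")
}
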