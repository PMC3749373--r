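# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force, separately from
# the package's lookup-table implementations.

NUCS <- c("A", "C", "G", "T")

aaOf <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

randomCds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# brute-force pathway enumeration for codon difference counting
oraclePathCounts <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  diffs <- which(av != bv)
  k <- length(diffs)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(1) else if (k == 2) list(1:2, 2:1) else
    list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  tot_s <- tot_n <- 0; n_ok <- 0
  for (ord in perms) {
    cur <- av; s <- 0; n <- 0; ok <- TRUE
    for (pos in diffs[ord]) {
      nxt <- cur; nxt[pos] <- bv[pos]
      if (aaOf(paste(nxt, collapse = "")) == "*") { ok <- FALSE; break }
      if (aaOf(paste(cur, collapse = "")) == aaOf(paste(nxt, collapse = "")))
        s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(sd = 0, nd = k))
  c(sd = tot_s / n_ok, nd = tot_n / n_ok)
}

# brute-force NG86 site count for one codon
oracleSiteCount <- function(codon) {
  cv <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(NUCS, cv[pos])
    alt_cod <- vapply(alts, function(nt) {
      x <- cv; x[pos] <- nt; paste(x, collapse = "")
    }, character(1))
    alt_aa <- aaOf(alt_cod)
    keep <- alt_aa != "*"
    if (any(keep)) s <- s + sum(alt_aa[keep] == aaOf(codon)) / sum(keep)
  }
  s
}

# random sense codon
randomSenseCodon <- function() {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sample(sense, 1)
}

# introduce exactly k random substitutions into a nucleotide string
mutateSites <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(NUCS, v[p]), 1)
  paste(v, collapse = "")
}

# small simulated family stacked into a complete-deletion alignment
stackFamily <- function(fam) {
  completeDeletion(CodonAlignment(names(fam$sequences), fam$sequences))
}
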