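## Readers and writers for the package's external formats: per-species
## CDS FASTA, 4-column gene-position TSV, GFF3 gene features, and the
## 12-column tabular hit format.

#' Read per-species CDS FASTA files into a CdsSet
#'
#' @param files Named character vector of FASTA paths; names are the
#'   species codes.
#' @param positions Optional position table (see [readPositions()]) used
#'   to fill chromosome and order index.
#' @return A [CdsSet-class].
#' @export
readCdsFasta <- function(files, positions = NULL) {
  if (is.null(names(files)) || any(names(files) == ""))
    stop("`files` must be named by species")
  sets <- lapply(files, Biostrings::readDNAStringSet)
  seqs <- do.call(c, unname(sets))
  ## FASTA headers may carry descriptions; the id is the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  species <- rep(names(files), vapply(sets, length, integer(1)))
  cds <- CdsSet(seqs, species = species)
  if (!is.null(positions)) cds <- attachPositions(cds, positions)
  cds
}

#' Read a 4-column gene-position table
#'
#' Columns: `id`, `species`, `chromosome`, `order_index` (1-based gene
#' rank on the chromosome), tab-separated with a header.
#'
#' @param path File path.
#' @return `data.frame` with those four columns.
#' @export
readPositions <- function(path) {
  pos <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  needed <- c("id", "species", "chromosome", "order_index")
  if (!all(needed %in% names(pos)))
    stop("position table must have columns: ", paste(needed, collapse = ", "))
  pos[needed]
}

#' Attach positional metadata to a CdsSet
#'
#' @param cds A [CdsSet-class].
#' @param positions Position table ([readPositions()] /
#'   [gff3Positions()]); ids absent from it stay unplaced.
#' @return The updated `CdsSet`.
#' @export
attachPositions <- function(cds, positions) {
  info <- cdsInfo(cds)
  m <- match(info$id, positions$id)
  info$chromosome <- ifelse(is.na(m), info$chromosome,
                            as.character(positions$chromosome[m]))
  info$order_index <- ifelse(is.na(m), info$order_index,
                             as.integer(positions$order_index[m]))
  methods::initialize(cds, info = info)
}

#' Derive gene-order positions from a GFF3 file
#'
#' Reads gene features (1-based inclusive coordinates) and ranks genes per
#' seqid by start coordinate to obtain the order index.
#'
#' @param path GFF3 file path.
#' @param species Species code to record.
#' @param feature_type Feature type to use (default `"gene"`).
#' @param id_attribute Attribute holding the gene id (default `"ID"`).
#' @return Position `data.frame` (`id`, `species`, `chromosome`,
#'   `order_index`).
#' @export
gff3Positions <- function(path, species, feature_type = "gene",
                          id_attribute = "ID") {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    df <- data.frame(
      id = as.character(S4Vectors::mcols(gr)[[id_attribute]]),
      chromosome = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr), stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, integer(1)) == 9L]
    typ <- vapply(f, `[[`, character(1), 3L)
    f <- f[typ == feature_type]
    getattr <- function(attrs) {
      m <- regmatches(attrs, regexec(paste0(id_attribute, "=([^;]+)"), attrs))[[1L]]
      if (length(m) == 2L) m[2L] else NA_character_
    }
    df <- data.frame(
      id = vapply(f, function(x) getattr(x[9L]), character(1)),
      chromosome = vapply(f, `[[`, character(1), 1L),
      start = as.integer(vapply(f, `[[`, character(1), 4L)),
      stringsAsFactors = FALSE)
  }
  df <- df[order(df$chromosome, df$start), ]
  df$order_index <- stats::ave(df$start, df$chromosome,
                               FUN = seq_along)
  data.frame(id = df$id, species = species, chromosome = df$chromosome,
             order_index = as.integer(df$order_index),
             stringsAsFactors = FALSE)
}

#' Read / write 12-column tabular homology hits
#'
#' The column order is the standard tabular alignment output: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore. Files have no header, as produced by common
#' search tools.
#'
#' @param path File path.
#' @return `readHits`: the hit `data.frame`.
#' @export
readHits <- function(path) {
  h <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(h) != 12L) stop("expected 12 tab-separated columns")
  names(h) <- .hitColumns
  h
}

#' @rdname readHits
#' @param hits Hit table.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits[.hitColumns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
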