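## Neighbor-joining trees, codon bootstrap supports, and the one- vs
## two-cluster partition used to separate orthologs from outparalogs.
##
## NJ is implemented here so that the tie-break (smallest (i, j) index
## pair in the Q matrix) and the clamping of negative branch-length
## estimates to zero are fully specified and deterministic; trees are
## returned as ape "phylo" objects and round-trip through Newick via ape.

#' Jukes-Cantor distance matrix of an alignment
#'
#' Pairwise p-distances over the complete-deletion columns, JC-corrected
#' by default. Saturated pairs (p >= 3/4) are clamped just below the
#' singularity rather than returned as `Inf` so that tree building stays
#' defined.
#'
#' @param msa A [CodonAlignment-class] after [completeDeletion()].
#' @param model `"jc"` (default) or `"p"` for the raw proportion.
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
distanceMatrix <- function(msa, model = c("jc", "p")) {
  model <- match.arg(model)
  kept <- keptColumns(msa)
  if (anyNA(kept)) stop("run completeDeletion() first")
  rows <- alignmentRows(msa)
  ch <- do.call(rbind, strsplit(rows, ""))[, kept, drop = FALSE]
  n <- nrow(ch)
  d <- matrix(0, n, n, dimnames = list(alignmentIds(msa), alignmentIds(msa)))
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(i + 1L, n)) {
      p <- sum(ch[i, ] != ch[j, ]) / ncol(ch)
      v <- if (model == "p") p else {
        pc <- min(p, 0.7499)
        -0.75 * log(1 - (4 / 3) * pc)
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on the Q criterion. Ties in Q are broken by
#' the smallest (row, column) index pair, so the result is deterministic;
#' negative branch-length estimates are clamped to zero.
#'
#' @param dm Symmetric, non-negative distance matrix with zero diagonal
#'   and ids as dimnames (2 taxa give a single edge).
#' @return An unrooted `phylo` object.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(nrow(dm)))
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(dm)
  tips <- rownames(dm)
  if (n < 2L) stop("need at least 2 taxa")
  clamp <- function(x) pmax(x, 0)

  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = clamp(c(dm[1, 2] / 2, dm[1, 2] / 2)),
                 tip.label = tips, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }

  ## active nodes carry their phylo node ids; tips are 1..n, internal
  ## nodes are numbered n+2, n+3, ... (n+1 is reserved for the root
  ## trifurcation created at the end)
  active_id <- seq_len(n)
  D <- dm
  next_internal <- n + 2L
  edges <- matrix(integer(0), 0L, 2L)
  elen <- numeric(0)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## smallest (i, j), i < j, among minima
    qmin <- min(Q)
    hit <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, active_id[i]), c(u, active_id[j]))
    elen <- c(elen, clamp(li), clamp(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active_id <- c(active_id[keep], u)
    D <- D2
  }

  ## final three nodes join at the root trifurcation (node n+1)
  root <- n + 1L
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  edges <- rbind(edges, c(root, active_id[1]), c(root, active_id[2]),
                 c(root, active_id[3]))
  elen <- c(elen, clamp(l1), clamp(l2), clamp(l3))

  ## renumber internal nodes so ape conventions hold (root = n+1 already;
  ## other internals appear as targets before sources)
  tree <- list(edge = edges, edge.length = elen, tip.label = tips,
               Nnode = n - 2L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Bootstrap supports from codon-column resampling
#'
#' Resamples codon columns (not single nucleotides, to respect coding
#' structure) of the complete-deletion alignment with replacement,
#' rebuilds the distance matrix and NJ tree per replicate, and reports
#' for each internal edge of the original tree the percentage of
#' replicates containing the same bipartition.
#'
#' @param msa A [CodonAlignment-class] after [completeDeletion()].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed RNG seed (resampling is deterministic given it).
#' @param model Distance model passed to [distanceMatrix()].
#' @return The NJ tree of the full alignment with node labels holding
#'   bootstrap percentages (root label empty).
#' @export
bootstrapSupports <- function(msa, n_replicates = 1000L, seed = 1L,
                              model = "jc") {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  kept <- keptColumns(msa)
  if (anyNA(kept)) stop("run completeDeletion() first")
  ids <- alignmentIds(msa)
  n <- length(ids)
  rows <- alignmentRows(msa)
  ch <- do.call(rbind, strsplit(rows, ""))[, kept, drop = FALSE]
  n_cod <- ncol(ch) / 3L

  ## per-codon mismatch counts for every pair: n_cod x n_pairs
  pairs <- utils::combn(n, 2L)
  mism <- matrix(0L, n_cod, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    neq <- ch[pairs[1, k], ] != ch[pairs[2, k], ]
    mism[, k] <- neq[seq(1, length(neq), 3)] + neq[seq(2, length(neq), 3)] +
      neq[seq(3, length(neq), 3)]
  }

  toDist <- function(pvec) {
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[t(pairs)] <- pvec
    d[t(pairs)[, 2:1, drop = FALSE]] <- pvec
    if (model == "jc") {
      pc <- pmin(d, 0.7499)
      d <- -0.75 * log(1 - (4 / 3) * pc)
      diag(d) <- 0
    }
    d
  }

  main <- njTree(toDist(colSums(mism) / (3 * n_cod)))
  if (n < 4L) {
    main$node.label <- rep("", main$Nnode)
    return(main)
  }

  set.seed(as.integer(seed))
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n_cod, n_cod, replace = TRUE)
    pvec <- colSums(mism[idx, , drop = FALSE]) / (3 * n_cod)
    reps[[b]] <- njTree(toDist(pvec))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_replicates)
  lab <- as.character(supports)
  lab[1L] <- ""   # root trifurcation, not a bipartition
  main$node.label <- lab
  main
}

## tips on the far side of the edge ending in `node`
.cladeTips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .cladeTips, tree = tree))
}

#' Partition a gene tree into one or two clusters
#'
#' Formalizes the visual one- vs two-cluster reading of a family tree:
#' the candidate split is the longest internal edge (ties broken by
#' higher bootstrap support, then by the lexicographically smallest tip
#' set). The split is accepted -- yielding two clusters interpreted as
#' lineages from a pre-speciation duplication -- only when its support
#' reaches `min_support` and the two sides share at least one species
#' (the signature of outparalogy: a one-cluster family has no
#' outparalogs). Without species information the fallback requirement is
#' at least two tips on each side.
#'
#' @param tree A `phylo` with bootstrap node labels
#'   ([bootstrapSupports()]).
#' @param species_of Named id-to-species map (strongly recommended).
#' @param min_support Minimum bootstrap percentage (default 50).
#' @return List with `n_clusters` (1 or 2), `clusters` (list of tip-id
#'   vectors), and for an accepted split `edge_length` and `support`.
#' @export
splitTwoClusters <- function(tree, species_of = NULL, min_support = 50) {
  n_tip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  one <- list(n_clusters = 1L, clusters = list(all_tips),
              edge_length = NA_real_, support = NA_real_)
  if (n_tip < 3L || is.null(tree$edge.length)) return(one)
  internal <- which(tree$edge[, 1] > n_tip & tree$edge[, 2] > n_tip)
  if (length(internal) == 0L) return(one)
  if (is.null(tree$node.label) && min_support > 0)
    stop("tree has no bootstrap supports; run bootstrapSupports() first")

  sup_of <- function(e) {
    child <- tree$edge[e, 2]
    lab <- tree$node.label[child - n_tip]
    suppressWarnings(as.numeric(lab))
  }
  lens <- tree$edge.length[internal]
  sups <- vapply(internal, sup_of, numeric(1))
  sides <- lapply(internal, function(e) sort(.cladeTips(tree, tree$edge[e, 2])))
  side_key <- vapply(sides, paste, character(1), collapse = ",")
  ord <- order(-lens, -ifelse(is.na(sups), -1, sups), side_key)
  best <- ord[1L]
  side_a <- sides[[best]]
  side_b <- setdiff(all_tips, side_a)
  sup <- sups[best]
  if (is.na(sup) || sup < min_support) return(one)
  ok <- if (!is.null(species_of)) {
    length(intersect(unique(species_of[side_a]),
                     unique(species_of[side_b]))) > 0L
  } else {
    length(side_a) >= 2L && length(side_b) >= 2L
  }
  if (!ok) return(one)
  list(n_clusters = 2L,
       clusters = list(sort(side_a), sort(side_b)),
       edge_length = lens[best], support = sup)
}

#' Write / read a gene tree in Newick format
#'
#' Bootstrap supports are stored as internal node labels; branch lengths
#' are written with six decimals.
#'
#' @param tree A `phylo`.
#' @param path Output file.
#' @return `writeGeneTree`: the path, invisibly. `readGeneTree`: a
#'   `phylo`.
#' @export
writeGeneTree <- function(tree, path) {
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeGeneTree
#' @export
readGeneTree <- function(path) {
  ape::read.tree(path)
}
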