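## Ortholog / inparalog / outparalog classification and tandem detection.
##
## The decision table combines species identity with the tree partition:
## same species + same cluster -> inparalog (duplicated after
## speciation); same species + different clusters -> outparalog
## (duplicated before speciation); different species + same cluster ->
## ortholog; different species + different clusters -> outparalog. When
## only one cluster exists, same-species pairs fall back to a Ks
## threshold (default 0.40, between the speciation peak near 0.4 and the
## outparalog average near 0.5).

#' Flag tandem-duplicate pairs from gene-order adjacency
#'
#' A pair is tandem iff both genes are placed, share species and
#' chromosome, and their gene-order indices differ by at most
#' `max_order_gap`.
#'
#' @param pairs `data.frame` with columns `id_a`, `id_b`.
#' @param positions Position table (`id`, `species`, `chromosome`,
#'   `order_index`), e.g. [cdsInfo()] of a [CdsSet-class].
#' @param max_order_gap Maximum order-index difference (default 1).
#' @return Logical vector, one flag per row of `pairs` (symmetric in the
#'   pair ordering). Pairs with missing positions are `FALSE` with one
#'   warning.
#' @export
detectTandem <- function(pairs, positions, max_order_gap = 1L) {
  ma <- match(pairs$id_a, positions$id)
  mb <- match(pairs$id_b, positions$id)
  chr_a <- positions$chromosome[ma]; chr_b <- positions$chromosome[mb]
  oi_a <- positions$order_index[ma]; oi_b <- positions$order_index[mb]
  sp_a <- positions$species[ma]; sp_b <- positions$species[mb]
  unknown <- is.na(ma) | is.na(mb) | is.na(chr_a) | is.na(chr_b) |
    is.na(oi_a) | is.na(oi_b)
  if (any(unknown))
    warning(sum(unknown), " pair(s) lack positions; tandem = FALSE for them")
  out <- !unknown & sp_a == sp_b & chr_a == chr_b &
    abs(oi_a - oi_b) <= max_order_gap
  out[is.na(out)] <- FALSE
  out
}

#' Classify one pair from its evidence
#'
#' @param same_species Logical.
#' @param same_cluster Logical, or `NA` when the family has a single
#'   cluster (or no tree).
#' @param ks Pairwise Ks (`NA` when undefined/saturated).
#' @param ks_outparalog_threshold Same-species Ks above which a
#'   one-cluster pair is called an outparalog (default 0.40).
#' @return `"ortholog"`, `"inparalog"` or `"outparalog"`.
#' @export
classifyPair <- function(same_species, same_cluster, ks,
                         ks_outparalog_threshold = 0.40) {
  if (is.na(same_cluster)) {
    ## single-cluster family: Ks decides same-species pairs
    if (!same_species) return("ortholog")
    if (is.na(ks)) return("inparalog")  # cluster evidence only
    return(if (ks > ks_outparalog_threshold) "outparalog" else "inparalog")
  }
  if (same_species) {
    if (same_cluster) "inparalog" else "outparalog"
  } else {
    if (same_cluster) "ortholog" else "outparalog"
  }
}

#' Classify every pair of a family
#'
#' @param rates Pairwise rate table of the family ([computeAllPairs()]).
#' @param partition Cluster partition from [splitTwoClusters()], or
#'   `NULL` when no tree is available (all cluster evidence `NA`).
#' @param species_of Named id-to-species map.
#' @param positions Optional position table for tandem flags.
#' @param ks_outparalog_threshold See [classifyPair()].
#' @param max_order_gap See [detectTandem()].
#' @return `data.frame`: `id_a`, `id_b`, `relation`, `tandem`,
#'   `same_species`, `same_cluster`, `ks`, `order_gap`.
#' @export
classifyFamilyPairs <- function(rates, partition, species_of,
                                positions = NULL,
                                ks_outparalog_threshold = 0.40,
                                max_order_gap = 1L) {
  if (is.null(partition) && all(is.na(rates$Ks)))
    stop("need a cluster partition or defined Ks values to classify")
  cluster_of <- NULL
  if (!is.null(partition) && partition$n_clusters == 2L) {
    cluster_of <- c(stats::setNames(rep(1L, length(partition$clusters[[1]])),
                                    partition$clusters[[1]]),
                    stats::setNames(rep(2L, length(partition$clusters[[2]])),
                                    partition$clusters[[2]]))
  }
  same_sp <- species_of[rates$id_a] == species_of[rates$id_b]
  same_cl <- if (is.null(cluster_of)) rep(NA, nrow(rates)) else
    cluster_of[rates$id_a] == cluster_of[rates$id_b]
  relation <- vapply(seq_len(nrow(rates)), function(i) {
    classifyPair(same_sp[i], same_cl[i], rates$Ks[i],
                 ks_outparalog_threshold)
  }, character(1))
  tandem <- if (is.null(positions)) rep(FALSE, nrow(rates)) else
    detectTandem(rates, positions, max_order_gap)
  order_gap <- if (is.null(positions)) rep(NA_integer_, nrow(rates)) else {
    oa <- positions$order_index[match(rates$id_a, positions$id)]
    ob <- positions$order_index[match(rates$id_b, positions$id)]
    as.integer(abs(oa - ob))
  }
  data.frame(id_a = rates$id_a, id_b = rates$id_b,
             relation = relation, tandem = tandem,
             same_species = unname(same_sp), same_cluster = unname(same_cl),
             ks = rates$Ks, order_gap = order_gap,
             stringsAsFactors = FALSE)
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Score classified pairs against a truth table
#'
#' @param classified Table with `id_a`, `id_b`, `relation` and optionally
#'   `tandem`.
#' @param truth Truth table with the same columns (e.g. from
#'   [simulateDataset()]).
#' @return List: `accuracy` (overall), `tandem_accuracy` (`NA` if either
#'   table lacks tandem flags), `by_relation` (`data.frame` of per-label
#'   precision/recall), `confusion` (table), `n_pairs`.
#' @export
evaluateAgainstTruth <- function(classified, truth) {
  kc <- .pairKey(classified$id_a, classified$id_b)
  kt <- .pairKey(truth$id_a, truth$id_b)
  common <- intersect(kc, kt)
  if (length(common) == 0L) stop("classified and truth tables share no pairs")
  pred <- classified$relation[match(common, kc)]
  ref <- truth$relation[match(common, kt)]
  labels <- c("ortholog", "inparalog", "outparalog")
  conf <- table(factor(ref, labels), factor(pred, labels),
                dnn = c("truth", "predicted"))
  by_rel <- do.call(rbind, lapply(labels, function(l) {
    tp <- conf[l, l]
    data.frame(relation = l,
               precision = if (sum(conf[, l]) > 0) tp / sum(conf[, l]) else NA_real_,
               recall = if (sum(conf[l, ]) > 0) tp / sum(conf[l, ]) else NA_real_,
               n_truth = sum(conf[l, ]))
  }))
  tandem_acc <- NA_real_
  if (!is.null(classified$tandem) && !is.null(truth$tandem)) {
    pt <- classified$tandem[match(common, kc)]
    rt <- truth$tandem[match(common, kt)]
    tandem_acc <- mean(pt == rt)
  }
  list(accuracy = mean(pred == ref), tandem_accuracy = tandem_acc,
       by_relation = by_rel, confusion = conf, n_pairs = length(common))
}
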