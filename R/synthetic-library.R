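#' Simulate a compound library with planted structural clusters
#'
#' Each cluster is grown from a random seed fingerprint by independent
#' per-bit flips at `flipRate`, so within-cluster Tanimoto similarity
#' exceeds between-cluster similarity in expectation (at `flipRate = 0` all
#' within-cluster similarities are exactly 1). Target annotations are
#' planted so that each target in `targetPanel` is enriched among the
#' clusters assigned to it (annotation probability `enrichedProb` inside
#' its clusters versus `backgroundProb` elsewhere).
#'
#' @param nClusters,clusterSize planted cluster structure (defaults 14
#'   clusters of 9, the scale of a hit-list dendrogram).
#' @param nBits fingerprint width (>= 64; default 256).
#' @param targetPanel character vector of target ids to plant (may be
#'   `NULL` for no annotations).
#' @param seed integer seed.
#' @param flipRate per-bit mutation probability within a cluster.
#' @param bitDensity expected density of set bits in cluster seeds.
#' @param enrichedProb,backgroundProb annotation probabilities inside /
#'   outside a target's clusters.
#' @return a [CompoundLibrary-class]; `libraryTruth()` records the planted
#'   cluster of every compound.
#' @export
generateCompoundLibrary <- function(nClusters = 14, clusterSize = 9,
                                    nBits = 256, targetPanel = NULL, seed = 1,
                                    flipRate = 0.05, bitDensity = 0.15,
                                    enrichedProb = 0.8, backgroundProb = 0.1) {
  if (nBits < 64) stop("nBits must be at least 64")
  set.seed(seed)
  n <- nClusters * clusterSize
  ids <- sprintf("LIB%04d", seq_len(n))
  cluster <- rep(seq_len(nClusters), each = clusterSize)
  fp <- matrix(0L, n, nBits, dimnames = list(ids, NULL))
  for (cl in seq_len(nClusters)) {
    seedFp <- stats::rbinom(nBits, 1L, bitDensity)
    for (i in which(cluster == cl)) {
      flip <- stats::runif(nBits) < flipRate
      fp[i, ] <- ifelse(flip, 1L - seedFp, seedFp)
    }
  }
  ann <- data.frame(compound_id = character(0), target_id = character(0))
  if (length(targetPanel)) {
    ownCluster <- rep(seq_len(nClusters), length.out = length(targetPanel))
    for (j in seq_along(targetPanel)) {
      p <- ifelse(cluster == ownCluster[j], enrichedProb, backgroundProb)
      hit <- stats::runif(n) < p
      ann <- rbind(ann, data.frame(compound_id = ids[hit],
                                   target_id = targetPanel[j]))
    }
  }
  truth <- data.frame(compound_id = ids, cluster = cluster)
  if (length(targetPanel)) {
    truth$planted_target <- targetPanel[match(cluster,
      rep(seq_len(nClusters), length.out = length(targetPanel)))]
  }
  new("CompoundLibrary", fingerprints = fp, annotations = ann, truth = truth)
}

#' @rdname accessors
#' @export
setMethod("fingerprints", "CompoundLibrary", function(x) x@fingerprints)

#' @rdname accessors
#' @export
setMethod("annotations", "CompoundLibrary", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("libraryTruth", "CompoundLibrary", function(x) x@truth)

setMethod("show", "CompoundLibrary", function(object) {
  cat("CompoundLibrary:", nrow(object@fingerprints), "compounds,",
      ncol(object@fingerprints), "fingerprint bits,",
      nrow(object@annotations), "annotations\n")
})
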