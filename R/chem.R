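#' Tanimoto similarity between binary fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints are identically empty:
#' their similarity is defined as 1 (with a warning); set
#' `zeroZero = "zero"` for the alternative convention.
#'
#' @param a,b binary vectors of equal length.
#' @param zeroZero value convention for two all-zero fingerprints.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b, zeroZero = c("one", "zero")) {
  zeroZero <- match.arg(zeroZero)
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints are all-zero; returning the identical-emptiness convention")
    return(if (zeroZero == "one") 1 else 0)
  }
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fp binary matrix, one fingerprint per row.
#' @param zeroZero as in [tanimoto()].
#' @return symmetric similarity matrix.
#' @export
tanimotoMatrix <- function(fp, zeroZero = c("one", "zero")) {
  zeroZero <- match.arg(zeroZero)
  fp <- (fp != 0) * 1L
  inter <- tcrossprod(fp)
  counts <- rowSums(fp)
  un <- outer(counts, counts, "+") - inter
  S <- ifelse(un == 0, if (zeroZero == "one") 1 else 0, inter / pmax(un, 1))
  diag(S) <- 1
  dimnames(S) <- list(rownames(fp), rownames(fp))
  S
}

#' Agglomerative clustering of hit compounds by Tanimoto distance
#'
#' Average-linkage hierarchical clustering on distance `1 - Tanimoto`, cut
#' to exactly `nClusters` labels. Deterministic given the input (merge ties
#' resolved by [stats::hclust]'s smallest-index rule).
#'
#' @param x a [CompoundLibrary-class] or binary fingerprint matrix (rows =
#'   compounds, rownames = ids).
#' @param nClusters number of clusters to cut (>= 1).
#' @return list with `tree` (an `hclust`), `labels` (named cluster
#'   assignment), and `method = "average"`.
#' @export
clusterHits <- function(x, nClusters) {
  fp <- if (is(x, "CompoundLibrary")) fingerprints(x) else x
  if (nClusters < 1) stop("nClusters must be at least 1")
  if (nrow(fp) < nClusters) stop("fewer compounds than requested clusters")
  d <- stats::as.dist(1 - tanimotoMatrix(fp))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = nClusters)
  list(tree = tree, labels = labels, method = "average")
}

#' Guilt-by-association target enrichment over a ranked hit list
#'
#' For each annotated target, the enrichment factor compares the target's
#' annotation frequency among the `topN` ranked compounds with its
#' frequency in the background:
#' `EF = (k / topN) / (K / N)` with `k` annotated compounds in the top set,
#' `K` in the background of size `N`. Significance is assessed by the
#' hypergeometric upper tail and, optionally, by label permutation
#' (resampling size-`topN` compound sets). P-values are Benjamini-Hochberg
#' adjusted across targets. Running several `topN` stringencies tabulates
#' how the enriched-target count shrinks as the hit list is restricted.
#'
#' For discrete statistics the plain permutation p-value
#' `(1 + #{k* >= k}) / (1 + nPerm)` is conservative; `ties = "midp"` gives
#' the mid-p variant and `ties = "random"` the fuzzy p-value (uniform under
#' the null), which is the appropriate choice for calibration studies.
#'
#' @param ranked character vector of compound ids, best first.
#' @param annotations `data.frame` with `compound_id`, `target_id`.
#' @param topN size of the top set (<= length of `ranked`).
#' @param background compound ids forming the background (default: the full
#'   ranked list). Every annotated target must occur in the background.
#' @param nPerm permutations (0 to skip the permutation test).
#' @param ties tie handling for permutation p-values.
#' @param seed RNG seed for permutations.
#' @return `data.frame`, one row per target: `target_id`, `k`, `K`,
#'   `top_n`, `background_n`, `EF`, `p_hyper`, `p_perm` (NA if skipped),
#'   `p_adj` (BH on the hypergeometric p-values).
#' @export
targetEnrichment <- function(ranked, annotations, topN,
                             background = ranked, nPerm = 0,
                             ties = c("conservative", "midp", "random"),
                             seed = 1) {
  ties <- match.arg(ties)
  if (topN > length(ranked)) stop("topN exceeds the ranked list length")
  unknown <- setdiff(annotations$compound_id, background)
  ann <- annotations[annotations$compound_id %in% background, , drop = FALSE]
  targets <- unique(annotations$target_id)
  absent <- setdiff(targets, unique(ann$target_id))
  if (length(absent)) {
    stop("target(s) absent from the background: ", paste(absent, collapse = ", "))
  }
  N <- length(background)
  top <- ranked[seq_len(topN)]
  byTarget <- split(ann$compound_id, ann$target_id)
  res <- do.call(rbind, lapply(names(byTarget), function(tg) {
    annIds <- unique(byTarget[[tg]])
    K <- length(annIds)
    k <- sum(top %in% annIds)
    EF <- (k / topN) / (K / N)
    pHyper <- stats::phyper(k - 1, K, N - K, topN, lower.tail = FALSE)
    data.frame(target_id = tg, k = k, K = K, top_n = topN, background_n = N,
               EF = EF, p_hyper = pHyper, p_perm = NA_real_)
  }))
  if (nPerm > 0) {
    set.seed(seed)
    ks <- matrix(0L, nPerm, nrow(res))
    annSets <- lapply(res$target_id, function(tg) unique(byTarget[[tg]]))
    for (b in seq_len(nPerm)) {
      draw <- sample(background, topN)
      ks[b, ] <- vapply(annSets, function(s) sum(draw %in% s), integer(1))
    }
    res$p_perm <- vapply(seq_len(nrow(res)), function(j) {
      gt <- sum(ks[, j] > res$k[j]); eq <- sum(ks[, j] == res$k[j])
      switch(ties,
        conservative = (1 + gt + eq) / (1 + nPerm),
        midp = (0.5 + gt + 0.5 * eq) / (1 + nPerm),
        # fuzzy p-value: uniform smoothing over the tie mass (incl. the
        # observed draw), exactly uniform under the null
        random = (gt + stats::runif(1) * (eq + 1)) / (1 + nPerm))
    }, numeric(1))
  }
  res$p_adj <- stats::p.adjust(res$p_hyper, method = "BH")
  res[order(-res$EF), , drop = FALSE]
}

#' Normalized binding affinity npKi
#'
#' `npKi = 4 + (-log10(Ki))`, with Ki in the panel's stated unit (default
#' uM; the unit convention is recorded alongside panels, not inferred).
#' A 1 uM Ki maps to 4, 0.1 uM to 5, 10 uM to 3.
#'
#' @param ki Ki values (> 0), scalar, vector or matrix.
#' @return npKi on the same shape; `NA` entries propagate.
#' @examples
#' npKi(c(1, 0.1, 10))  # 4, 5, 3
#' @export
npKi <- function(ki) {
  if (any(ki <= 0, na.rm = TRUE)) stop("Ki must be positive")
  4 - log10(ki)
}

#' Normalize a compound x receptor Ki panel
#'
#' @param panel numeric matrix of Ki values (compound x receptor), `NA`
#'   where unmeasured.
#' @param unit unit the Ki values are expressed in (metadata, recorded on
#'   the result).
#' @return npKi matrix with attribute `unit`.
#' @export
bindingPanel <- function(panel, unit = "uM") {
  out <- npKi(panel)
  attr(out, "unit") <- unit
  out
}
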