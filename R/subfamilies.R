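#' Pairwise identity distances between aligned sequences
#'
#' For each pair of sequences, the distance is 1 minus the fraction of
#' identical residues over the columns where neither sequence has a gap or an
#' 'X'. Pairs sharing fewer than \code{minOverlap} mutually ungapped columns
#' are assigned the maximal distance 1.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param minOverlap minimum number of mutually ungapped columns below which
#'   a pair's distance is set to 1 (default 10).
#' @return a symmetric n x n numeric matrix with zero diagonal, entries in
#'   [0, 1], dimnames = sequence ids.
#' @export
pairwiseDistances <- function(msa, minOverlap = 10L) {
  m <- msa@mat
  n <- nrow(m)
  ok <- m != GAP_CHAR & m != MISSING_CHAR
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nb <- sum(both)
      dij <- if (nb < minOverlap) 1 else 1 - sum(m[i, both] == m[j, both]) / nb
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Cluster alignment sequences into subfamilies
#'
#' Implements the subfamily step of the pipeline: sequences whose distance to
#' every other sequence is at least \code{orphanThreshold} are set aside as
#' orphans; the remainder are clustered by average-linkage hierarchical
#' clustering on the identity distance, and the tree is cut automatically at
#' the largest gap in the sorted merge heights (so the number of subfamilies
#' is not a user parameter). Singleton clusters produced by the cut are
#' reassigned to the nearest (average-distance) multi-member cluster. The
#' query sequence is never discarded: if it qualifies as an orphan it is
#' placed in a singleton subfamily of its own.
#'
#' @param dm distance matrix from \code{\link{pairwiseDistances}}.
#' @param queryIndex 1-based index of the query sequence.
#' @param orphanThreshold minimum-distance floor above which a sequence is an
#'   orphan (default 0.85).
#' @param minSplitGap smallest gap in merge heights that justifies splitting
#'   into more than one subfamily (default 0.1); below it all clustered
#'   sequences form a single subfamily.
#' @return a \linkS4class{SubfamilyPartition}.
#' @export
clusterSubfamilies <- function(dm, queryIndex, orphanThreshold = 0.85,
                               minSplitGap = 0.1) {
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 sequences to cluster")
  minOther <- vapply(seq_len(n), function(i) min(dm[i, -i]), numeric(1L))
  orph <- which(minOther >= orphanThreshold)
  queryOrphan <- queryIndex %in% orph
  orph <- setdiff(orph, queryIndex)
  keep <- setdiff(seq_len(n), c(orph, if (queryOrphan) queryIndex))

  assignments <- integer(n)                       # 0 = orphan
  if (length(keep) == 1L) {
    assignments[keep] <- 1L
  } else if (length(keep) > 1L) {
    hc <- hclust(as.dist(dm[keep, keep, drop = FALSE]), method = "average")
    h <- sort(hc$height)
    k <- 1L
    if (length(h) >= 2L) {
      gaps <- diff(h)
      g <- which.max(gaps)                        # ties: earliest, most clusters
      if (gaps[g] > minSplitGap) k <- length(keep) - g
    }
    cl <- if (k == 1L) rep(1L, length(keep)) else cutree(hc, k = k)
    cl <- reassignSingletons(cl, dm[keep, keep, drop = FALSE])
    assignments[keep] <- cl
  }
  if (queryOrphan) assignments[queryIndex] <- max(assignments) + 1L

  labs <- sort(unique(assignments[assignments > 0L]))
  subf <- lapply(labs, function(l) which(assignments == l))
  ## deterministic order: by smallest member index
  ord <- order(vapply(subf, min, integer(1L)))
  subf <- subf[ord]
  qsub <- which(vapply(subf, function(s) queryIndex %in% s, logical(1L)))
  new("SubfamilyPartition", subfamilies = subf,
      orphans = as.integer(sort(orph)), querySubfamily = as.integer(qsub))
}

## move singleton clusters into the multi-member cluster with the smallest
## average distance; if every cluster is a singleton, collapse to one
reassignSingletons <- function(cl, dm) {
  sizes <- table(cl)
  if (all(sizes == 1L)) return(rep(1L, length(cl)))
  for (i in which(cl %in% as.integer(names(sizes)[sizes == 1L]))) {
    big <- as.integer(names(sizes)[sizes >= 2L])
    avg <- vapply(big, function(l) mean(dm[i, cl == l]), numeric(1L))
    cl[i] <- big[which.min(avg)]
    sizes <- table(cl)
  }
  cl
}
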