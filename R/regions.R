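#' Chain core blocks into candidate regions
#'
#' Greedy left-to-right chaining of sorted, disjoint blocks: consecutive
#' blocks whose inter-block gap (next start minus previous end, in alignment
#' columns) is at most \code{maxGap} join one region; regions whose column
#' span is below \code{minRegionLength} are discarded (a span of exactly
#' \code{minRegionLength} is kept). The region score is the sum of the member
#' block scores.
#'
#' @param blocks data.frame with \code{start}, \code{end}, \code{blockScore}
#'   (0-based half-open column intervals).
#' @param maxGap maximum distance between chained blocks, in columns
#'   (default 40).
#' @param minRegionLength minimum region column span (default 21).
#' @return data.frame of regions: start, end, regionScore, nBlocks.
#' @examples
#' b <- data.frame(start = c(0, 50), end = c(10, 60), blockScore = c(5, 7))
#' chainBlocks(b)                     # gap 40: one region [0, 60)
#' chainBlocks(b, maxGap = 39)        # split; both spans < 21: none kept
#' @export
chainBlocks <- function(blocks, maxGap = 40L, minRegionLength = 21L) {
  stopifnot(maxGap >= 0L, minRegionLength >= 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      regionScore = numeric(0), nBlocks = integer(0))
  if (nrow(blocks) == 0L) return(empty)
  b <- blocks[order(blocks$start, blocks$end), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(b$start[-1L] - b$end[-nrow(b)] > maxGap)))
  out <- do.call(rbind, lapply(split(seq_len(nrow(b)), grp), function(ix) {
    data.frame(start = min(b$start[ix]), end = max(b$end[ix]),
               regionScore = sum(b$blockScore[ix]), nBlocks = length(ix))
  }))
  out <- out[out$end - out$start >= minRegionLength, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a region's alignment columns to sequence (residue) coordinates
#'
#' Maps a 0-based half-open alignment-column interval to the corresponding
#' residue interval on one sequence, clipping gap-only flanks. Residue
#' indices covered by an alignment interval are always contiguous, so the
#' result is a single interval (or no interval when the sequence is entirely
#' gapped across the region).
#'
#' @param start,end alignment-column interval (0-based half-open).
#' @param cmap coordinate map from \code{\link{coordinateMap}}.
#' @return data.frame with columns \code{resStart}, \code{resEnd} (0-based
#'   half-open), with zero rows if the sequence has no residues in the region.
#' @export
regionToSequenceCoords <- function(start, end, cmap) {
  res <- cmap$colToRes[(start + 1L):end]
  res <- res[!is.na(res)]
  if (length(res) == 0L)
    return(data.frame(resStart = integer(0), resEnd = integer(0)))
  data.frame(resStart = min(res), resEnd = max(res) + 1L)
}

#' Filter unrelated sequences and rank the survivors by homology to the query
#'
#' Assembles the per-sequence verdicts: for each subfamily member, the
#' query-related blocks of its subfamily in which the sequence has at least
#' one non-gap, non-'X' residue and is not flagged inconsistent are chained
#' into regions; for each orphan, the query blocks it passed in the
#' posterior-predictive comparison are chained. A sequence is retained iff it
#' has at least one region with score strictly above \code{scoreCutoff}.
#' Retained non-query sequences are ranked by total region score
#' (descending, ties by input order); the query is always retained, unranked,
#' with status \code{"query"}.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param partition a \linkS4class{SubfamilyPartition}.
#' @param blocks marked block data.frame (\code{relatedToQuery} filled).
#' @param verdicts inconsistent-segment data.frame from
#'   \code{\link{flagInconsistentSegments}}.
#' @param orphanVerdicts data.frame from \code{\link{compareOrphansToQuery}}.
#' @param maxGap,minRegionLength chaining parameters (defaults 40 and 21).
#' @param scoreCutoff minimum region score for retention (default 0, strict).
#' @return list with \code{perSequence} (id, status, rank, totalScore) and
#'   \code{regions} (seqId + region columns + sequence coordinates).
#' @export
filterAndRank <- function(msa, partition, blocks, verdicts, orphanVerdicts,
                          maxGap = 40L, minRegionLength = 21L,
                          scoreCutoff = 0) {
  ids <- seqIds(msa)
  n <- length(ids)
  qid <- queryId(msa)
  subfOf <- integer(n)
  for (f in seq_along(partition@subfamilies))
    subfOf[partition@subfamilies[[f]]] <- f

  regionRows <- list()
  status <- character(n)
  totalScore <- numeric(n)

  for (i in seq_len(n)) {
    isOrphan <- i %in% partition@orphans
    myBlocks <- if (isOrphan) {
      ov <- orphanVerdicts[orphanVerdicts$seqId == ids[i] & orphanVerdicts$pass,
                           , drop = FALSE]
      ov[, c("start", "end", "blockScore"), drop = FALSE]
    } else {
      f <- subfOf[i]
      fb <- blocks[blocks$subfamily == f & blocks$relatedToQuery %in% TRUE,
                   , drop = FALSE]
      if (nrow(fb) > 0L) {
        keep <- vapply(seq_len(nrow(fb)), function(b) {
          pr <- segmentPairing(msa, i, fb$start[b], fb$end[b])
          if (is.null(pr)) return(FALSE)       # fully gapped: ineligible
          flagged <- any(verdicts$seqId == ids[i] &
                         verdicts$start == fb$start[b] &
                         verdicts$end == fb$end[b] &
                         verdicts$inconsistent)
          !flagged
        }, logical(1L))
        fb <- fb[keep, , drop = FALSE]
      }
      fb[, c("start", "end", "blockScore"), drop = FALSE]
    }
    reg <- chainBlocks(myBlocks, maxGap = maxGap,
                       minRegionLength = minRegionLength)
    reg <- reg[reg$regionScore > scoreCutoff, , drop = FALSE]
    totalScore[i] <- sum(reg$regionScore)
    retained <- nrow(reg) > 0L
    status[i] <- if (ids[i] == qid) "query"
      else if (retained && isOrphan) "related"
      else if (retained) "related"
      else if (isOrphan) "orphan-removed"
      else "removed"
    if (nrow(reg) > 0L) {
      cmap <- coordinateMap(msa, ids[i])
      sc <- do.call(rbind, lapply(seq_len(nrow(reg)), function(r) {
        x <- regionToSequenceCoords(reg$start[r], reg$end[r], cmap)
        if (nrow(x) == 0L) data.frame(resStart = NA_integer_,
                                      resEnd = NA_integer_) else x
      }))
      regionRows[[length(regionRows) + 1L]] <-
        cbind(data.frame(seqId = ids[i]), reg, sc)
    }
  }

  ranked <- which(status == "related")
  rank <- rep(NA_integer_, n)
  if (length(ranked))
    rank[ranked[order(-totalScore[ranked], ranked)]] <- seq_along(ranked)

  perSequence <- data.frame(id = ids, status = status, rank = rank,
                            totalScore = totalScore)
  regions <- if (length(regionRows)) do.call(rbind, regionRows) else
    data.frame(seqId = character(0), start = integer(0), end = integer(0),
               regionScore = numeric(0), nBlocks = integer(0),
               resStart = integer(0), resEnd = integer(0))
  rownames(regions) <- NULL
  list(perSequence = perSequence, regions = regions)
}
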