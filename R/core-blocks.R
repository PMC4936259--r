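#' Per-column BILD score track for one subfamily
#'
#' Builds, for every alignment column, the residue counts contributed by the
#' subfamily members (gaps and 'X' excluded) and computes the BILD log-odds
#' and its normalized probability. Columns where the subfamily contributes
#' fewer than \code{minObs} residues are forced to probability 0, so a
#' single observation (dominated by the prior) can never certify a block.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param members integer vector of member sequence indices (or character ids).
#' @param mix a \linkS4class{DirichletMixture}.
#' @param subfamily index recorded on the track (default \code{NA}).
#' @param minObs minimum residues per column for a nonzero probability
#'   (default 2).
#' @return a \linkS4class{ScoreTrack}.
#' @export
scoreTrack <- function(msa, members, mix, subfamily = NA_integer_,
                       minObs = 2L) {
  if (length(members) == 0L) stop("members must be non-empty")
  if (is.character(members)) members <- match(members, seqIds(msa))
  counts <- columnCounts(msa, members, alphabet = mix@alphabet)
  sc <- bildScore(counts, mix)
  nObs <- as.integer(colSums(counts))
  prob <- sc$prob
  prob[nObs < minObs] <- 0
  new("ScoreTrack", subfamily = as.integer(subfamily), rawS = sc$S,
      prob = prob, nObs = nObs)
}

#' Detect core blocks from a score track by sliding-window analysis
#'
#' A column is block-covered if it lies in at least one window of
#' \code{window} consecutive columns whose mean normalized score exceeds
#' \code{threshold} (strictly). Maximal runs of covered columns become core
#' blocks; each block therefore spans at least \code{window} columns. A core
#' block is a segment whose mean score is above the threshold, so covered
#' runs whose own mean probability fails the threshold (possible because a
#' single spike column can qualify a window) are discarded. The block score
#' is the sum of the raw BILD log-odds over the block.
#'
#' @param track a \linkS4class{ScoreTrack}.
#' @param window sliding-window length in columns (default 7).
#' @param threshold mean normalized-score threshold (default 0.05, strict
#'   "above").
#' @return data.frame of blocks: subfamily, start, end (0-based half-open),
#'   meanProb, blockScore, relatedToQuery (initialized \code{NA}).
#' @export
detectCoreBlocks <- function(track, window = 7L, threshold = 0.05) {
  stopifnot(window >= 1L, threshold > 0, threshold < 1)
  p <- track@prob
  n <- length(p)
  if (window > n) {
    warning("window (", window, ") exceeds track length (", n,
            "); no blocks detected")
    return(emptyBlockTable())
  }
  means <- as.numeric(stats::filter(p, rep(1 / window, window),
                                    sides = 1))[window:n]
  qual <- means > threshold                     # window i covers [i, i+w-1]
  covered <- logical(n)
  for (i in which(qual)) covered[i:(i + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(emptyBlockTable())
  out <- data.frame(
    subfamily = track@subfamily,
    start = starts[runs] - 1L,
    end = ends[runs],
    meanProb = vapply(runs, function(k) mean(p[starts[k]:ends[k]]), numeric(1L)),
    blockScore = vapply(runs, function(k) sum(track@rawS[starts[k]:ends[k]]),
                        numeric(1L)),
    relatedToQuery = NA)
  out <- out[out$meanProb > threshold, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relatedness between two core blocks that overlap in the alignment
#'
#' Sums the Bayesian column-pair score \code{\link{columnPairScore}} over the
#' columns where the two blocks overlap; the blocks are judged related when
#' the sum is strictly positive. Columns where one subfamily is entirely
#' gapped contribute exactly 0.
#'
#' @param blockA,blockB single-row block data.frames (as returned by
#'   \code{\link{detectCoreBlocks}}) carrying \code{start}/\code{end}.
#' @param countsA,countsB 20 x nCols count matrices of the two blocks'
#'   subfamilies (full alignment width, mixture alphabet row order).
#' @param mix a \linkS4class{DirichletMixture}.
#' @return list with \code{related} (logical) and \code{score} (nats).
#' @export
blockRelatedness <- function(blockA, blockB, countsA, countsB, mix) {
  lo <- max(blockA$start, blockB$start)
  hi <- min(blockA$end, blockB$end)
  if (hi <= lo) stop("blocks do not overlap")
  cols <- (lo + 1L):hi                           # 1-based matrix columns
  score <- sum(columnPairScore(countsA[, cols, drop = FALSE],
                               countsB[, cols, drop = FALSE], mix))
  list(related = score > 0, score = score)
}

#' Mark which core blocks are related to the query subfamily
#'
#' Each block of a non-query subfamily is compared with every query-subfamily
#' block it overlaps by at least \code{minOverlap} columns; it is marked
#' related to the query if at least one such comparison yields a strictly
#' positive summed column-pair score. Query-subfamily blocks are related by
#' definition. If the query subfamily has no blocks, every other block is
#' unrelated (with a warning).
#'
#' @param blocks block data.frame for all subfamilies (row-bound output of
#'   \code{\link{detectCoreBlocks}}).
#' @param partition a \linkS4class{SubfamilyPartition}.
#' @param countsList list (one 20 x nCols matrix per subfamily) of column
#'   counts.
#' @param mix a \linkS4class{DirichletMixture}.
#' @param minOverlap minimum overlap, in columns, for a comparison (default 1).
#' @return \code{blocks} with \code{relatedToQuery} filled in.
#' @export
markQueryRelatedBlocks <- function(blocks, partition, countsList, mix,
                                   minOverlap = 1L) {
  if (nrow(blocks) == 0L) return(blocks)
  qs <- partition@querySubfamily
  isQ <- blocks$subfamily == qs
  blocks$relatedToQuery <- FALSE
  blocks$relatedToQuery[isQ] <- TRUE
  qBlocks <- blocks[isQ, , drop = FALSE]
  if (nrow(qBlocks) == 0L) {
    warning("query subfamily has no core blocks; all other blocks unrelated")
    return(blocks)
  }
  for (i in which(!isQ)) {
    b <- blocks[i, ]
    for (k in seq_len(nrow(qBlocks))) {
      q <- qBlocks[k, ]
      if (min(b$end, q$end) - max(b$start, q$start) >= minOverlap) {
        rel <- blockRelatedness(b, q, countsList[[b$subfamily]],
                                countsList[[qs]], mix)
        if (rel$related) { blocks$relatedToQuery[i] <- TRUE; break }
      }
    }
  }
  blocks
}
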