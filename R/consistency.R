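#' Posterior-predictive log score of a sequence segment against block columns
#'
#' Scores the alignment of one sequence segment to a core block as the sum of
#' log posterior-predictive probabilities of each residue against its paired
#' column (positions are treated as independent). The caller supplies count
#' columns from which the evaluated sequence's own residues have already been
#' removed (leave-one-out), so a sequence can never validate itself.
#'
#' @param residues character vector of residues, one per paired column.
#' @param counts 20 x k matrix of the paired columns' residue counts
#'   (mixture alphabet row order), excluding the evaluated sequence.
#' @param mix a \linkS4class{DirichletMixture}.
#' @return total log probability (nats).
#' @export
segmentLogScore <- function(residues, counts, mix) {
  counts <- as.matrix(counts)
  if (length(residues) == 0L || ncol(counts) == 0L)
    stop("empty segment/column pairing")
  if (length(residues) != ncol(counts))
    stop("one residue per column required")
  p <- posteriorPredictive(counts, mix, residue = residues)
  sum(log(pmax(p, PROB_FLOOR)))
}

#' Log score of a uniform-random sequence against block columns
#'
#' The unrelatedness baseline: the expected probability, per column, of a
#' residue drawn uniformly from the 20-letter alphabet,
#' \eqn{\sum_a (1/L)\, P(a \mid \Theta_M)} with \eqn{L = 20}, accumulated in
#' log space over the block columns. Because the posterior predictive
#' normalizes over residues, each column contributes exactly \eqn{\log(1/20)};
#' the baseline is computed through the predictive nonetheless so the
#' contract holds for any predictive model.
#'
#' @param counts 20 x k matrix of block-column residue counts.
#' @param mix a \linkS4class{DirichletMixture}.
#' @return total log probability (nats) of the random baseline.
#' @export
randomBaseline <- function(counts, mix) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) stop("block must have at least 1 column")
  pred <- posteriorPredictive(counts, mix)
  sum(log(pmax(colSums(pred) / 20, PROB_FLOOR)))
}

## residues of sequence `seqIdx` inside block columns [start, end), with the
## paired (non-gap, non-'X') column positions; returns NULL if none
segmentPairing <- function(msa, seqIdx, start, end) {
  cols <- (start + 1L):end
  res <- msa@mat[seqIdx, cols]
  keep <- res != GAP_CHAR & res != MISSING_CHAR
  if (!any(keep)) return(NULL)
  list(cols = cols[keep], residues = res[keep])
}

#' Flag inconsistent sequence segments across subfamily core blocks
#'
#' For every sequence and every core block of its own subfamily, compares the
#' leave-one-out posterior-predictive segment score with the uniform-random
#' baseline over the same paired positions; segments scoring below the
#' baseline are flagged as inconsistent (badly predicted) and are excluded
#' from region chaining downstream. Sequences entirely gapped across a block
#' yield no verdict for that block.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param blocks block data.frame (subfamily/start/end columns).
#' @param partition a \linkS4class{SubfamilyPartition}.
#' @param countsList list of per-subfamily 20 x nCols count matrices.
#' @param mix a \linkS4class{DirichletMixture}.
#' @return data.frame of verdicts: seqId, subfamily, start, end, nPaired,
#'   logScore, logBaseline, inconsistent.
#' @export
flagInconsistentSegments <- function(msa, blocks, partition, countsList, mix) {
  out <- list()
  ids <- seqIds(msa)
  for (f in seq_along(partition@subfamilies)) {
    fb <- blocks[blocks$subfamily == f, , drop = FALSE]
    if (nrow(fb) == 0L) next
    members <- partition@subfamilies[[f]]
    for (b in seq_len(nrow(fb))) {
      for (s in members) {
        pr <- segmentPairing(msa, s, fb$start[b], fb$end[b])
        if (is.null(pr)) next
        cnt <- countsList[[f]][, pr$cols, drop = FALSE]
        ## leave-one-out: remove this sequence's residues from the counts
        ri <- match(pr$residues, mix@alphabet)
        cnt[cbind(ri, seq_along(ri))] <- cnt[cbind(ri, seq_along(ri))] - 1L
        sc <- segmentLogScore(pr$residues, cnt, mix)
        bl <- randomBaseline(cnt, mix)
        out[[length(out) + 1L]] <- data.frame(
          seqId = ids[s], subfamily = f,
          start = fb$start[b], end = fb$end[b],
          nPaired = length(pr$cols), logScore = sc, logBaseline = bl,
          inconsistent = sc < bl)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seqId = character(0), subfamily = integer(0),
                      start = integer(0), end = integer(0),
                      nPaired = integer(0), logScore = numeric(0),
                      logBaseline = numeric(0), inconsistent = logical(0)))
  do.call(rbind, out)
}

#' Compare orphan sequences with the query subfamily's core blocks
#'
#' Each orphan's segments across the query-subfamily core blocks are scored
#' with the posterior-predictive criterion (no leave-one-out: orphans are not
#' members of the query subfamily). Query blocks whose segment score is at
#' least the random baseline become that orphan's core blocks for region
#' chaining. If the query subfamily has no blocks, every orphan gets none
#' (and will be removed downstream).
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param queryBlocks block data.frame of the query subfamily.
#' @param queryCounts 20 x nCols count matrix of the query subfamily.
#' @param orphanIdx integer vector of orphan sequence indices.
#' @param mix a \linkS4class{DirichletMixture}.
#' @return data.frame: seqId, start, end, blockScore, nPaired, logScore,
#'   logBaseline, pass.
#' @export
compareOrphansToQuery <- function(msa, queryBlocks, queryCounts, orphanIdx,
                                  mix) {
  empty <- data.frame(seqId = character(0), start = integer(0),
                      end = integer(0), blockScore = numeric(0),
                      nPaired = integer(0), logScore = numeric(0),
                      logBaseline = numeric(0), pass = logical(0))
  if (length(orphanIdx) == 0L) return(empty)
  if (nrow(queryBlocks) == 0L) {
    warning("query subfamily has no core blocks; orphans cannot be rescued")
    return(empty)
  }
  ids <- seqIds(msa)
  out <- list()
  for (s in orphanIdx) {
    for (b in seq_len(nrow(queryBlocks))) {
      pr <- segmentPairing(msa, s, queryBlocks$start[b], queryBlocks$end[b])
      if (is.null(pr)) next
      cnt <- queryCounts[, pr$cols, drop = FALSE]
      sc <- segmentLogScore(pr$residues, cnt, mix)
      bl <- randomBaseline(cnt, mix)
      out[[length(out) + 1L]] <- data.frame(
        seqId = ids[s], start = queryBlocks$start[b],
        end = queryBlocks$end[b], blockScore = queryBlocks$blockScore[b],
        nPaired = length(pr$cols), logScore = sc, logBaseline = bl,
        pass = sc >= bl)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
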