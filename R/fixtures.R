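#' Generate a synthetic alignment with planted ground truth
#'
#' Deterministic generator of test alignments emulating a curated homology
#' benchmark at desk scale: a set of subfamilies sharing planted conserved
#' blocks (columns drawn from tight per-column compositions, optionally
#' shared across subfamilies so they are related to the query subfamily),
#' background columns drawn uniformly from the 20-letter alphabet, a few
#' unrelated sequences drawn entirely from background (verified post hoc to
#' share less than \code{maxUnrelatedIdentity} identity with the query), and
#' optional corrupted segments in which a member's residues across a planted
#' block are overwritten with uniform draws (emulating badly predicted
#' sequence stretches). The same seed always yields byte-identical output;
#' the caller's RNG state is untouched.
#'
#' @param seed integer seed of the fixture's private random stream.
#' @param nSubfamilies number of subfamilies (default 3).
#' @param membersPerSubfamily sequences per subfamily (default 5).
#' @param nCols alignment columns (default 240).
#' @param plantedBlocks data.frame with columns \code{start}, \code{end}
#'   (0-based half-open, disjoint), \code{shared} (logical: one consensus
#'   across all subfamilies), \code{conservation} (probability a member
#'   emits the consensus residue). Default: two shared blocks of 30 columns.
#' @param nUnrelated unrelated background sequences appended (default 3;
#'   the benchmark design adds up to 4 per family).
#' @param nCorrupted members whose residues across one shared block are
#'   replaced by uniform draws (default 0).
#' @param maxUnrelatedIdentity maximum query identity allowed for an
#'   unrelated sequence (default 0.5, strict); resampled up to 100 times.
#' @param withinConservation probability that a member emits its subfamily's
#'   parent residue in non-block columns (default 0: non-block columns are
#'   pure background noise). Positive values create subfamily-level identity
#'   structure for clustering fixtures.
#' @return list with \code{msa} (a \linkS4class{ProteinMSA}, query id
#'   \code{"query"}) and \code{truth} (ids of related/unrelated sequences,
#'   planted block table, corrupted-segment table, subfamily membership).
#' @examples
#' fx <- generateFixture(seed = 1)
#' fx$msa
#' fx$truth$unrelated
#' @export
generateFixture <- function(seed, nSubfamilies = 3L, membersPerSubfamily = 5L,
                            nCols = 240L,
                            plantedBlocks = data.frame(
                              start = c(30L, 130L), end = c(60L, 160L),
                              shared = c(TRUE, TRUE),
                              conservation = c(0.9, 0.9)),
                            nUnrelated = 3L, nCorrupted = 0L,
                            maxUnrelatedIdentity = 0.5,
                            withinConservation = 0) {
  stopifnot(nSubfamilies >= 1L, membersPerSubfamily >= 1L,
            all(plantedBlocks$end <= nCols),
            all(plantedBlocks$end > plantedBlocks$start))
  ord <- order(plantedBlocks$start)
  plantedBlocks <- plantedBlocks[ord, , drop = FALSE]
  if (nrow(plantedBlocks) > 1L &&
      any(plantedBlocks$start[-1L] < plantedBlocks$end[-nrow(plantedBlocks)]))
    stop("planted blocks must be disjoint")

  withLocalSeed(seed, {
    nMember <- nSubfamilies * membersPerSubfamily
    ids <- unlist(lapply(seq_len(nSubfamilies), function(f)
      paste0("sf", f, "_s", seq_len(membersPerSubfamily))))
    ids[1L] <- "query"                            # query = first member of sf1
    subfamilyOf <- rep(seq_len(nSubfamilies), each = membersPerSubfamily)
    mat <- matrix(sample(AA20, nMember * nCols, replace = TRUE),
                  nrow = nMember, ncol = nCols)

    ## subfamily-level identity structure in non-block columns (clustering
    ## fixtures): members copy a subfamily parent with prob withinConservation
    if (withinConservation > 0) {
      inBlock <- logical(nCols)
      for (b in seq_len(nrow(plantedBlocks)))
        inBlock[(plantedBlocks$start[b] + 1L):plantedBlocks$end[b]] <- TRUE
      bg <- which(!inBlock)
      for (f in seq_len(nSubfamilies)) {
        parent <- sample(AA20, length(bg), replace = TRUE)
        for (r in which(subfamilyOf == f)) {
          emit <- stats::runif(length(bg)) < withinConservation
          mat[r, bg[emit]] <- parent[emit]
        }
      }
    }

    ## plant conserved blocks
    for (b in seq_len(nrow(plantedBlocks))) {
      cols <- (plantedBlocks$start[b] + 1L):plantedBlocks$end[b]
      cons <- plantedBlocks$conservation[b]
      sharedConsensus <- sample(AA20, length(cols), replace = TRUE)
      for (f in seq_len(nSubfamilies)) {
        consensus <- if (plantedBlocks$shared[b]) sharedConsensus
          else sample(AA20, length(cols), replace = TRUE)
        rows <- which(subfamilyOf == f)
        for (r in rows) {
          emit <- stats::runif(length(cols)) < cons
          mat[r, cols] <- ifelse(emit, consensus,
                                 sample(AA20, length(cols), replace = TRUE))
        }
      }
    }

    ## corrupted segments: overwrite one shared block in chosen members
    corrupted <- data.frame(seqId = character(0), start = integer(0),
                            end = integer(0))
    if (nCorrupted > 0L) {
      shared <- which(plantedBlocks$shared)
      if (length(shared) == 0L) stop("corruption requires a shared block")
      candidates <- setdiff(seq_len(nMember), 1L)   # never the query
      pick <- sample(candidates, min(nCorrupted, length(candidates)))
      for (r in pick) {
        b <- shared[sample.int(length(shared), 1L)]
        cols <- (plantedBlocks$start[b] + 1L):plantedBlocks$end[b]
        mat[r, cols] <- sample(AA20, length(cols), replace = TRUE)
        corrupted <- rbind(corrupted, data.frame(
          seqId = ids[r], start = plantedBlocks$start[b],
          end = plantedBlocks$end[b]))
      }
    }

    ## unrelated background sequences, < maxUnrelatedIdentity to the query
    unrelIds <- character(0)
    if (nUnrelated > 0L) {
      unrelIds <- paste0("unrelated", seq_len(nUnrelated))
      unrel <- matrix("", nrow = nUnrelated, ncol = nCols)
      for (u in seq_len(nUnrelated)) {
        for (attempt in seq_len(100L)) {
          row <- sample(AA20, nCols, replace = TRUE)
          if (mean(row == mat[1L, ]) < maxUnrelatedIdentity) break
          if (attempt == 100L)
            stop("could not generate an unrelated sequence below the identity target")
        }
        unrel[u, ] <- row
      }
      mat <- rbind(mat, unrel)
    }
    rownames(mat) <- c(ids, unrelIds)

    msa <- new("ProteinMSA", mat = mat, queryId = "query")
    validObject(msa)
    list(msa = msa,
         truth = list(
           related = ids,
           unrelated = unrelIds,
           blocks = plantedBlocks,
           corrupted = corrupted,
           subfamilies = split(ids, subfamilyOf)))
  })
}
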