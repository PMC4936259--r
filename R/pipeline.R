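#' Run the full homology-delineation pipeline
#'
#' Executes the five stages end to end: (1) subfamily clustering with orphan
#' detection, (2) per-subfamily BILD score tracks and sliding-window core
#' blocks, with posterior-predictive flagging of inconsistent segments,
#' (3) Bayesian relatedness of every block to the query subfamily's blocks,
#' (4) orphan-versus-query-subfamily comparison, (5) chaining of
#' query-related blocks into regions, removal of sequences with no region
#' above the score cutoff, and ranking of the survivors. The pipeline is
#' fully deterministic: identical inputs give identical reports.
#'
#' @param msa a \linkS4class{ProteinMSA}, or the path of an aligned FASTA
#'   file (then \code{queryId} is required).
#' @param mix a \linkS4class{DirichletMixture}, or the path of a mixture
#'   file in the UCSC flat format.
#' @param queryId query sequence id (only when \code{msa} is a path).
#' @param window sliding-window length for block detection (columns,
#'   default 7).
#' @param blockThreshold mean normalized-score threshold for core blocks
#'   (default 0.05, strict "above").
#' @param maxGap maximum distance between chained blocks (columns,
#'   default 40).
#' @param minRegionLength minimum region span (columns, default 21,
#'   inclusive).
#' @param scoreCutoff minimum region score for sequence retention (default
#'   0, strict).
#' @param orphanThreshold minimum-distance floor for orphan detection
#'   (default 0.85).
#' @param minSplitGap merge-height gap required to split subfamilies
#'   (default 0.1).
#' @param minOverlap minimum block overlap for relatedness comparisons
#'   (columns, default 1).
#' @param outputPrefix if non-\code{NULL}, write the filtered aligned FASTA,
#'   GFF3 (alignment-space and sequence-space), BED6 blocks and JSON report
#'   under this path prefix.
#' @return a \linkS4class{HomologyReport}.
#' @export
runPipeline <- function(msa, mix, queryId = NULL,
                        window = 7L, blockThreshold = 0.05,
                        maxGap = 40L, minRegionLength = 21L, scoreCutoff = 0,
                        orphanThreshold = 0.85, minSplitGap = 0.1,
                        minOverlap = 1L, outputPrefix = NULL) {
  if (is.character(msa)) {
    if (is.null(queryId)) stop("queryId is required when msa is a file path")
    msa <- readProteinMSA(msa, queryId)
  }
  if (is.character(mix)) mix <- parseDirichletMixture(mix)
  stopifnot(is(msa, "ProteinMSA"), is(mix, "DirichletMixture"))

  ## 1. subfamilies and orphans
  dm <- pairwiseDistances(msa)
  qIdx <- match(queryId(msa), seqIds(msa))
  partition <- clusterSubfamilies(dm, qIdx, orphanThreshold = orphanThreshold,
                                  minSplitGap = minSplitGap)

  ## 2. score tracks and core blocks per subfamily
  countsList <- lapply(partition@subfamilies, function(members)
    columnCounts(msa, members, alphabet = mix@alphabet))
  blocks <- do.call(rbind, lapply(seq_along(partition@subfamilies), function(f) {
    tr <- scoreTrack(msa, partition@subfamilies[[f]], mix, subfamily = f)
    detectCoreBlocks(tr, window = window, threshold = blockThreshold)
  }))
  if (is.null(blocks)) blocks <- emptyBlockTable()

  ## 2b. inconsistent-segment flagging
  verdicts <- flagInconsistentSegments(msa, blocks, partition, countsList, mix)

  ## 3. relatedness of each block to the query subfamily
  blocks <- markQueryRelatedBlocks(blocks, partition, countsList, mix,
                                   minOverlap = minOverlap)

  ## 4. orphans vs query subfamily
  qs <- partition@querySubfamily
  qBlocks <- blocks[blocks$subfamily == qs, , drop = FALSE]
  orphanVerdicts <- compareOrphansToQuery(msa, qBlocks, countsList[[qs]],
                                          partition@orphans, mix)

  ## 5. regions, removal, ranking
  fr <- filterAndRank(msa, partition, blocks, verdicts, orphanVerdicts,
                      maxGap = maxGap, minRegionLength = minRegionLength,
                      scoreCutoff = scoreCutoff)

  report <- new("HomologyReport",
                perSequence = fr$perSequence, regions = fr$regions,
                blocks = blocks, inconsistent = verdicts,
                partition = partition,
                parameters = list(
                  schema_version = "1.0",
                  queryId = queryId(msa), window = window,
                  blockThreshold = blockThreshold, maxGap = maxGap,
                  minRegionLength = minRegionLength,
                  scoreCutoff = scoreCutoff,
                  orphanThreshold = orphanThreshold,
                  minSplitGap = minSplitGap, minOverlap = minOverlap))
  if (!is.null(outputPrefix)) writeReportFiles(report, msa, outputPrefix)
  report
}

#' Write all pipeline output files
#'
#' Writes \code{<prefix>.filtered.fasta} (retained sequences, aligned),
#' \code{<prefix>.alignment.gff3} (core blocks, conserved regions and
#' inconsistent segments in alignment-column space), \code{<prefix>.sequence.gff3}
#' (regions in residue space per sequence), \code{<prefix>.blocks.bed}
#' (BED6) and \code{<prefix>.report.json}. GFF3 is 1-based inclusive; BED is
#' 0-based half-open; the JSON report keeps the package's internal 0-based
#' half-open convention.
#'
#' @param report a \linkS4class{HomologyReport}.
#' @param msa the \linkS4class{ProteinMSA} the report was computed from.
#' @param prefix output path prefix.
#' @return invisibly, the vector of paths written.
#' @export
writeReportFiles <- function(report, msa, prefix) {
  ps <- report@perSequence
  keep <- ps$id[ps$status %in% c("query", "related")]
  paths <- c(
    fasta = paste0(prefix, ".filtered.fasta"),
    agff = paste0(prefix, ".alignment.gff3"),
    sgff = paste0(prefix, ".sequence.gff3"),
    bed = paste0(prefix, ".blocks.bed"),
    json = paste0(prefix, ".report.json"))
  writeProteinMSA(msa, paths["fasta"], ids = keep)

  ## alignment-space GFF3: blocks + regions + inconsistent segments
  gr <- alignmentSpaceGRanges(report)
  rtracklayer::export(gr, paths[["agff"]], format = "gff3")

  ## sequence-space GFF3: regions on each retained sequence
  reg <- report@regions[!is.na(report@regions$resStart), , drop = FALSE]
  if (nrow(reg) > 0L) {
    sgr <- GenomicRanges::GRanges(
      seqnames = reg$seqId,
      ranges = IRanges::IRanges(start = reg$resStart + 1L, end = reg$resEnd),
      type = "conserved_region", score = reg$regionScore,
      ID = sprintf("region_%s_%d", reg$seqId, seq_len(nrow(reg))))
  } else {
    sgr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(sgr, paths[["sgff"]], format = "gff3")

  writeBlocksBED(report@blocks, paths[["bed"]])
  writeReportJSON(report, paths[["json"]])
  invisible(paths)
}

alignmentSpaceGRanges <- function(report) {
  blk <- report@blocks
  reg <- report@regions
  inc <- report@inconsistent[report@inconsistent$inconsistent %in% TRUE,
                             , drop = FALSE]
  mk <- function(start0, end0, type, score, name) {
    if (length(start0) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
      seqnames = "alignment",
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      type = type, score = score, Name = name)
  }
  suppressWarnings(c(
    mk(blk$start, blk$end, "core_block", blk$blockScore,
       sprintf("subfamily%d_block%d", blk$subfamily, seq_len(nrow(blk)))),
    mk(reg$start, reg$end, "conserved_region", reg$regionScore, reg$seqId),
    mk(inc$start, inc$end, "inconsistent_segment", inc$logScore - inc$logBaseline,
       inc$seqId)))
}

## BED6 writer: name = subfamily, score = raw block score (log-odds sum,
## unbounded — deliberately not clamped to the browser's 0-1000 convention)
writeBlocksBED <- function(blocks, path) {
  if (nrow(blocks) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- sprintf("alignment\t%d\t%d\tsubfamily%d\t%.6g\t+",
                   blocks$start, blocks$end, blocks$subfamily,
                   blocks$blockScore)
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a HomologyReport to JSON
#'
#' @param report a \linkS4class{HomologyReport}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(
    schema_version = report@parameters$schema_version,
    parameters = report@parameters[setdiff(names(report@parameters),
                                           "schema_version")],
    subfamilies = lapply(report@partition@subfamilies, as.integer),
    orphans = as.integer(report@partition@orphans),
    query_subfamily = report@partition@querySubfamily,
    per_sequence = report@perSequence,
    regions = report@regions,
    blocks = report@blocks,
    inconsistent_segments = report@inconsistent)
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = 10, na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
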