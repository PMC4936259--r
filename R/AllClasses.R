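#' ProteinMSA: a protein multiple sequence alignment with a designated query
#'
#' Holds an aligned set of protein sequences as a character matrix (rows =
#' sequences, columns = alignment columns) over the 20 canonical amino acids,
#' \code{"X"} (unknown residue, treated as missing data) and \code{"-"} (gap),
#' together with the identifier of the query sequence relative to which
#' homology is assessed. All coordinates handled by the package are 0-based,
#' half-open alignment-column intervals unless a writer states otherwise.
#'
#' @slot mat character matrix of single residues; rownames are sequence ids.
#' @slot queryId id of the query sequence (must be a rowname of \code{mat}).
#' @exportClass ProteinMSA
setClass("ProteinMSA",
         representation(mat = "matrix", queryId = "character"))

setValidity("ProteinMSA", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be character")
  if (nrow(m) < 1L || ncol(m) < 1L) return("alignment must be non-empty")
  ids <- rownames(m)
  if (is.null(ids) || anyDuplicated(ids))
    return("sequence ids must be present and unique")
  bad <- matrix(!(m %in% c(AA20, GAP_CHAR, MISSING_CHAR)), nrow(m), ncol(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("illegal character '%s' in record '%s' at column %d",
                   m[bad][1L], ids[idx[1L]], idx[2L]))
  }
  if (length(object@queryId) != 1L || !(object@queryId %in% ids))
    return(sprintf("query '%s' not found in alignment",
                   paste(object@queryId, collapse = ",")))
  TRUE
})

#' DirichletMixture: a mixture-of-Dirichlets prior over amino-acid columns
#'
#' A weighted mixture of Dirichlet densities over compositions of the 20
#' amino acids, plus the background residue frequencies used as the
#' independence model in log-odds scores. Components are rows of
#' \code{alpha}; \code{alphabet} fixes the residue order of all vectors.
#'
#' @slot weights numeric vector of component weights summing to 1.
#' @slot alpha numeric matrix (components x 20) of positive concentration
#'   parameters.
#' @slot background numeric 20-vector of background frequencies summing to 1.
#' @slot alphabet character 20-vector: the residue order of all columns.
#' @exportClass DirichletMixture
setClass("DirichletMixture",
         representation(weights = "numeric", alpha = "matrix",
                        background = "numeric", alphabet = "character"))

setValidity("DirichletMixture", function(object) {
  J <- length(object@weights)
  if (J < 1L) return("mixture needs at least one component")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("component weights must sum to 1")
  if (any(object@weights < 0)) return("component weights must be non-negative")
  if (!is.numeric(object@alpha) || nrow(object@alpha) != J ||
      ncol(object@alpha) != 20L)
    return("alpha must be a (components x 20) numeric matrix")
  if (any(object@alpha <= 0)) return("all alpha parameters must be positive")
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0))
    return("background must be 20 positive frequencies summing to 1")
  if (length(object@alphabet) != 20L || anyDuplicated(object@alphabet))
    return("alphabet must list 20 distinct residues")
  TRUE
})

#' SubfamilyPartition: subfamily clustering of alignment sequences
#'
#' A partition of the sequence indices of a \linkS4class{ProteinMSA} into
#' subfamilies plus a set of highly divergent orphan sequences that were set
#' aside before clustering. The query is never an orphan: if it would be, it
#' is placed in a singleton subfamily of its own.
#'
#' @slot subfamilies list of integer vectors of 1-based sequence indices.
#' @slot orphans integer vector of orphan sequence indices.
#' @slot querySubfamily index (into \code{subfamilies}) of the subfamily
#'   containing the query.
#' @exportClass SubfamilyPartition
setClass("SubfamilyPartition",
         representation(subfamilies = "list", orphans = "integer",
                        querySubfamily = "integer"))

setValidity("SubfamilyPartition", function(object) {
  all_idx <- c(unlist(object@subfamilies), object@orphans)
  if (anyDuplicated(all_idx)) return("subfamilies and orphans must be disjoint")
  if (any(lengths(object@subfamilies) == 0L))
    return("subfamilies must be non-empty")
  k <- object@querySubfamily
  if (length(k) != 1L || k < 1L || k > length(object@subfamilies))
    return("querySubfamily out of range")
  TRUE
})

#' ScoreTrack: per-column BILD scores for one subfamily
#'
#' @slot subfamily index of the subfamily the track belongs to.
#' @slot rawS per-column BILD log-odds (nats).
#' @slot prob per-column normalized score in [0, 1); forced to 0 where the
#'   subfamily contributes fewer than 2 residues.
#' @slot nObs per-column number of residues observed in the subfamily.
#' @exportClass ScoreTrack
setClass("ScoreTrack",
         representation(subfamily = "integer", rawS = "numeric",
                        prob = "numeric", nObs = "integer"))

setValidity("ScoreTrack", function(object) {
  n <- length(object@rawS)
  if (length(object@prob) != n || length(object@nObs) != n)
    return("rawS, prob and nObs must have equal length")
  if (any(object@prob < 0 | object@prob > 1, na.rm = TRUE))
    return("prob values must lie in [0, 1]")
  TRUE
})

#' HomologyReport: the end-to-end result of a pipeline run
#'
#' Per-sequence verdicts (query / related / removed / orphan-removed), ranks
#' and total scores, the homologous regions found for each retained sequence,
#' all detected core blocks, flagged inconsistent segments, the subfamily
#' partition, and the parameters of the run.
#'
#' @slot perSequence data.frame: id, status, rank (NA if unranked), totalScore.
#' @slot regions data.frame of chained regions per sequence (alignment and
#'   sequence coordinates, 0-based half-open).
#' @slot blocks data.frame of core blocks per subfamily.
#' @slot inconsistent data.frame of segment verdicts.
#' @slot partition the \linkS4class{SubfamilyPartition} used.
#' @slot parameters named list of run parameters.
#' @exportClass HomologyReport
setClass("HomologyReport",
         representation(perSequence = "data.frame", regions = "data.frame",
                        blocks = "data.frame", inconsistent = "data.frame",
                        partition = "SubfamilyPartition", parameters = "list"))

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d sequences x %d columns, query '%s'\n",
              nrow(object@mat), ncol(object@mat), object@queryId))
})

setMethod("show", "DirichletMixture", function(object) {
  cat(sprintf("DirichletMixture: %d components over {%s}\n",
              length(object@weights), paste(object@alphabet, collapse = "")))
})

setMethod("show", "SubfamilyPartition", function(object) {
  cat(sprintf("SubfamilyPartition: %d subfamilies (sizes %s), %d orphans, query in subfamily %d\n",
              length(object@subfamilies),
              paste(lengths(object@subfamilies), collapse = ","),
              length(object@orphans), object@querySubfamily))
})

setMethod("show", "HomologyReport", function(object) {
  tab <- table(object@perSequence$status)
  cat("HomologyReport:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                               collapse = " "), "\n")
  cat(sprintf("  %d regions, %d core blocks, %d flagged segments\n",
              nrow(object@regions), nrow(object@blocks),
              sum(object@inconsistent$inconsistent %in% TRUE)))
})

## ---- accessors ----

#' Number of alignment columns
#' @param x a ProteinMSA
#' @export
nCols <- function(x) ncol(x@mat)

#' Sequence identifiers of an alignment
#' @param x a ProteinMSA
#' @export
seqIds <- function(x) rownames(x@mat)

#' Query sequence identifier
#' @param x a ProteinMSA or HomologyReport
#' @export
queryId <- function(x) {
  if (is(x, "HomologyReport")) x@parameters$queryId else x@queryId
}

#' Alignment as a character matrix (rows = sequences)
#' @param x a ProteinMSA
#' @export
msaMatrix <- function(x) x@mat

#' Subfamily membership list (1-based sequence indices)
#' @param x a SubfamilyPartition
#' @export
subfamilies <- function(x) x@subfamilies

#' Orphan sequence indices
#' @param x a SubfamilyPartition
#' @export
orphans <- function(x) x@orphans

#' Index of the subfamily containing the query
#' @param x a SubfamilyPartition
#' @export
querySubfamily <- function(x) x@querySubfamily

#' Per-sequence verdict table of a report
#' @param x a HomologyReport
#' @export
perSequence <- function(x) x@perSequence

#' Region table of a report
#' @param x a HomologyReport
#' @export
reportRegions <- function(x) x@regions

#' Core-block table of a report
#' @param x a HomologyReport
#' @export
reportBlocks <- function(x) x@blocks

#' Inconsistent-segment table of a report
#' @param x a HomologyReport
#' @export
inconsistentSegments <- function(x) x@inconsistent

#' Component weights of a Dirichlet mixture
#' @param x a DirichletMixture
#' @export
mixtureWeights <- function(x) x@weights

#' Concentration parameters (components x 20) of a Dirichlet mixture
#' @param x a DirichletMixture
#' @export
mixtureAlpha <- function(x) x@alpha

#' Background residue frequencies of a Dirichlet mixture
#' @param x a DirichletMixture
#' @export
mixtureBackground <- function(x) x@background
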