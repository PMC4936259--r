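#' Read an aligned FASTA file as a ProteinMSA
#'
#' Parses an aligned FASTA file (gap character \code{"-"}), uppercases
#' residues, verifies that all records have equal length, that ids are
#' unique, that the query is present, and that no character outside the 20
#' canonical amino acids, \code{"X"} or \code{"-"} occurs. Ambiguity codes
#' (B, Z, J), selenocysteine/pyrrolysine (U, O), stops (\code{"*"}) and dots
#' are rejected rather than silently recoded.
#'
#' @param path path to an aligned FASTA file with at least 2 records.
#' @param queryId id of the query sequence; must match a record id (the FASTA
#'   id is the first whitespace-delimited token of the header).
#' @return a \linkS4class{ProteinMSA}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">q", "ACDE", ">s1", "ACD-"), f)
#' msa <- readProteinMSA(f, "q")
#' nCols(msa)
#' @export
readProteinMSA <- function(path, queryId) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("alignment must contain at least 2 records")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  proteinMSA(setNames(seqs, ids), queryId)
}

#' Construct a ProteinMSA from named aligned strings
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param queryId id of the query sequence.
#' @return a \linkS4class{ProteinMSA}.
#' @export
proteinMSA <- function(seqs, queryId) {
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("not an alignment: records have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  mat <- matrix(unlist(strsplit(unname(seqs), "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(ids, NULL))
  obj <- new("ProteinMSA", mat = mat, queryId = as.character(queryId))
  validObject(obj)
  obj
}

#' Write a ProteinMSA as aligned FASTA
#'
#' Sequences and ids round-trip losslessly through
#' \code{readProteinMSA(writeProteinMSA(...))}, including all-gap columns.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param path output path.
#' @param ids optional subset/order of sequence ids to write.
#' @return invisibly, \code{path}.
#' @export
writeProteinMSA <- function(msa, path, ids = seqIds(msa)) {
  if (length(ids) == 0L) stop("refusing to write an empty alignment")
  miss <- setdiff(ids, seqIds(msa))
  if (length(miss)) stop("unknown sequence ids: ", paste(miss, collapse = ", "))
  seqs <- apply(msa@mat[ids, , drop = FALSE], 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Column/residue coordinate map for one sequence of an alignment
#'
#' Maps 0-based alignment columns to 0-based residue indices of a sequence
#' and back. Gap columns map to \code{NA}. On non-gap columns the two maps
#' compose to the identity.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param seqId a sequence id.
#' @return a list with elements \code{colToRes} (length \code{nCols},
#'   \code{NA} at gaps) and \code{resToCol} (length = number of residues).
#' @examples
#' msa <- proteinMSA(c(q = "A-C", s = "AAC"), "q")
#' coordinateMap(msa, "q")$colToRes   # 0, NA, 1
#' @export
coordinateMap <- function(msa, seqId) {
  if (!(seqId %in% seqIds(msa))) stop("unknown sequence id: ", seqId)
  row <- msa@mat[seqId, ]
  nongap <- row != GAP_CHAR
  colToRes <- rep(NA_integer_, length(row))
  colToRes[nongap] <- seq_len(sum(nongap)) - 1L
  list(colToRes = colToRes, resToCol = which(nongap) - 1L)
}
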