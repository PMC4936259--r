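#' @importFrom methods new validObject is slot
#' @importFrom stats hclust cutree as.dist setNames
NULL

## the 20 canonical amino acids, in the conventional alphabetical one-letter
## order used by the UCSC mixture files
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## characters allowed in an input alignment besides the 20 amino acids
GAP_CHAR <- "-"
MISSING_CHAR <- "X"

## numerical floor before taking logs
PROB_FLOOR <- 1e-300

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's RNG state afterwards
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## empty block table with the canonical column layout (0-based, half-open)
emptyBlockTable <- function() {
  data.frame(subfamily = integer(0), start = integer(0), end = integer(0),
             meanProb = numeric(0), blockScore = numeric(0),
             relatedToQuery = logical(0))
}
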