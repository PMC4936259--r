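## shared fixture builders and independent oracles for the test suite

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## the default informative prior used across tests
testMixture <- function() syntheticMixture20()

## a small 3-component hand-written mixture (weights 0.5/0.3/0.2):
## one near-uniform broad component and two peaked ones
toyMixture <- function() {
  a1 <- rep(1, 20)
  a2 <- c(rep(0.05, 20)); a2[1] <- 2      # favours A
  a3 <- c(rep(0.05, 20)); a3[19] <- 2     # favours W
  dirichletMixture(c(0.5, 0.3, 0.2), rbind(a1, a2, a3))
}

## write the toy mixture in the flat-file format and return the path
toyMixtureFile <- function(dir = tempdir()) {
  path <- file.path(dir, "toy3comp.mixture")
  writeDirichletMixture(toyMixture(), path)
  path
}

## a random Dirichlet mixture with J components (for property tests)
randomMixture <- function(J = 3) {
  w <- stats::runif(J); w <- w / sum(w)
  alpha <- matrix(stats::rexp(J * 20, rate = 1) + 0.05, nrow = J)
  dirichletMixture(w, alpha)
}

## a random count column with M observations over few distinct residues
randomColumn <- function(M, maxDistinct = 4) {
  cnt <- integer(20)
  if (M > 0) {
    res <- sample.int(20, min(maxDistinct, M))
    draws <- sample(res, M, replace = TRUE)
    cnt <- tabulate(draws, 20)
  }
  cnt
}

## independent sequential-product oracle for the column marginal likelihood:
## Q(x_1..x_M) = sum_j q_j prod_k (alpha_{j,x_k} + n_jk) / (alpha*_j + k - 1)
## where n_jk counts previous occurrences of x_k. Implemented directly from
## the mixture parameters, independently of the package's closed form.
oracleLogQ <- function(order, mix) {
  w <- mixtureWeights(mix)
  alpha <- mixtureAlpha(mix)
  astar <- rowSums(alpha)
  total <- 0
  for (j in seq_along(w)) {
    seen <- integer(20)
    pj <- 1
    for (k in seq_along(order)) {
      x <- order[k]
      pj <- pj * (alpha[j, x] + seen[x]) / (astar[j] + k - 1)
      seen[x] <- seen[x] + 1L
    }
    total <- total + w[j] * pj
  }
  log(total)
}

## all distinct permutations of a small integer vector
distinctPermutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in unique(seq_along(x)[!duplicated(x)])) {
    for (p in distinctPermutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  unique(out)
}

## brute-force sliding-window core-block oracle: enumerate every window,
## mark covered columns, take maximal runs, keep runs whose own mean
## probability clears the threshold
oracleBlocks <- function(prob, window, threshold) {
  n <- length(prob)
  covered <- logical(n)
  if (window <= n) {
    for (i in seq_len(n - window + 1L)) {
      if (mean(prob[i:(i + window - 1L)]) > threshold)
        covered[i:(i + window - 1L)] <- TRUE
    }
  }
  blocks <- list()
  i <- 1L
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1L]) j <- j + 1L
      if (mean(prob[i:j]) > threshold)
        blocks[[length(blocks) + 1L]] <- c(start = i - 1L, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  blocks
}

## random aligned-FASTA fixture (possibly gapped) as a named string vector
randomAlignedSeqs <- function(n = 4, len = 30, gapProb = 0.15) {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(AA, len, replace = TRUE)
    gaps <- stats::runif(len) < gapProb
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1L))
  stats::setNames(seqs, paste0("seq", seq_len(n)))
}

## mutated copy of the query over the planted block columns of the default
## fixture; returns a new alignment with the extra sequence appended
appendDivergentCopy <- function(fx, blockCols, matchProb, seed) {
  set.seed(seed)
  m <- msaMatrix(fx$msa)
  q <- m["query", ]
  orow <- sample(AA, ncol(m), replace = TRUE)
  match <- stats::runif(length(blockCols)) < matchProb
  orow[blockCols][match] <- q[blockCols][match]
  seqs <- c(apply(m, 1L, paste, collapse = ""),
            divergent = paste(orow, collapse = ""))
  proteinMSA(seqs, "query")
}
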