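test_that("segment scores reduce to the Dirichlet-multinomial closed form", {
  ## one-column block, all observations 'A', uniform single-component prior:
  ## P(A | column) = (alpha_A + c_A) / (alpha* + M)
  u <- dirichletMixture(1, rep(1, 20))
  cnt <- matrix(0L, 20, 1); cnt[1, 1] <- 5L
  expect_equal(segmentLogScore("A", cnt, u), log((1 + 5) / (20 + 5)),
               tolerance = 1e-12)
  ## position order does not matter (sum of independent column terms)
  mix <- testMixture()
  cnt3 <- cbind(c(5L, rep(0L, 19)), c(0L, 5L, rep(0L, 18)), c(rep(0L, 18), 5L, 0L))
  s1 <- segmentLogScore(c("A", "C", "W"), cnt3, mix)
  s2 <- segmentLogScore(c("W", "A", "C"), cnt3[, c(3, 1, 2)], mix)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(segmentLogScore(character(0), matrix(0L, 20, 0), mix), "empty")
})

test_that("the random baseline equals the uniform-residue expectation per column", {
  mix <- testMixture()
  cnt <- matrix(0L, 20, 1); cnt[1, 1] <- 5L
  ## normalization of the posterior predictive makes each column log(1/20)
  expect_equal(randomBaseline(cnt, mix), log(1 / 20), tolerance = 1e-10)
  cnt4 <- cnt[, rep(1, 4)]
  expect_equal(randomBaseline(cnt4, mix), 4 * randomBaseline(cnt, mix),
               tolerance = 1e-10)
  ## Monte-Carlo: the mean probability of a uniformly random residue against
  ## the column matches exp(baseline) within sampling error
  set.seed(99)
  cntR <- matrix(randomColumn(8), ncol = 1)
  draws <- sample(AA, 10000, replace = TRUE)
  mc <- mean(posteriorPredictive(cntR, mix, residue = NULL)[cbind(match(draws, AA), 1L)])
  expect_equal(mc, exp(randomBaseline(cntR, mix)), tolerance = 0.05)
})

test_that("baseline and segment scores are monotone non-increasing in block length", {
  mix <- testMixture()
  set.seed(4)
  cnt <- sapply(1:6, function(i) randomColumn(6))
  res <- sample(AA, 6, replace = TRUE)
  bl <- vapply(1:6, function(k) randomBaseline(cnt[, 1:k, drop = FALSE], mix),
               numeric(1L))
  sc <- vapply(1:6, function(k)
    segmentLogScore(res[1:k], cnt[, 1:k, drop = FALSE], mix), numeric(1L))
  expect_true(all(diff(bl) <= 1e-12))
  expect_true(all(diff(sc) <= 1e-12))
})

test_that("leave-one-out scoring removes the evaluated sequence's own residues", {
  mix <- testMixture()
  ## 3-member subfamily, 8-column conserved block, one member deviant:
  ## its verdict must be computed against the other two members only
  seqs <- c(q = strrep("A", 8), s1 = strrep("A", 8), s2 = strrep("W", 8))
  msa <- proteinMSA(seqs, "q")
  p <- new("SubfamilyPartition", subfamilies = list(1:3),
           orphans = integer(0), querySubfamily = 1L)
  blocks <- data.frame(subfamily = 1L, start = 0L, end = 8L, meanProb = 1,
                       blockScore = 10, relatedToQuery = TRUE)
  counts <- list(columnCounts(msa, 1:3, alphabet = mix@alphabet))
  v <- flagInconsistentSegments(msa, blocks, p, counts, mix)
  ## expected: s2 scored against counts {A:2}, q against {A:1, W:1}
  cntAA <- matrix(0L, 20, 8); cntAA[1, ] <- 2L
  expect_equal(v$logScore[v$seqId == "s2"],
               segmentLogScore(rep("W", 8), cntAA, mix), tolerance = 1e-10)
  cntAW <- matrix(0L, 20, 8); cntAW[1, ] <- 1L; cntAW[19, ] <- 1L
  expect_equal(v$logScore[v$seqId == "q"],
               segmentLogScore(rep("A", 8), cntAW, mix), tolerance = 1e-10)
  expect_true(v$inconsistent[v$seqId == "s2"])
  expect_false(v$inconsistent[v$seqId == "q"])
})

test_that("a sequence fully gapped across a block yields no verdict", {
  mix <- testMixture()
  seqs <- c(q = "AAAAAAAA", s1 = "AAAAAAAA", s2 = "--------")
  msa <- proteinMSA(seqs, "q")
  p <- new("SubfamilyPartition", subfamilies = list(1:3),
           orphans = integer(0), querySubfamily = 1L)
  blocks <- data.frame(subfamily = 1L, start = 0L, end = 8L, meanProb = 1,
                       blockScore = 10, relatedToQuery = TRUE)
  counts <- list(columnCounts(msa, 1:3, alphabet = mix@alphabet))
  v <- flagInconsistentSegments(msa, blocks, p, counts, mix)
  expect_false("s2" %in% v$seqId)
})

test_that("uniform-random corruptions are flagged and intact members are not", {
  mix <- testMixture()
  hit <- integer(0); fp <- integer(0)
  for (s in 1:25) {
    fx <- generateFixture(seed = s, nCorrupted = 2)
    r <- runPipeline(fx$msa, mix)
    v <- inconsistentSegments(r)
    tb <- fx$truth$blocks; cor <- fx$truth$corrupted
    onPlanted <- vapply(seq_len(nrow(v)), function(i)
      any(v$start[i] < tb$end & v$end[i] > tb$start), logical(1L))
    vb <- v[onPlanted, , drop = FALSE]
    isCor <- mapply(function(sq, st, en)
      any(cor$seqId == sq & cor$start < en & cor$end > st),
      vb$seqId, vb$start, vb$end)
    hit <- c(hit, vb$inconsistent[isCor])
    fp <- c(fp, vb$inconsistent[!isCor])
  }
  expect_gte(mean(hit), 0.9)
  expect_lte(mean(fp), 0.05)
})

test_that("diverged query copies are rescued by the orphan comparison, random ones are not", {
  mix <- testMixture()
  rescued <- 0L
  for (s in 1:20) {
    fx <- generateFixture(seed = s, nUnrelated = 0)
    msa2 <- appendDivergentCopy(fx, blockCols = c(31:60, 131:160),
                                matchProb = 0.75, seed = s + 777)
    p <- clusterSubfamilies(pairwiseDistances(fx$msa), 1L)
    qs <- querySubfamily(p)
    memberIds <- seqIds(fx$msa)[subfamilies(p)[[qs]]]
    members2 <- match(memberIds, seqIds(msa2))
    qc <- columnCounts(msa2, members2, alphabet = mix@alphabet)
    qb <- detectCoreBlocks(scoreTrack(msa2, members2, mix, subfamily = qs))
    ov <- compareOrphansToQuery(msa2, qb, qc,
                                match("divergent", seqIds(msa2)), mix)
    rescued <- rescued + any(ov$pass)
  }
  expect_gte(rescued, 19L)

  ## purely random orphans fail the comparison against every block
  failAll <- 0L
  for (s in 1:20) {
    fx <- generateFixture(seed = 100 + s, nUnrelated = 1)
    msa <- fx$msa
    related <- match(fx$truth$related, seqIds(msa))
    qc <- columnCounts(msa, related, alphabet = mix@alphabet)
    qb <- detectCoreBlocks(scoreTrack(msa, related, mix, subfamily = 1L))
    ov <- compareOrphansToQuery(msa, qb, qc,
                                match("unrelated1", seqIds(msa)), mix)
    failAll <- failAll + (nrow(ov) > 0L && !any(ov$pass))
  }
  expect_gte(failAll, 19L)
})

test_that("orphans gapped across all query blocks receive no blocks", {
  mix <- testMixture()
  seqs <- c(q = strrep("A", 30), s1 = strrep("A", 30),
            gappy = paste0(strrep("-", 30)))
  msa <- proteinMSA(seqs, "q")
  qb <- data.frame(subfamily = 1L, start = 0L, end = 30L, meanProb = 1,
                   blockScore = 10, relatedToQuery = TRUE)
  qc <- columnCounts(msa, 1:2, alphabet = mix@alphabet)
  ov <- compareOrphansToQuery(msa, qb, qc, 3L, mix)
  expect_identical(nrow(ov), 0L)
  ## and with no query blocks at all: warning, empty verdicts
  expect_warning(ov2 <- compareOrphansToQuery(msa, qb[0, ], qc, 3L, mix),
                 "no core blocks")
  expect_identical(nrow(ov2), 0L)
})
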