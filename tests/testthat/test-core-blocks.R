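test_that("score tracks handle gaps, conservation and member order correctly", {
  mix <- testMixture()
  seqs <- c(q = paste0(strrep("W", 10), "-----"),
            s1 = paste0(strrep("W", 10), "-----"),
            s2 = paste0(strrep("W", 10), "-----"))
  msa <- proteinMSA(seqs, "q")
  tr <- scoreTrack(msa, 1:3, mix, subfamily = 1L)
  expect_equal(tr@prob[11:15], rep(0, 5))            # fully gapped columns
  expect_true(all(tr@prob[1:10] > 0.9))              # conserved tryptophans
  tr2 <- scoreTrack(msa, c(3L, 1L, 2L), mix, subfamily = 1L)
  expect_identical(tr@prob, tr2@prob)                # member order irrelevant
  ## a singleton subfamily cannot certify columns (fewer than 2 observations)
  tr1 <- scoreTrack(msa, 1L, mix, subfamily = 1L)
  expect_true(all(tr1@prob == 0))
})

test_that("core-block detection obeys the threshold and spans", {
  mkTrack <- function(prob) new("ScoreTrack", subfamily = 1L,
                                rawS = log(prob / (1 - prob)), prob = prob,
                                nObs = rep(5L, length(prob)))
  ## uniformly sub-threshold scores yield no blocks
  expect_identical(nrow(detectCoreBlocks(mkTrack(rep(0.04, 50)),
                                         window = 7, threshold = 0.05)), 0L)
  ## a perfect track is one block spanning all columns
  b <- detectCoreBlocks(mkTrack(rep(0.99, 50)), window = 7, threshold = 0.05)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0L, 50L))
  ## window longer than the track: warning and no blocks
  expect_warning(out <- detectCoreBlocks(mkTrack(rep(0.99, 5)), window = 7),
                 "window")
  expect_identical(nrow(out), 0L)
})

test_that("core-block detection matches the brute-force window oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(10:120, 1)
    prob <- stats::runif(n)^sample(1:4, 1)     # vary sparsity of high scores
    window <- sample(2:9, 1)
    threshold <- stats::runif(1, 0.05, 0.6)
    tr <- new("ScoreTrack", subfamily = 1L, rawS = stats::rnorm(n),
              prob = prob, nObs = rep(5L, n))
    got <- detectCoreBlocks(tr, window = window, threshold = threshold)
    want <- oracleBlocks(prob, window, threshold)
    expect_identical(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_identical(got$start[k], unname(want[[k]]["start"]))
      expect_identical(got$end[k], unname(want[[k]]["end"]))
      expect_equal(got$blockScore[k],
                   sum(tr@rawS[(got$start[k] + 1L):got$end[k]]),
                   tolerance = 1e-12)
    }
    expect_true(all(got$end - got$start >= window))
    expect_true(all(got$meanProb > threshold))
  }
})

test_that("raising the threshold never enlarges the covered column set", {
  set.seed(33)
  for (i in 1:30) {
    n <- 80
    prob <- stats::runif(n)^2
    tr <- new("ScoreTrack", subfamily = 1L, rawS = stats::rnorm(n),
              prob = prob, nObs = rep(5L, n))
    cover <- function(b) {
      cv <- logical(n)
      for (k in seq_len(nrow(b))) cv[(b$start[k] + 1L):b$end[k]] <- TRUE
      cv
    }
    lo <- cover(detectCoreBlocks(tr, window = 5, threshold = 0.1))
    hi <- cover(detectCoreBlocks(tr, window = 5, threshold = 0.3))
    expect_true(all(lo | !hi))                 # hi-covered implies lo-covered
  }
})

test_that("block relatedness is symmetric, strict at zero, and respects overlap", {
  mix <- testMixture()
  fx <- generateFixture(seed = 8, nUnrelated = 0)
  counts <- columnCounts(fx$msa, seq_along(seqIds(fx$msa)))
  bA <- data.frame(start = 30L, end = 60L)
  bB <- data.frame(start = 40L, end = 70L)
  r1 <- blockRelatedness(bA, bB, counts, counts, mix)
  r2 <- blockRelatedness(bB, bA, counts, counts, mix)
  expect_equal(r1$score, r2$score, tolerance = 1e-10)
  ## identical conserved composition: related
  expect_true(r1$related)
  ## disjoint blocks cannot be compared
  expect_error(blockRelatedness(data.frame(start = 0L, end = 10L),
                                data.frame(start = 10L, end = 20L),
                                counts, counts, mix), "do not overlap")
  ## overlap only on empty (all-gap) columns scores exactly 0: not related
  empty <- matrix(0L, 20L, 100L)
  r0 <- blockRelatedness(data.frame(start = 0L, end = 10L),
                         data.frame(start = 5L, end = 15L), empty, empty, mix)
  expect_identical(r0$score, 0)
  expect_false(r0$related)
})

test_that("blocks shared with the query subfamily are marked related; subfamily-specific ones are not", {
  mix <- testMixture()
  pb <- data.frame(start = c(40L, 120L), end = c(80L, 160L),
                   shared = c(TRUE, FALSE), conservation = 0.9)
  hits <- 0L
  for (s in 1:5) {
    fx <- generateFixture(seed = s, nSubfamilies = 2, membersPerSubfamily = 8,
                          nCols = 200, plantedBlocks = pb, nUnrelated = 0)
    p <- clusterSubfamilies(pairwiseDistances(fx$msa), 1L)
    expect_length(subfamilies(p), 2L)
    cl <- lapply(subfamilies(p), function(x) columnCounts(fx$msa, x))
    blocks <- do.call(rbind, lapply(1:2, function(f)
      detectCoreBlocks(scoreTrack(fx$msa, subfamilies(p)[[f]], mix,
                                  subfamily = f))))
    blocks <- markQueryRelatedBlocks(blocks, p, cl, mix)
    expect_true(all(blocks$relatedToQuery[blocks$subfamily == querySubfamily(p)]))
    other <- blocks[blocks$subfamily != querySubfamily(p), , drop = FALSE]
    sharedRel <- other$relatedToQuery[other$start < 80 & other$end > 40]
    specificRel <- other$relatedToQuery[other$start >= 80 & other$end > 120]
    expect_true(all(sharedRel))
    expect_false(any(specificRel))
    hits <- hits + 1L
  }
  expect_identical(hits, 5L)
})

test_that("without query-subfamily blocks every other block is unrelated", {
  mix <- testMixture()
  blocks <- data.frame(subfamily = 2L, start = 0L, end = 10L, meanProb = 0.5,
                       blockScore = 5, relatedToQuery = NA)
  p <- new("SubfamilyPartition", subfamilies = list(1L, 2:3),
           orphans = integer(0), querySubfamily = 1L)
  counts <- list(matrix(0L, 20, 10), matrix(0L, 20, 10))
  expect_warning(out <- markQueryRelatedBlocks(blocks, p, counts, mix),
                 "no core blocks")
  expect_false(any(out$relatedToQuery))
})

test_that("planted conserved domains are recovered with high column overlap", {
  mix <- testMixture()
  jac <- vapply(1:50, function(s) {
    fx <- generateFixture(seed = s, nSubfamilies = 1, membersPerSubfamily = 12,
                          nCols = 240,
                          plantedBlocks = data.frame(start = 90L, end = 150L,
                                                     shared = TRUE,
                                                     conservation = 0.9),
                          nUnrelated = 0)
    tr <- scoreTrack(fx$msa, 1:12, mix, subfamily = 1L)
    b <- detectCoreBlocks(tr)
    det <- logical(240)
    for (i in seq_len(nrow(b))) det[(b$start[i] + 1L):b$end[i]] <- TRUE
    pl <- logical(240); pl[91:150] <- TRUE
    sum(det & pl) / sum(det | pl)
  }, numeric(1L))
  expect_gte(mean(jac), 0.8)
})
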