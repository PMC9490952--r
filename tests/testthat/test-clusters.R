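# Build n distinct 28-nt tag sequences with controlled 5' base and 10th
# base ("U" -> 1U read, "A" -> 10A read, "x" -> neither).
biasSeqs <- function(n, kind = "U", seed = 1) {
  body <- randomSeqs(n, 27, seed = seed)
  body <- gsub("A", "G", body)  # keep position 10 under control
  switch(kind,
    U = paste0("T", body),
    A = paste0("G", substr(body, 1, 8), "A", substr(body, 10, 27)),
    x = paste0("G", substr(body, 1, 8), "G", substr(body, 10, 27)))
}

hitsAcross <- function(tagSeqs, starts, contig = "c1", strand = "+",
                       count = 1) {
  makeHitFixture(data.frame(
    contig = contig, start = starts, len = nchar(tagSeqs),
    strand = strand, tagSeq = tagSeqs, count = count,
    stringsAsFactors = FALSE))
}

test_that("candidate scanning groups hits by gap and applies run minima", {
  # hits every 100 bp across 2 kb with gap 500 -> one candidate
  fx <- hitsAcross(biasSeqs(21, "U"), starts = seq(1, 2001, by = 100))
  cands <- scanCandidates(fx$hits, maxGap = 500, minTags = 10,
                          minWeight = 20)
  expect_length(cands, 1)
  expect_equal(GenomicRanges::start(cands), 1)
  expect_equal(GenomicRanges::end(cands), 2028)

  # two groups separated by 5 kb -> two candidates
  fx2 <- hitsAcross(biasSeqs(24, "U"),
                    starts = c(seq(1, 1101, by = 100),
                               seq(6200, 7300, by = 100)))
  expect_length(scanCandidates(fx2$hits, minWeight = 10), 2)

  # too few tags -> no candidate
  fx3 <- hitsAcross(biasSeqs(5, "U"), starts = seq(1, 401, by = 100))
  expect_length(scanCandidates(fx3$hits, minTags = 10, minWeight = 1), 0)

  expect_length(scanCandidates(GenomicRanges::GRanges()), 0)
})

test_that("acceptance flips exactly at the printed 0.75 and 1000 bp thresholds", {
  starts <- seq(1, 1486, length.out = 100)  # span 1500 with 28-nt reads
  mkCand <- function(nU, span = 1500) {
    sq <- c(biasSeqs(nU, "U", seed = 2), biasSeqs(100 - nU, "x", seed = 3))
    st <- seq(1, span - 28 + 1, length.out = 100)
    fx <- hitsAcross(sq, starts = round(st))
    cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(
      min(GenomicRanges::start(fx$hits)), max(GenomicRanges::end(fx$hits))))
    clusterFilters(cand, fx$hits, fx$tags)
  }
  # 80 of 100 reads with 5'U over 1500 bp -> accept
  expect_true(mkCand(80)$accept)
  # exactly 0.75 passes; 0.74 fails
  expect_true(mkCand(75)$accept)
  r <- mkCand(74)
  expect_false(r$accept)
  expect_equal(r$frac1u10a, 0.74)
  # 10A rescues reads without 5'U
  sqA <- c(biasSeqs(40, "U", seed = 4), biasSeqs(40, "A", seed = 5),
           biasSeqs(20, "x", seed = 6))
  fxA <- hitsAcross(sqA, starts = round(seq(1, 1473, length.out = 100)))
  candA <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1500))
  expect_equal(clusterFilters(candA, fxA$hits, fxA$tags)$frac1u10a, 0.80)

  # span 999 bp rejects, span 1000 accepts, all else perfect
  spanCand <- function(span) {
    sq <- biasSeqs(100, "U", seed = 7)
    st <- round(seq(1, span - 28 + 1, length.out = 100))
    fx <- hitsAcross(sq, starts = st)
    cand <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, span))
    clusterFilters(cand, fx$hits, fx$tags)
  }
  expect_false(spanCand(999)$accept)
  expect_true(spanCand(1000)$accept)

  # typical-length filter: 26 of 100 reads outside 24-35 nt -> reject
  long <- vapply(randomSeqs(26, 40, seed = 8), function(s)
    paste0("T", substr(s, 2, 40)), character(1), USE.NAMES = FALSE)
  sqL <- c(biasSeqs(74, "U", seed = 9), long)
  fxL <- hitsAcross(sqL, starts = round(seq(1, 1461, length.out = 100)))
  candL <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 1500))
  rl <- clusterFilters(candL, fxL$hits, fxL$tags)
  expect_equal(rl$fracTypicalLen, 0.74)
  expect_false(rl$accept)
})

test_that("directionality is mono at >= 0.75 main-strand weight, bi below", {
  mkDir <- function(nPlus, nMinus) {
    sq <- biasSeqs(nPlus + nMinus, "U", seed = 10)
    fx <- hitsAcross(sq, starts = seq_len(nPlus + nMinus) * 30,
                     strand = rep(c("+", "-"), c(nPlus, nMinus)))
    classifyDirectionality(fx$hits)
  }
  expect_equal(mkDir(100, 0), "mono:+")
  expect_equal(mkDir(50, 50), "bi")
  expect_equal(mkDir(80, 20), "mono:+")
  expect_equal(mkDir(20, 80), "mono:-")
  expect_equal(mkDir(74, 26), "bi")
  expect_equal(mkDir(75, 25), "mono:+")
})

test_that("called clusters always satisfy the printed thresholds and behave monotonically", {
  truth <- tinyTruth()
  lib <- do.call(c, lapply(c("FB-", "FB+"), function(g)
    simulateSrnaLibrary(truth, g, nReads = 3000, mirnaFrac = 0,
                        seed = match(g, c("FB-", "FB+")))))
  tags <- collapseReads(lengthFilter(lib))
  hits <- mapTags(tags, buildGenomeIndex(truth))$hits
  cl <- callClusters(hits, tags)
  expect_length(cl, 1)
  m <- S4Vectors::mcols(cl)
  expect_true(all(m$size >= 1000))
  expect_true(all(m$frac1u10a >= 0.75))
  expect_true(all(m$fracTypicalLen >= 0.75))
  expect_true(all(m$mainStrandFraction >= 0.5 & m$mainStrandFraction <= 1))
  expect_equal(m$directionality, "mono:+")
  expect_true(m$`expressed.FB-` && m$`expressed.FB+`)

  # raising minima never increases the number of accepted clusters
  n0 <- length(cl)
  for (args in list(list(minTags = 200), list(minWeight = 5000),
                    list(minSize = 2000))) {
    n <- length(do.call(callClusters, c(list(hits, tags), args)))
    expect_lte(n, n0)
  }
  # degenerate minimum size: pipeline-compatible empty result
  expect_length(callClusters(hits, tags, minSize = 1e9), 0)
  expect_length(callClusters(GenomicRanges::GRanges(), tags), 0)
})

test_that("noise-free planted clusters are recovered with full precision and recall", {
  truth <- simulateGenome(
    3, 20000,
    clusterSpec = data.frame(
      contig = c("contig1", "contig2", "contig3"),
      start = c(3001, 8001, 12001), end = c(4800, 10500, 13400),
      directionality = c("mono:+", "mono:-", "bi"),
      strandFraction = c(0.95, 0.95, 0.5),
      u1Prob = 0.9, a10Prob = 0.3),
    seed = 61)
  lib <- do.call(c, lapply(SRNA_GROUPS <- c("FB-", "FB+", "MB-", "MB+"),
    function(g) simulateSrnaLibrary(truth, g, nReads = 8000,
                                    mirnaFrac = 0,
                                    seed = 70 + match(g, SRNA_GROUPS))))
  tags <- collapseReads(lengthFilter(lib))
  hits <- mapTags(tags, buildGenomeIndex(truth))$hits
  cl <- callClusters(hits, tags)
  tr <- plantedClusters(truth)
  expect_length(cl, 3)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(cl, tr,
                                                     ignore.strand = TRUE))
  expect_length(ov, 3)
  # reciprocal overlap >= 80 %
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(cl)[S4Vectors::queryHits(ov)],
    GenomicRanges::granges(tr)[S4Vectors::subjectHits(ov)],
    ignore.strand = TRUE))
  expect_true(all(w / GenomicRanges::width(cl)[S4Vectors::queryHits(ov)]
                  >= 0.8))
  expect_true(all(w / GenomicRanges::width(tr)[S4Vectors::subjectHits(ov)]
                  >= 0.8))
  expect_equal(S4Vectors::mcols(cl)$directionality[S4Vectors::queryHits(ov)],
               S4Vectors::mcols(tr)$directionality[S4Vectors::subjectHits(ov)])
})

test_that("overlapping clusters from parameter re-runs merge by union", {
  truth <- tinyTruth()
  lib <- simulateSrnaLibrary(truth, "FB+", nReads = 3000, mirnaFrac = 0,
                             seed = 81)
  tags <- collapseReads(lengthFilter(lib))
  hits <- mapTags(tags, buildGenomeIndex(truth))$hits
  a <- callClusters(hits, tags)
  b <- callClusters(hits, tags, maxGap = 300)
  merged <- mergeClusterRuns(list(a, b), hits, tags)
  expect_length(merged, 1)
  expect_lte(GenomicRanges::start(merged),
             min(GenomicRanges::start(a), GenomicRanges::start(b)))
  expect_gte(GenomicRanges::end(merged),
             max(GenomicRanges::end(a), GenomicRanges::end(b)))
})
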