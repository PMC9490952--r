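test_that("genome simulation is deterministic and respects planted truth", {
  t1 <- simulateGenome(2, 10000, seed = 1)
  expect_length(genomeSeq(t1), 2)
  expect_true(all(Biostrings::width(genomeSeq(t1)) == 10000))
  expect_length(plantedClusters(t1), 0)

  # same seed -> byte-identical FASTA
  t2 <- simulateGenome(2, 10000, seed = 7)
  t3 <- simulateGenome(2, 10000, seed = 7)
  f2 <- tempfile(fileext = ".fasta"); f3 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(genomeSeq(t2), f2)
  Biostrings::writeXStringSet(genomeSeq(t3), f3)
  expect_identical(readLines(f2), readLines(f3))
  expect_false(identical(as.character(genomeSeq(t1)),
                         as.character(genomeSeq(t2))))

  # planted cluster round-trips through the truth BED exactly
  tr <- simulateGenome(
    2, 10000,
    clusterSpec = data.frame(contig = "contig1", start = 2001, end = 3500),
    seed = 5)
  d <- tempfile(); paths <- exportTruth(tr, d)
  bed <- readTruthBed(paths[["clusters"]])
  expect_length(bed, 1)
  expect_equal(GenomicRanges::start(bed), 2001)
  expect_equal(GenomicRanges::end(bed), 3500)
  # and re-reading the FASTA reproduces the sequences exactly
  again <- Biostrings::readDNAStringSet(paths[["genome"]])
  expect_identical(as.character(again), as.character(genomeSeq(tr)))
})

test_that("genome simulation rejects invalid plantings", {
  expect_error(
    simulateGenome(1, 5000,
                   clusterSpec = data.frame(contig = "contig1",
                                            start = 4000, end = 6000),
                   seed = 1),
    "bounds")
  expect_error(
    simulateGenome(1, 9000,
                   clusterSpec = data.frame(
                     contig = c("contig1", "contig1"),
                     start = c(1000, 1500), end = c(2500, 3000),
                     directionality = c("mono:+", "mono:+")),
                   seed = 1),
    "overlap")
  expect_error(simulateGenome(2, 5000, bContigs = c(contig1 = 0.5),
                              seed = 1),
               ">= 1")
})

test_that("TE copy mutation realizes exact transition/transversion counts", {
  cons <- randomSeqs(1, 100, seed = 2)
  # no mutation requested -> identity
  m0 <- mutateTeCopy(cons, 0, 0, seed = 1)
  expect_identical(m0$sequence, cons)
  expect_equal(c(m0$p, m0$q), c(0, 0))

  m <- mutateTeCopy(cons, 0.10, 0.05, seed = 3)
  expect_equal(nchar(m$sequence), 100)
  # direct pairwise comparison: exactly 10 transitions, 5 transversions
  a <- strsplit(cons, "")[[1]]; b <- strsplit(m$sequence, "")[[1]]
  mism <- which(a != b)
  pur <- c("A", "G")
  ts <- sum((a[mism] %in% pur) == (b[mism] %in% pur))
  expect_equal(ts, 10)
  expect_equal(length(mism) - ts, 5)
  expect_equal(m$p, 0.10)
  expect_equal(m$q, 0.05)

  expect_error(mutateTeCopy(substr(cons, 1, 49), 0.1, 0.05, seed = 1),
               ">= 50")
  expect_error(mutateTeCopy(cons, 0.5, 0.3, seed = 1), "range")
})

test_that("sRNA library simulation honors its contracts", {
  truth <- tinyTruth()
  expect_error(simulateSrnaLibrary(truth, "XB+", seed = 1), "unknown group")

  # empty library is a valid empty FASTQ
  fq <- tempfile(fileext = ".fastq")
  r0 <- simulateSrnaLibrary(truth, "FB-", nReads = 0, seed = 1, path = fq)
  expect_length(r0, 0)
  expect_identical(readLines(fq), character(0))

  # forced 5'U: all piRNA-derived reads begin with T
  r <- simulateSrnaLibrary(truth, "FB+", nReads = 1000, u1Prob = 1,
                           mirnaFrac = 0, seed = 2)
  expect_length(r, 1000)
  expect_true(all(substr(as.character(r), 1, 1) == "T"))

  # point-mass length profile -> point-mass histogram
  r28 <- simulateSrnaLibrary(truth, "MB-", nReads = 500,
                             lengthProfile = c(`28` = 1), mirnaFrac = 0,
                             seed = 3)
  expect_true(all(Biostrings::width(r28) == 28))

  # reads are exact genomic substrings at their planted origins
  idx <- buildGenomeIndex(truth)
  tags <- collapseReads(r28)
  expect_length(mapTags(tags, idx)$unmapped, 0)

  # determinism: same arguments + seed -> byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  simulateSrnaLibrary(truth, "FB+", nReads = 200, seed = 9, path = f1)
  simulateSrnaLibrary(truth, "FB+", nReads = 200, seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))

  # noise fraction contributes the requested number of reads
  rn <- simulateSrnaLibrary(truth, "FB+", nReads = 1000, noiseFrac = 0.2,
                            seed = 4)
  expect_equal(sum(S4Vectors::mcols(rn)$origin == "noise"), 200)
  expect_length(rn, 1000)
})

test_that("B- libraries never express B-exclusive clusters", {
  truth <- simulateGenome(
    2, 8000,
    clusterSpec = data.frame(
      contig = c("contig1", "contig2"), start = 2001, end = 3500,
      directionality = "mono:+"),
    bContigs = c(contig1 = 3), seed = 21)
  expect_equal(unname(S4Vectors::mcols(plantedClusters(truth))$bExclusive),
               c(TRUE, FALSE))
  rMinus <- simulateSrnaLibrary(truth, "MB-", nReads = 2000,
                                mirnaFrac = 0, seed = 5)
  tags <- collapseReads(rMinus)
  hits <- mapTags(tags, buildGenomeIndex(truth))$hits
  onB <- sum(as.character(GenomicRanges::seqnames(hits)) == "contig1" &
             GenomicRanges::start(hits) >= 2001 &
             GenomicRanges::end(hits) <= 3500)
  expect_equal(onB, 0)
})

test_that("WGS simulation reproduces multiplier-scaled depth and SNP allele frequencies", {
  truth <- simulateGenome(2, 5000, bContigs = c(contig2 = 3), seed = 31)
  lens <- stats::setNames(Biostrings::width(genomeSeq(truth)),
                          names(genomeSeq(truth)))

  # B-: multipliers ignored
  simM <- simulateWgs(truth, "B-", meanDepth = 20, readLength = 100,
                      seed = 1)
  baseOn <- function(sim, cn) {
    sel <- as.character(GenomicRanges::seqnames(sim$placements)) == cn
    sum(GenomicRanges::width(sim$placements)[sel]) / lens[[cn]]
  }
  expect_lt(abs(baseOn(simM, "contig2") - 20) / 20, 0.15)

  # B+: depth scales with the multiplier
  simP <- simulateWgs(truth, "B+", meanDepth = 20, readLength = 100,
                      seed = 2)
  expect_lt(abs(baseOn(simP, "contig1") - 20) / 20, 0.15)
  expect_lt(abs(baseOn(simP, "contig2") - 60) / 60, 0.15)

  # determinism
  simP2 <- simulateWgs(truth, "B+", meanDepth = 20, readLength = 100,
                       seed = 2)
  expect_identical(as.character(simP$reads), as.character(simP2$reads))

  # alt allele frequency ~ (m-1)/m = 0.5 at multiplier 2, depth >= 40
  truth2 <- simulateGenome(1, 4000, bContigs = c(contig1 = 2),
                           nSnpsPerBContig = 3, seed = 33)
  sim2 <- simulateWgs(truth2, "B+", meanDepth = 40, readLength = 100,
                      seed = 3)
  snp <- bSnps(truth2)[1, ]
  obs <- hitSequences(sim2$placements, genomeSeq(truth2))
  # tally bases of reads overlapping the site (reference orientation)
  covers <- GenomicRanges::start(sim2$placements) <= snp$pos &
            GenomicRanges::end(sim2$placements) >= snp$pos
  readsRef <- as.character(sim2$reads)
  neg <- as.character(GenomicRanges::strand(sim2$placements)) == "-"
  readsRef[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(readsRef[neg])))
  off <- snp$pos - GenomicRanges::start(sim2$placements) + 1
  bases <- substr(readsRef[covers], off[covers], off[covers])
  altFreq <- mean(bases == snp$alt)
  expect_gt(length(bases), 30)
  expect_lt(abs(altFreq - 0.5), 0.1)

  # B- emits no alt alleles
  simM2 <- simulateWgs(truth2, "B-", meanDepth = 40, readLength = 100,
                       seed = 4)
  pile <- alignmentPileup(simM2$reads, simM2$placements, genomeSeq(truth2))
  expect_equal(nrow(pile$sites), 0)
})
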