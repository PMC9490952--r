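test_that("kimura2p evaluates the two-parameter closed form on its domain", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.10, 0.05),
               -0.5 * log((1 - 2 * 0.10 - 0.05) * sqrt(1 - 2 * 0.05)),
               tolerance = 1e-15)
  expect_equal(round(kimura2p(0.10, 0.05), 4), 0.1702)
  # monotone increasing in p and q
  expect_gt(kimura2p(0.11, 0.05), kimura2p(0.10, 0.05))
  expect_gt(kimura2p(0.10, 0.06), kimura2p(0.10, 0.05))
  # domain violations saturate with an error
  expect_error(kimura2p(0.40, 0.30), "beyond model domain")
  expect_error(kimura2p(0.1, 0.5), "beyond model domain")
  expect_error(kimura2p(-0.1, 0), "non-negative")
  # small-divergence limit: K ~ p + q within 10 % for p + q <= 0.05
  for (pq in list(c(0.02, 0.01), c(0.03, 0.02), c(0.005, 0.005))) {
    K <- kimura2p(pq[1], pq[2])
    expect_lt(abs(K - sum(pq)) / sum(pq), 0.1)
  }
})

test_that("alignment divergence equals the brute-force per-site count", {
  ident <- strrep("ACGT", 25)
  e <- alignmentDivergence(ident, ident)
  expect_equal(c(e$p, e$q, e$K, e$nSites), c(0, 0, 0, 100))

  e2 <- alignmentDivergence("GAAAAAAAAT", "AAAAAAAAAA")
  expect_equal(c(e2$p, e2$q), c(0.1, 0.1))
  expect_equal(round(e2$K, 4), 0.2341)

  # gaps are stripped pairwise; N is not a usable site
  e3 <- alignmentDivergence("GA-AAAAAANT", "AA-AAAAAAAT")
  expect_equal(e3$nSites, 9)
  expect_equal(e3$p, 1 / 9)

  expect_error(alignmentDivergence("----", "----"), "zero usable")
  expect_error(alignmentDivergence("ACGT", "ACG"), "equal length")

  # property: agreement with the brute-force classifier on random pairs
  a <- randomSeqs(25, 100, seed = 101)
  b <- randomSeqs(25, 100, seed = 202)
  for (i in seq_along(a)) {
    mine <- alignmentDivergence(a[i], b[i])
    oracle <- bruteDivergence(a[i], b[i])
    expect_equal(mine$p, oracle$p)
    expect_equal(mine$q, oracle$q)
    expect_equal(mine$nSites, oracle$n)
  }
})

test_that("CpG masking skips consensus CpG dinucleotide positions", {
  #          1234567
  cons <- "ACGTACGA"
  copy <- "ATGTATGA"   # mismatches at 2 and 6, both inside CpG (pos 2-3, 6-7)
  eAll <- alignmentDivergence(copy, cons)
  expect_equal(eAll$nSites, 8)
  expect_gt(eAll$p + eAll$q, 0)
  eCpg <- alignmentDivergence(copy, cons, excludeCpG = TRUE)
  expect_equal(eCpg$nSites, 4)
  expect_equal(eCpg$p + eCpg$q, 0)
  expect_true(eCpg$cpgExcluded)
})

test_that("mutate-then-estimate round-trips the realized proportions exactly", {
  cons <- randomSeqs(1, 400, seed = 7)
  for (tc in list(c(0.10, 0.05), c(0.02, 0.02), c(0, 0.1))) {
    m <- mutateTeCopy(cons, tc[1], tc[2], seed = 13)
    e <- alignmentDivergence(m$sequence, cons)
    expect_equal(e$p, m$p)
    expect_equal(e$q, m$q)
  }
})

test_that("landscapes bin aligned bp by floor(100K) and conserve mass", {
  est <- data.frame(family = c("hAT", "hAT", "L2"),
                    K = c(0.053, 0.012, 0.49),
                    alignedBp = c(500, 300, 200))
  ls <- teLandscape(est)
  expect_equal(ls$bp[ls$family == "hAT" & ls$bin == 5], 500)
  expect_equal(ls$bp[ls$family == "hAT" & ls$bin == 1], 300)
  expect_equal(sum(ls$bp), sum(est$alignedBp))
  # clamping at maxBin
  expect_equal(teLandscape(data.frame(family = "x", K = 0.9,
                                      alignedBp = 10))$bin, 50)
  expect_equal(nrow(teLandscape(NULL)), 0)

  # planted copies at ~5 % divergence concentrate around bin 5
  lib <- Biostrings::DNAStringSet(c(PAO = randomSeqs(1, 600, seed = 31)))
  truth <- simulateGenome(
    2, 10000, teLibrary = lib,
    teSpec = data.frame(contig = c("contig1", "contig2"),
                        start = c(1001, 2001), family = "PAO",
                        pTarget = 0.035, qTarget = 0.015),
    seed = 41)
  ls2 <- truthLandscape(truth, lib)
  expect_true(all(ls2$bin %in% 4:6))
  expect_equal(sum(ls2$bp), 1200)
})

test_that("landscape comparison flags B+ amplified low-divergence mass", {
  a <- data.frame(family = "hAT", bin = c(1, 5), bp = c(100, 100))
  # identical landscapes: nothing flagged
  cmp0 <- compareLandscapes(a, a, 1e4, 1e4)
  expect_true(all(cmp0$diff == 0))
  expect_false(any(cmp0$flagged))
  # B+ with extra low-divergence mass of one family -> low bin flagged
  b <- data.frame(family = "hAT", bin = c(1, 5), bp = c(300, 100))
  cmp <- compareLandscapes(a, b, 1e4, 1e4)
  expect_true(cmp$flagged[cmp$bin == 1])
  expect_false(cmp$flagged[cmp$bin == 5])
  # family absent from both is absent from the output
  expect_false("L2" %in% cmp$family)
  expect_error(compareLandscapes(a, data.frame(family = "hAT",
                                               bin = c(0, 2), bp = 1:2)),
               "different binnings")

  # multiplier-scaled truth landscapes reproduce the pattern end to end:
  # the hAT copy on the multiplier-3 contig triples in the B+ assembly
  lib <- Biostrings::DNAStringSet(c(hAT = randomSeqs(1, 500, seed = 51),
                                    L2 = randomSeqs(1, 500, seed = 52)))
  truth <- simulateGenome(
    10, 8000, teLibrary = lib,
    teSpec = data.frame(
      contig = c("contig1", "contig2", "contig3"),
      start = 1001, family = c("hAT", "hAT", "L2"),
      pTarget = c(0.02, 0.02, 0.10), qTarget = c(0.01, 0.01, 0.05)),
    bContigs = c(contig1 = 3), seed = 53)
  lsM <- truthLandscape(truth, lib, "B-")
  lsP <- truthLandscape(truth, lib, "B+")
  gSize <- sum(Biostrings::width(genomeSeq(truth)))
  gEff <- gSize + 2 * 8000  # B+ assembly carries contig1 three times
  cmp2 <- compareLandscapes(lsM, lsP, gSize, gEff)
  flaggedFams <- unique(cmp2$family[cmp2$flagged])
  expect_identical(flaggedFams, "hAT")
})

test_that("RepeatMasker .out parsing maps columns, strands and classes", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left)  ID",
    "",
    "  463   10.4  0.0  0.0  contig1    101   400  (9600) + hAT-Ac    DNA/hAT-Ac      1  300   (0)   1",
    "  312    5.1  0.3  0.0  contig1    901  1100  (8900) C L2-fish   LINE/L2         1  200  (10)   2 *",
    "  199   22.9  0.1  0.2  contig2     51   250  (9750) + PAO-x     LTR/Pao         1  200   (0)   3"),
    out)
  ann <- parseRepeatMaskerOut(out)
  expect_length(ann, 3)
  expect_equal(S4Vectors::mcols(ann)$teClass, c("DNA", "LINE", "LTR"))
  expect_equal(as.character(GenomicRanges::strand(ann)), c("+", "-", "+"))
  expect_equal(GenomicRanges::start(ann), c(101, 901, 51))
  expect_equal(S4Vectors::mcols(ann)$divergencePct, c(10.4, 5.1, 22.9))

  # empty after headers
  empty <- tempfile(fileext = ".out")
  writeLines(c("header", "header", ""), empty)
  expect_length(parseRepeatMaskerOut(empty), 0)

  # malformed column count reports the line number
  bad <- tempfile(fileext = ".out")
  writeLines(c("h", "h", "", "  463   10.4  0.0"), bad)
  expect_error(parseRepeatMaskerOut(bad), "line 4")
})

test_that("piRNA mass is classified by largest-overlap TE annotation", {
  ann <- GenomicRanges::GRanges(
    c("c1", "c1", "c1"),
    IRanges::IRanges(c(100, 131, 300), c(130, 160, 340)),
    teClass = c("DNA", "LTR", "LINE"))
  # hit 111..138: 20 bp on DNA vs 8 bp on LTR -> DNA
  fx <- makeHitFixture(data.frame(
    contig = "c1", start = c(111, 305, 500), len = 28, strand = "+",
    tagSeq = randomSeqs(3, 28, seed = 61), count = c(4, 2, 2),
    stringsAsFactors = FALSE))
  prof <- classifyPirnaTe(fx$hits, ann, fx$tags)
  pct <- stats::setNames(prof$pct, prof$teClass)
  expect_equal(unname(pct["DNA"]), 50)
  expect_equal(unname(pct["LINE"]), 25)
  expect_equal(unname(pct["non-TE"]), 25)
  expect_false("LTR" %in% prof$teClass[prof$mass > 0])
  expect_lte(sum(prof$pct[prof$teClass != "non-TE"]), 100)
})
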