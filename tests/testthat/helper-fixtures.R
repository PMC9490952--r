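# Shared fixture builders and independent oracles.

# A tiny two-contig truth with one planted cluster; cheap enough for most
# unit tests.
tinyTruth <- function(seed = 11, contigLength = 6000L, multiplier = NULL,
                      nSnps = 0L) {
  simulateGenome(
    nContigs = 2, contigLength = contigLength,
    clusterSpec = data.frame(contig = "contig1", start = 2001L,
                             end = 3500L, directionality = "mono:+",
                             strandFraction = 0.95,
                             u1Prob = 0.9, a10Prob = 0.3),
    bContigs = multiplier, nSnpsPerBContig = nSnps, seed = seed)
}

# Hand-built hit stream: one hit per row of the description data.frame
# (contig, start, len, strand, tagSeq, count).
makeHitFixture <- function(df) {
  tab <- table(factor(df$tagSeq, levels = unique(df$tagSeq)))
  tags <- TagSet(unique(df$tagSeq),
                 matrix(as.integer(df$count[match(unique(df$tagSeq),
                                                  df$tagSeq)]),
                        ncol = 1, dimnames = list(NULL, "LIB")))
  tagId <- match(df$tagSeq, unique(df$tagSeq))
  nh <- as.integer(table(tagId)[as.character(tagId)])
  hits <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start, df$start + df$len - 1L),
    strand = df$strand, tagId = tagId, nGenomicHits = nh,
    weight = df$count[match(unique(df$tagSeq), df$tagSeq)][tagId] / nh)
  list(tags = tags, hits = hits)
}

# Brute-force mapper: slide a window over every contig position on both
# strands and count mismatches directly. The oracle for mapTags.
bruteMap <- function(seq, genome, maxMismatch = 0) {
  out <- list()
  L <- nchar(seq)
  countMismatch <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (cn in names(genome)) {
    g <- as.character(genome[[cn]])
    if (nchar(g) < L) next
    for (s in seq_len(nchar(g) - L + 1)) {
      win <- substr(g, s, s + L - 1)
      mmF <- countMismatch(seq, win)
      rcw <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(win)))
      mmR <- countMismatch(seq, rcw)
      if (mmF <= maxMismatch)
        out[[length(out) + 1]] <- data.frame(contig = cn, start = s,
                                             strand = "+", mm = mmF)
      if (mmR <= maxMismatch)
        out[[length(out) + 1]] <- data.frame(contig = cn, start = s,
                                             strand = "-", mm = mmR)
    }
  }
  if (!length(out)) return(NULL)
  all <- do.call(rbind, out)
  all[all$mm == min(all$mm), , drop = FALSE]  # best stratum
}

# Brute-force per-site transition/transversion counter. The oracle for
# alignmentDivergence.
bruteDivergence <- function(copy, consensus) {
  a <- strsplit(copy, "")[[1]]
  b <- strsplit(consensus, "")[[1]]
  pur <- c("A", "G")
  ts <- 0; tv <- 0; n <- 0
  for (i in seq_along(a)) {
    if (!(a[i] %in% c("A", "C", "G", "T")) ||
        !(b[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1
    if (a[i] != b[i]) {
      samePur <- (a[i] %in% pur) == (b[i] %in% pur)
      if (samePur) ts <- ts + 1 else tv <- tv + 1
    }
  }
  list(p = ts / n, q = tv / n, n = n)
}

randomSeqs <- function(n, len, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1)))
}
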