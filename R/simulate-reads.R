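#' Default small-RNA length profile
#'
#' Discrete probability mass over read lengths for simulated piRNA-derived
#' reads, peaked at 28-29 nt as observed for gonadal piRNA populations.
#' @return named numeric vector of probabilities (names are lengths in nt).
#' @export
defaultLengthProfile <- function() {
  c(`26` = 0.08, `27` = 0.15, `28` = 0.28, `29` = 0.27,
    `30` = 0.14, `31` = 0.08)
}

# Sample read start positions inside a cluster so that the 5' base bias is
# realized by placement: exact genomic substrings, no sequence editing.
# Returns global 1-based starts on the contig.
.sampleBiasedStarts <- function(chars, cs, ce, L, n, strandChar,
                                u1Prob, a10Prob) {
  lastStart <- ce - L + 1L
  if (lastStart < cs || n == 0) return(integer())
  gstarts <- cs:lastStart
  if (strandChar == "+") {
    first <- chars[gstarts]
    tenth <- chars[gstarts + 9L]
    isU <- first == "T"
    isA10 <- tenth == "A"
  } else {
    # minus-strand read 5' base is the complement of the base at its
    # rightmost genomic position; 10th base maps to offset L-10 from start
    isU <- chars[gstarts + L - 1L] == "A"
    isA10 <- chars[gstarts + L - 10L] == "T"
  }
  setU <- gstarts[isU]
  setA <- gstarts[!isU & isA10]
  setO <- gstarts[!isU & !isA10]
  pick <- function(set, k) {
    if (k == 0) return(integer())
    if (!length(set)) set <- gstarts  # degenerate cluster composition
    set[sample.int(length(set), k, replace = TRUE)]
  }
  u <- stats::runif(n) < u1Prob
  a <- !u & stats::runif(n) < a10Prob
  out <- integer(n)
  out[u] <- pick(setU, sum(u))
  out[a] <- pick(setA, sum(a))
  out[!u & !a] <- pick(setO, sum(!u & !a))
  out
}

#' Simulate one gonadal small-RNA sequencing library
#'
#' Draws \code{nReads} single-end reads for one of the four gonad groups
#' (female/male crossed with B-chromosome absence/presence). Reads are a
#' mixture of piRNA-derived reads from the planted clusters, miRNA-derived
#' reads of 21-22 nt from the planted miRNA loci, and (optionally) uniform
#' random genomic noise fragments. piRNA reads carry a 5'U with probability
#' \code{u1Prob} and, among the remaining reads, a 10A with probability
#' \code{a10Prob}; both biases are realized by placing read starts at
#' genomic positions with the required base, so every simulated read is an
#' exact genomic substring. B- groups never draw reads from clusters marked
#' B-exclusive.
#'
#' @param truth a [GenomeTruth].
#' @param group one of \code{"FB-"}, \code{"FB+"}, \code{"MB-"}, \code{"MB+"}.
#' @param nReads number of reads to emit (exactly).
#' @param lengthProfile named probability vector over piRNA read lengths;
#'   default [defaultLengthProfile()].
#' @param u1Prob probability that a piRNA-derived read starts with U (T);
#'   \code{NULL} (default) uses each planted cluster's own value.
#' @param a10Prob probability that a non-5'U piRNA-derived read carries an
#'   A at position 10; \code{NULL} uses the planted per-cluster value.
#' @param noiseFrac fraction of reads that are uniform random genomic
#'   fragments (default 0: noise-free).
#' @param mirnaFrac fraction of the non-noise reads drawn from miRNA loci
#'   (default 0.3; ignored when no miRNA loci are planted).
#' @param seed integer seed.
#' @param path optional FASTQ output path (Phred+33, dummy quality "I").
#' @return a [Biostrings::DNAStringSet] with metadata columns
#'   \code{library} (the group) and \code{origin} (\code{"pirna"},
#'   \code{"mirna"} or \code{"noise"}).
#' @export
simulateSrnaLibrary <- function(truth, group, nReads = 2e5,
                                lengthProfile = defaultLengthProfile(),
                                u1Prob = NULL, a10Prob = NULL,
                                noiseFrac = 0, mirnaFrac = 0.3,
                                seed, path = NULL) {
  if (!is.character(group) || length(group) != 1 || !(group %in% SRNA_GROUPS))
    stop("unknown group label '", group, "'; expected one of ",
         paste(SRNA_GROUPS, collapse = ", "))
  stopifnot(is.null(u1Prob) || (u1Prob >= 0 && u1Prob <= 1),
            is.null(a10Prob) || (a10Prob >= 0 && a10Prob <= 1),
            noiseFrac >= 0, noiseFrac <= 1, mirnaFrac >= 0, mirnaFrac <= 1)
  nReads <- as.integer(nReads)
  bPlus <- grepl("\\+$", group)

  genome <- genomeSeq(truth)
  contigChars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)

  clusters <- plantedClusters(truth)
  if (!bPlus && length(clusters))
    clusters <- clusters[!S4Vectors::mcols(clusters)$bExclusive]
  mirnas <- plantedMirnas(truth)

  lengths <- as.integer(names(lengthProfile))
  lengthP <- lengthProfile / sum(lengthProfile)

  nNoise <- round(noiseFrac * nReads)
  nMirna <- if (length(mirnas)) round(mirnaFrac * (nReads - nNoise)) else 0L
  nPi <- nReads - nNoise - nMirna
  if (!length(clusters)) { nNoise <- nNoise + nPi; nPi <- 0L }

  withSeed(seed, {
    seqs <- character(0); origin <- character(0)

    if (nPi > 0) {
      w <- GenomicRanges::width(clusters)
      clIdx <- sample.int(length(clusters), nPi, replace = TRUE,
                          prob = w / sum(w))
      piSeqs <- character(nPi)
      for (ci in seq_along(clusters)) {
        rows <- which(clIdx == ci)
        if (!length(rows)) next
        cl <- clusters[ci]
        cn <- as.character(GenomicRanges::seqnames(cl))
        chars <- contigChars[[cn]]
        dirn <- S4Vectors::mcols(cl)$directionality
        sf <- S4Vectors::mcols(cl)$strandFraction
        mainStrand <- if (dirn == "mono:-") "-" else "+"
        onMain <- stats::runif(length(rows)) < sf
        strandChar <- ifelse(onMain, mainStrand,
                             if (mainStrand == "+") "-" else "+")
        Ls <- lengths[sample.int(length(lengths), length(rows),
                                 replace = TRUE, prob = lengthP)]
        for (st in c("+", "-")) {
          for (L in unique(Ls)) {
            sel <- which(strandChar == st & Ls == L)
            if (!length(sel)) next
            gs <- .sampleBiasedStarts(
              chars, GenomicRanges::start(cl), GenomicRanges::end(cl), L,
              length(sel), st,
              if (is.null(u1Prob)) S4Vectors::mcols(cl)$u1Prob else u1Prob,
              if (is.null(a10Prob)) S4Vectors::mcols(cl)$a10Prob else a10Prob)
            frag <- substring(as.character(genome[[cn]]), gs, gs + L - 1L)
            if (st == "-") frag <- revCompChar(frag)
            piSeqs[rows[sel]] <- frag
          }
        }
      }
      seqs <- c(seqs, piSeqs)
      origin <- c(origin, rep("pirna", nPi))
    }

    if (nMirna > 0) {
      mi <- sample.int(length(mirnas), nMirna, replace = TRUE)
      Ls <- sample(c(21L, 22L), nMirna, replace = TRUE)
      ms <- GenomicRanges::start(mirnas)[mi]
      me <- GenomicRanges::end(mirnas)[mi]
      Ls <- pmin(Ls, me - ms + 1L)
      lastStart <- me - Ls + 1L
      gs <- ms + floor(stats::runif(nMirna) * (lastStart - ms + 1L))
      cn <- as.character(GenomicRanges::seqnames(mirnas))[mi]
      frag <- substring(as.character(genome)[cn], gs, gs + Ls - 1L)
      neg <- as.character(GenomicRanges::strand(mirnas))[mi] == "-"
      if (any(neg)) frag[neg] <- revCompChar(frag[neg])
      seqs <- c(seqs, frag)
      origin <- c(origin, rep("mirna", nMirna))
    }

    if (nNoise > 0) {
      ci <- sample.int(length(genome), nNoise, replace = TRUE,
                       prob = lens / sum(lens))
      Ls <- lengths[sample.int(length(lengths), nNoise,
                               replace = TRUE, prob = lengthP)]
      Ls <- pmin(Ls, lens[ci])
      gs <- 1L + floor(stats::runif(nNoise) * (lens[ci] - Ls + 1L))
      frag <- substring(as.character(genome)[ci], gs, gs + Ls - 1L)
      neg <- stats::runif(nNoise) < 0.5
      if (any(neg)) frag[neg] <- revCompChar(frag[neg])
      seqs <- c(seqs, frag)
      origin <- c(origin, rep("noise", nNoise))
    }

    reads <- Biostrings::DNAStringSet(seqs)
    if (length(reads))
      names(reads) <- paste0(sub("([+-])$", "\\1", group), "_read",
                             seq_along(reads))
    S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
      library = rep(group, length(reads)), origin = origin)
    if (!is.null(path)) writeFastqFile(reads, path)
    reads
  })
}

#' Whole-genome sequencing read simulation for B-/B+ samples
#'
#' Simulates error-free (by default) single-end genomic reads. For a B+
#' sample the expected depth of each contig is \code{meanDepth} times its
#' copy-number multiplier, and a read drawn from one of the B-resident
#' copies (probability \code{(m-1)/m} on a multiplier-\code{m} contig)
#' carries the alternative allele at every B-specific SNP it covers. For a
#' B- sample multipliers are ignored and no alternative alleles are emitted.
#'
#' @param truth a [GenomeTruth].
#' @param bStatus \code{"B-"} or \code{"B+"}.
#' @param meanDepth target fold-coverage of a single-copy contig (> 0).
#' @param readLength read length in bp.
#' @param errorRate per-base substitution error probability (default 0).
#' @param seed integer seed.
#' @return a list of class \code{"WgsSim"} with elements \code{reads}
#'   ([Biostrings::DNAStringSet], sequenced orientation), \code{placements}
#'   ([GenomicRanges::GRanges] of true alignment positions), \code{bStatus},
#'   \code{readLength} and \code{totalMappedBases}.
#' @export
simulateWgs <- function(truth, bStatus = c("B-", "B+"), meanDepth = 20,
                        readLength = 100L, errorRate = 0, seed) {
  bStatus <- match.arg(bStatus)
  if (meanDepth <= 0) stop("meanDepth must be > 0")
  readLength <- as.integer(readLength)
  genome <- genomeSeq(truth)
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  mult <- copyMultiplier(truth)
  snps <- bSnps(truth)
  bPlus <- bStatus == "B+"

  withSeed(seed, {
    allSeq <- character(0)
    allCn <- character(0); allStart <- integer(0); allNeg <- logical(0)
    for (cn in names(genome)) {
      L <- lens[[cn]]
      if (L < readLength) next
      m <- if (bPlus) mult[[cn]] else 1
      n <- round(meanDepth * m * L / readLength)
      if (n == 0) next
      gs <- 1L + floor(stats::runif(n) * (L - readLength + 1L))
      frag <- substring(as.character(genome[[cn]]), gs, gs + readLength - 1L)
      if (bPlus && m > 1 && nrow(snps)) {
        csnps <- snps[snps$contig == cn, , drop = FALSE]
        if (nrow(csnps)) {
          fromB <- stats::runif(n) < (m - 1) / m
          for (k in seq_len(nrow(csnps))) {
            off <- csnps$pos[k] - gs + 1L
            rows <- which(fromB & off >= 1L & off <= readLength)
            if (length(rows))
              substr(frag[rows], off[rows], off[rows]) <- csnps$alt[k]
          }
        }
      }
      if (errorRate > 0) {
        nErr <- stats::rbinom(n, readLength, errorRate)
        for (r in which(nErr > 0)) {
          pos <- sample.int(readLength, nErr[r])
          for (pp in pos) {
            old <- substr(frag[r], pp, pp)
            substr(frag[r], pp, pp) <- sample(setdiff(BASES, old), 1)
          }
        }
      }
      neg <- stats::runif(n) < 0.5
      if (any(neg)) frag[neg] <- revCompChar(frag[neg])
      allSeq <- c(allSeq, frag)
      allCn <- c(allCn, rep(cn, n))
      allStart <- c(allStart, gs)
      allNeg <- c(allNeg, neg)
    }
    reads <- Biostrings::DNAStringSet(allSeq)
    if (length(reads))
      names(reads) <- paste0("wgs_", sub("([+-])$", "\\1", bStatus), "_read",
                             seq_along(reads))
    placements <- GenomicRanges::GRanges(
      allCn, IRanges::IRanges(allStart, allStart + readLength - 1L),
      strand = ifelse(allNeg, "-", "+"))
    S4Vectors::mcols(placements)$readId <- names(reads)
    structure(list(reads = reads, placements = placements,
                   bStatus = bStatus, readLength = readLength,
                   totalMappedBases = sum(GenomicRanges::width(placements))),
              class = "WgsSim")
  })
}

#' @export
print.WgsSim <- function(x, ...) {
  cat("WgsSim [", x$bStatus, "]: ", length(x$reads), " reads of ",
      x$readLength, " bp (", x$totalMappedBases, " mapped bases)\n", sep = "")
  invisible(x)
}

#' Write simulated WGS reads as FASTQ
#' @param sim a \code{WgsSim} from [simulateWgs()].
#' @param path output FASTQ path.
#' @export
writeWgsFastq <- function(sim, path) writeFastqFile(sim$reads, path)

#' Write simulated WGS alignments as SAM
#'
#' Emits a minimal SAM file (\code{@HD}/\code{@SQ} header plus one record
#' per read at its true placement, CIGAR \code{<len>M}); reverse-strand
#' placements are stored reference-oriented with flag 16, following the SAM
#' convention.
#'
#' @param sim a \code{WgsSim} from [simulateWgs()].
#' @param genome the [Biostrings::DNAStringSet] the reads were drawn from.
#' @param path output SAM path.
#' @export
writeWgsSam <- function(sim, genome, path) {
  neg <- as.character(GenomicRanges::strand(sim$placements)) == "-"
  seqs <- as.character(sim$reads)
  if (any(neg)) seqs[neg] <- revCompChar(seqs[neg])
  writeSamFile(
    qname = names(sim$reads),
    flag = ifelse(neg, 16L, 0L),
    rname = as.character(GenomicRanges::seqnames(sim$placements)),
    pos = GenomicRanges::start(sim$placements),
    seq = seqs, genome = genome, path = path)
}
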