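# Read a SAM/BAM file into a GRanges of aligned spans (helper shared by the
# depth and pileup operations; simulator placements can be passed directly).
.readAlignmentSpans <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "cigar")))[[1]]
  keep <- !bitwAnd(b$flag, 4L) & !is.na(b$pos)
  w <- .cigarRefWidth(b$cigar[keep])
  GenomicRanges::GRanges(
    as.character(b$rname)[keep],
    IRanges::IRanges(b$pos[keep], b$pos[keep] + w - 1L),
    strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0, "-", "+"))
}

#' Per-base depth-of-coverage track for one contig
#'
#' \code{depth[i]} counts the reads whose aligned span covers position
#' \code{i}. The track also records the library-wide total of mapped bases,
#' used by [coverageRatio()] to normalize libraries of unequal size.
#'
#' @param alignments aligned spans as a [GenomicRanges::GRanges] (e.g. the
#'   \code{placements} of a [simulateWgs()] result) or a SAM/BAM path.
#' @param contig contig name.
#' @param contigLength contig length in bp; taken from
#'   \code{seqlengths(alignments)} when absent there, the track ends at the
#'   last covered base.
#' @param sample sample label (\code{"B-"} or \code{"B+"}).
#' @return a [DepthTrack].
#' @export
depthProfile <- function(alignments, contig, contigLength = NA,
                         sample = "B+") {
  if (is.character(alignments)) alignments <- .readAlignmentSpans(alignments)
  total <- sum(GenomicRanges::width(alignments))
  known <- unique(as.character(GenomicRanges::seqnames(alignments)))
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (!(contig %in% c(known, names(sl))))
    stop("contig '", contig, "' absent from the alignment set")
  sub <- alignments[as.character(GenomicRanges::seqnames(alignments)) ==
                    contig]
  cov <- GenomicRanges::coverage(GenomicRanges::ranges(sub))
  if (is.na(contigLength) && contig %in% names(sl) && !is.na(sl[[contig]]))
    contigLength <- sl[[contig]]
  if (!is.na(contigLength)) {
    if (length(cov) < contigLength)
      cov <- c(cov, S4Vectors::Rle(0L, contigLength - length(cov)))
    else cov <- cov[seq_len(contigLength)]
  }
  new("DepthTrack", contig = contig, depth = cov, sample = sample,
      totalMappedBases = as.numeric(total))
}

#' Normalized B+/B- coverage ratio for one contig
#'
#' The ratio divides the per-contig mean depths after normalizing each by
#' its library-wide total of mapped bases:
#' \deqn{ratio = (mean_{B+} / total_{B+}) / (mean_{B-} / total_{B-})}
#' A contig is flagged as a putative B-chromosome sequence when the ratio
#' strictly exceeds \code{threshold} (default 2). A zero B- mean yields an
#' infinite ratio, reported with the \code{infinite} marker column.
#'
#' @param trackBplus,trackBminus [DepthTrack]s of the same contig from the
#'   B+ and B- libraries.
#' @param threshold flag contigs with ratio strictly greater than this.
#' @return one-row data.frame: \code{contig}, \code{meanDepthBminus},
#'   \code{meanDepthBplus}, \code{normRatio}, \code{infinite},
#'   \code{flagged}.
#' @export
coverageRatio <- function(trackBplus, trackBminus, threshold = 2) {
  if (trackBplus@contig != trackBminus@contig)
    stop("tracks cover different contigs")
  if (trackBplus@totalMappedBases <= 0 || trackBminus@totalMappedBases <= 0)
    stop("zero total mapped bases")
  mPlus <- mean(trackBplus@depth)
  mMinus <- mean(trackBminus@depth)
  ratio <- if (mMinus == 0) Inf else
    (mPlus / trackBplus@totalMappedBases) /
    (mMinus / trackBminus@totalMappedBases)
  data.frame(contig = trackBplus@contig,
             meanDepthBminus = mMinus, meanDepthBplus = mPlus,
             normRatio = ratio, infinite = is.infinite(ratio),
             flagged = ratio > threshold,
             stringsAsFactors = FALSE)
}

#' Coverage-ratio table over all contigs
#'
#' Vectorized form of [coverageRatio()]: the mean depth of a contig equals
#' its aligned bases divided by its length, so the table is computed from
#' alignment spans without materializing per-base tracks.
#'
#' @param alnBplus,alnBminus aligned spans ([GenomicRanges::GRanges] or
#'   SAM/BAM paths) for the B+ and B- libraries.
#' @param contigLengths named vector of contig lengths (e.g.
#'   \code{width(genomeSeq(truth))} named by contig).
#' @param threshold flag threshold (strict inequality), default 2.
#' @return data.frame with one row per contig, columns as in
#'   [coverageRatio()].
#' @export
coverageRatioTable <- function(alnBplus, alnBminus, contigLengths,
                               threshold = 2) {
  if (is.character(alnBplus)) alnBplus <- .readAlignmentSpans(alnBplus)
  if (is.character(alnBminus)) alnBminus <- .readAlignmentSpans(alnBminus)
  totP <- sum(GenomicRanges::width(alnBplus))
  totM <- sum(GenomicRanges::width(alnBminus))
  if (totP <= 0 || totM <= 0) stop("zero total mapped bases")
  basesOn <- function(aln) {
    b <- tapply(GenomicRanges::width(aln),
                as.character(GenomicRanges::seqnames(aln)), sum)
    out <- stats::setNames(rep(0, length(contigLengths)),
                           names(contigLengths))
    out[names(b)] <- b
    out
  }
  mP <- basesOn(alnBplus) / contigLengths
  mM <- basesOn(alnBminus) / contigLengths
  ratio <- ifelse(mM == 0, Inf, (mP / totP) / (mM / totM))
  data.frame(contig = names(contigLengths),
             meanDepthBminus = unname(mM), meanDepthBplus = unname(mP),
             normRatio = unname(ratio), infinite = is.infinite(ratio),
             flagged = unname(ratio > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate piRNA clusters as B-chromosome candidates
#'
#' A cluster is a B-candidate if and only if the coverage-ratio record of
#' its contig is flagged (ratio strictly above \code{threshold}).
#'
#' @param records coverage-ratio data.frame from [coverageRatioTable()].
#' @param clusters cluster [GenomicRanges::GRanges].
#' @param threshold ratio threshold, default 2.
#' @return \code{clusters} with added metadata columns \code{contigRatio}
#'   and \code{bCandidate}.
#' @export
flagBIntervals <- function(records, clusters, threshold = 2) {
  cn <- as.character(GenomicRanges::seqnames(clusters))
  missing <- setdiff(cn, records$contig)
  if (length(missing))
    stop("no coverage-ratio record for contig(s): ",
         paste(missing, collapse = ", "))
  i <- match(cn, records$contig)
  S4Vectors::mcols(clusters)$contigRatio <- records$normRatio[i]
  S4Vectors::mcols(clusters)$bCandidate <- records$normRatio[i] > threshold
  clusters
}

#' Base-level pileup summary of error-aware alignments
#'
#' Compares each read with the reference at its placement and tallies every
#' mismatching base in reference orientation, together with per-contig
#' coverage. With error-free reads the only mismatch sites are true
#' variants, so the summary stays small even at high depth.
#'
#' @param reads [Biostrings::DNAStringSet] in sequenced orientation.
#' @param placements [GenomicRanges::GRanges] of the reads' aligned spans
#'   (same order as \code{reads}).
#' @param genome named [Biostrings::DNAStringSet].
#' @return a list of class \code{"BasePileup"}: \code{coverage}
#'   (per-contig [S4Vectors::Rle] list), \code{sites} (data.frame
#'   \code{contig}, \code{pos}, \code{ref}, \code{base}, \code{count}),
#'   \code{totalMappedBases}.
#' @export
alignmentPileup <- function(reads, placements, genome) {
  stopifnot(length(reads) == length(placements))
  refs <- hitSequences(placements, genome)
  obs <- as.character(reads)
  mism <- which(refs != obs)
  rows <- list()
  for (r in mism) {
    a <- strsplit(obs[r], "", fixed = TRUE)[[1]]
    b <- strsplit(refs[r], "", fixed = TRUE)[[1]]
    d <- which(a != b)
    neg <- as.character(GenomicRanges::strand(placements))[r] == "-"
    gpos <- if (neg) GenomicRanges::end(placements)[r] - d + 1L
            else GenomicRanges::start(placements)[r] + d - 1L
    base <- a[d]
    if (neg) base <- chartr("ACGT", "TGCA", base)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = as.character(GenomicRanges::seqnames(placements))[r],
      pos = gpos, base = base, stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) {
    df <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df[c("contig", "pos", "base")], FUN = sum)
    agg$ref <- substring(as.character(genome)[agg$contig], agg$pos, agg$pos)
    agg[order(agg$contig, agg$pos), c("contig", "pos", "ref", "base",
                                      "count")]
  } else {
    data.frame(contig = character(), pos = integer(), ref = character(),
               base = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  covs <- lapply(names(genome), function(cn) {
    sub <- placements[as.character(GenomicRanges::seqnames(placements)) == cn]
    cov <- GenomicRanges::coverage(GenomicRanges::ranges(sub))
    L <- Biostrings::width(genome[cn])
    if (length(cov) < L) cov <- c(cov, S4Vectors::Rle(0L, L - length(cov)))
    cov[seq_len(L)]
  })
  names(covs) <- names(genome)
  structure(list(coverage = covs, sites = sites,
                 totalMappedBases = sum(GenomicRanges::width(placements))),
            class = "BasePileup")
}

#' @export
print.BasePileup <- function(x, ...) {
  cat("BasePileup:", length(x$coverage), "contigs,",
      nrow(x$sites), "mismatch site records,",
      x$totalMappedBases, "mapped bases\n")
  invisible(x)
}

.pileupDepthAt <- function(pileup, contig, pos) {
  vapply(seq_along(pos), function(i) {
    cov <- pileup$coverage[[contig[i]]]
    if (is.null(cov) || pos[i] > length(cov)) 0
    else as.numeric(cov[pos[i]])
  }, numeric(1))
}

.pileupAltAt <- function(pileup, contig, pos, base) {
  s <- pileup$sites
  key <- paste(s$contig, s$pos, s$base)
  hit <- match(paste(contig, pos, base), key)
  ifelse(is.na(hit), 0L, s$count[hit])
}

#' Call B-specific variant sites from paired pileups
#'
#' A site is reported as B-specific when both samples reach
#' \code{minDepth}, the alternative-allele frequency in the B+ sample is at
#' least \code{minAltBplus}, and in the B- sample at most
#' \code{maxAltBminus}. Polymorphisms present in both samples are thereby
#' excluded as standard A-complement SNPs. Inputs are either
#' \code{"BasePileup"} objects from [alignmentPileup()] or plain site-tally
#' data.frames with columns \code{contig}, \code{pos}, \code{ref},
#' \code{A}, \code{C}, \code{G}, \code{T}.
#'
#' @param pileupBplus,pileupBminus pileups for the B+ and B- samples.
#' @param minDepth minimum depth required in both samples (default 5).
#' @param minAltBplus minimum B+ alternative-allele frequency (default 0.2).
#' @param maxAltBminus maximum B- alternative-allele frequency
#'   (default 0.02).
#' @return data.frame of B-specific sites: \code{contig}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}, \code{depthBplus},
#'   \code{altFreqBplus}, \code{depthBminus}, \code{altFreqBminus}.
#' @export
bSpecificVariants <- function(pileupBplus, pileupBminus, minDepth = 5L,
                              minAltBplus = 0.2, maxAltBminus = 0.02) {
  emptyOut <- data.frame(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), depthBplus = numeric(), altFreqBplus = numeric(),
    depthBminus = numeric(), altFreqBminus = numeric(),
    stringsAsFactors = FALSE)

  if (is.data.frame(pileupBplus)) {
    tp <- pileupBplus; tm <- pileupBminus
    if (!nrow(tp)) return(emptyOut)
    rows <- lapply(seq_len(nrow(tp)), function(i) {
      cnt <- as.numeric(tp[i, BASES])
      depthP <- sum(cnt)
      altBases <- setdiff(BASES, tp$ref[i])
      altCnt <- cnt[match(altBases, BASES)]
      if (all(altCnt == 0)) return(NULL)
      alt <- altBases[which.max(altCnt)]
      j <- which(tm$contig == tp$contig[i] & tm$pos == tp$pos[i])
      depthM <- if (length(j)) sum(as.numeric(tm[j[1], BASES])) else 0
      altM <- if (length(j)) as.numeric(tm[j[1], alt]) else 0
      data.frame(contig = tp$contig[i], pos = tp$pos[i], ref = tp$ref[i],
                 alt = alt, depthBplus = depthP,
                 altFreqBplus = max(altCnt) / depthP,
                 depthBminus = depthM,
                 altFreqBminus = if (depthM > 0) altM / depthM else NA_real_,
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  } else {
    s <- pileupBplus$sites
    if (is.null(s) || !nrow(s)) return(emptyOut)
    s <- s[s$base != s$ref, , drop = FALSE]
    if (!nrow(s)) return(emptyOut)
    # strongest alternative base per site
    s <- s[order(s$contig, s$pos, -s$count), , drop = FALSE]
    s <- s[!duplicated(s[c("contig", "pos")]), , drop = FALSE]
    depthP <- .pileupDepthAt(pileupBplus, s$contig, s$pos)
    depthM <- .pileupDepthAt(pileupBminus, s$contig, s$pos)
    altM <- .pileupAltAt(pileupBminus, s$contig, s$pos, s$base)
    cand <- data.frame(contig = s$contig, pos = s$pos, ref = s$ref,
                       alt = s$base, depthBplus = depthP,
                       altFreqBplus = s$count / pmax(depthP, 1),
                       depthBminus = depthM,
                       altFreqBminus = ifelse(depthM > 0, altM / depthM,
                                              NA_real_),
                       stringsAsFactors = FALSE)
  }
  if (is.null(cand) || !nrow(cand)) return(emptyOut)
  keep <- cand$depthBplus >= minDepth & cand$depthBminus >= minDepth &
    cand$altFreqBplus >= minAltBplus &
    !is.na(cand$altFreqBminus) & cand$altFreqBminus <= maxAltBminus
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a depth track as BedGraph
#' @param track a [DepthTrack].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  r <- S4Vectors::runLength(track@depth)
  v <- S4Vectors::runValue(track@depth)
  ends <- cumsum(r)
  starts0 <- ends - r  # 0-based starts
  utils::write.table(
    data.frame(track@contig, starts0, ends, v),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
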