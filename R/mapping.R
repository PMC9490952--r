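#' Exact-search index over a reference genome
#'
#' @slot genome named [Biostrings::DNAStringSet] of contigs.
#' @seealso [buildGenomeIndex()], [mapTags()]
#' @export
setClass("GenomeIndex", slots = c(genome = "DNAStringSet"))

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex:", length(object@genome), "contigs,",
      sum(Biostrings::width(object@genome)), "bp\n")
})

#' Build a searchable index of a genome
#'
#' @param genome a named [Biostrings::DNAStringSet] (or a [GenomeTruth]).
#' @return a [GenomeIndex] supporting exact substring queries on both
#'   strands via [mapTags()].
#' @export
buildGenomeIndex <- function(genome) {
  if (is(genome, "GenomeTruth")) genome <- genomeSeq(genome)
  if (!length(genome)) stop("genome must be non-empty")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("duplicate or missing contig names")
  new("GenomeIndex", genome = genome)
}

# All exact placements of `seqs` (character) on both strands of the genome.
# Returns data.frame(patternId, contig, start, end, strand).
.exactPlacements <- function(seqs, genome) {
  widths <- nchar(seqs)
  out <- vector("list", 0)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(seqs[idx])
    rev <- Biostrings::reverseComplement(fwd)
    for (strandChar in c("+", "-")) {
      pd <- Biostrings::PDict(if (strandChar == "+") fwd else rev)
      for (cn in names(genome)) {
        if (w > Biostrings::width(genome[cn])) next
        m <- Biostrings::matchPDict(pd, genome[[cn]])
        nh <- S4Vectors::elementNROWS(m)
        if (!sum(nh)) next
        ir <- unlist(m)
        out[[length(out) + 1L]] <- data.frame(
          patternId = idx[rep(seq_along(nh), nh)],
          contig = cn,
          start = IRanges::start(ir), end = IRanges::end(ir),
          strand = strandChar, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(patternId = integer(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Placements of one sequence at exactly `mm` allowed mismatches (both
# strands). Used for the 1-mismatch stratum of tags without exact hits.
.fuzzyPlacements <- function(seq, genome, mm) {
  out <- list()
  for (strandChar in c("+", "-")) {
    pat <- if (strandChar == "+") seq else revCompChar(seq)
    for (cn in names(genome)) {
      if (nchar(seq) > Biostrings::width(genome[cn])) next
      m <- Biostrings::matchPattern(pat, genome[[cn]], max.mismatch = mm)
      if (!length(m)) next
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = IRanges::start(m), end = IRanges::end(m),
        strand = strandChar, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Place sequence tags on the genome with multi-mapper weighting
#'
#' Reports all placements of each tag at its best stratum (fewest
#' mismatches: exact placements if any exist, otherwise 1-mismatch
#' placements when \code{maxMismatch = 1}). Each hit records the tag's
#' total genome-wide placement count \code{nGenomicHits}, and the tag's
#' read count is spread fractionally over its placements
#' (\code{weight = total / nGenomicHits}), so summed weights conserve read
#' counts under multi-mapping. Tags with more than \code{maxHits}
#' placements are dropped as hyper-repetitive.
#'
#' @param tags a [TagSet] (or a named [Biostrings::DNAStringSet], counts 1).
#' @param index a [GenomeIndex] (or a genome to index on the fly).
#' @param maxMismatch 0 (default) or 1.
#' @param maxHits drop tags with more genomic placements than this
#'   (default 100); \code{Inf} disables the cap.
#' @return list with \code{hits}: [GenomicRanges::GRanges] with metadata
#'   columns \code{tagId}, \code{nGenomicHits}, \code{weight};
#'   \code{unmapped}: integer ids of tags with no placement;
#'   \code{dropped}: integer ids removed by the \code{maxHits} cap.
#' @export
mapTags <- function(tags, index, maxMismatch = 0L, maxHits = 100L) {
  if (!maxMismatch %in% c(0L, 1L)) stop("maxMismatch must be 0 or 1")
  if (!is(index, "GenomeIndex")) index <- buildGenomeIndex(index)
  genome <- index@genome
  if (is(tags, "TagSet")) {
    seqs <- SummarizedExperiment::rowData(tags)$sequence
    totals <- unname(tagTotals(tags))
  } else {
    seqs <- as.character(tags)
    totals <- rep(1, length(seqs))
  }
  if (!length(seqs))
    return(list(hits = GenomicRanges::GRanges(), unmapped = integer(),
                dropped = integer()))

  pl <- .exactPlacements(seqs, genome)
  noExact <- setdiff(seq_along(seqs), unique(pl$patternId))
  if (maxMismatch >= 1L && length(noExact)) {
    extra <- lapply(noExact, function(i) {
      f <- .fuzzyPlacements(seqs[i], genome, 1L)
      if (is.null(f)) return(NULL)
      cbind(patternId = i, f)
    })
    extra <- extra[!vapply(extra, is.null, logical(1))]
    if (length(extra)) pl <- rbind(pl, do.call(rbind, extra))
  }

  unmapped <- setdiff(seq_along(seqs), unique(pl$patternId))
  nh <- table(pl$patternId)
  nHitsOf <- stats::setNames(as.integer(nh), names(nh))
  pl$nGenomicHits <- nHitsOf[as.character(pl$patternId)]
  dropped <- as.integer(names(nHitsOf)[nHitsOf > maxHits])
  pl <- pl[!(pl$patternId %in% dropped), , drop = FALSE]
  pl <- pl[order(match(pl$contig, names(genome)), pl$start, pl$strand), ,
           drop = FALSE]
  hits <- GenomicRanges::GRanges(
    pl$contig, IRanges::IRanges(pl$start, pl$end), strand = pl$strand,
    tagId = pl$patternId, nGenomicHits = unname(pl$nGenomicHits),
    weight = totals[pl$patternId] / unname(pl$nGenomicHits))
  list(hits = hits, unmapped = unmapped, dropped = dropped)
}

#' Extract the genomic sequence under each hit
#'
#' Returns, for every hit, the strand-aware genomic sequence (reverse
#' complement on the minus strand), which at zero mismatches reproduces the
#' tag sequence exactly.
#'
#' @param hits a [GenomicRanges::GRanges] of hits.
#' @param genome a named [Biostrings::DNAStringSet].
#' @return character vector of sequences.
#' @export
hitSequences <- function(hits, genome) {
  cn <- as.character(GenomicRanges::seqnames(hits))
  s <- unname(substring(as.character(genome)[cn],
                        GenomicRanges::start(hits),
                        GenomicRanges::end(hits)))
  neg <- as.character(GenomicRanges::strand(hits)) == "-"
  if (any(neg)) s[neg] <- revCompChar(s[neg])
  s
}

# Minimal SAM writer shared by the simulators and the mapper.
writeSamFile <- function(qname, flag, rname, pos, seq, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(paste0("@SQ\tSN:", names(genome),
                    "\tLN:", Biostrings::width(genome)), con)
  if (length(qname)) {
    writeLines(paste(qname, flag, rname, pos, 255L,
                     paste0(nchar(seq), "M"), "*", 0L, 0L, seq,
                     strrep("I", nchar(seq)), sep = "\t"), con)
  }
  invisible(path)
}

#' Export tag hits as SAM
#'
#' Query names follow the \code{tag{serial}-{total}} convention; multi-hit
#' tags produce one record per placement. Minus-strand hits are stored
#' reference-oriented with flag 16.
#'
#' @param hits hit [GenomicRanges::GRanges] from [mapTags()].
#' @param tags the [TagSet] the hits refer to.
#' @param genome the reference [Biostrings::DNAStringSet].
#' @param path output SAM path.
#' @export
writeTagHitsSam <- function(hits, tags, genome, path) {
  tagId <- S4Vectors::mcols(hits)$tagId
  seqs <- SummarizedExperiment::rowData(tags)$sequence[tagId]
  neg <- as.character(GenomicRanges::strand(hits)) == "-"
  if (any(neg)) seqs[neg] <- revCompChar(seqs[neg])
  writeSamFile(
    qname = paste0("tag", tagId, "-", unname(tagTotals(tags))[tagId]),
    flag = ifelse(neg, 16L, 0L),
    rname = as.character(GenomicRanges::seqnames(hits)),
    pos = GenomicRanges::start(hits),
    seq = seqs, genome = genome, path = path)
}

# reference-span width of a simple CIGAR (M/D/N/=/X consume reference)
.cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stop("cannot parse CIGAR '", cg, "'")
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Import external alignments of tags as a hit stream
#'
#' Lets a production aligner stand in for [mapTags()]: reads a SAM or BAM
#' file whose query names resolve to tags (the \code{tag{serial}-{total}}
#' FASTA convention of [writeTagSet()], or literal \code{tag{serial}} row
#' names), sets \code{nGenomicHits} to the number of records per query
#' (primary plus secondary), and assigns fractional weights exactly as
#' [mapTags()] does.
#'
#' @param path SAM or BAM file.
#' @param tags the [TagSet] queried.
#' @return hit [GenomicRanges::GRanges] with \code{tagId},
#'   \code{nGenomicHits}, \code{weight} metadata columns.
#' @export
importAlignments <- function(path, tags) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar")))[[1]]
  keep <- !bitwAnd(b$flag, 4L)  # aligned records only
  qname <- b$qname[keep]; flag <- b$flag[keep]
  rname <- as.character(b$rname)[keep]; pos <- b$pos[keep]
  cigar <- b$cigar[keep]

  serial <- suppressWarnings(as.integer(sub("^tag(\\d+)(-.*)?$", "\\1", qname)))
  bad <- is.na(serial) | serial < 1 | serial > nrow(tags)
  if (any(bad)) {
    warning(sum(bad), " alignment record(s) with unresolvable query names ",
            "were skipped")
    serial <- serial[!bad]; flag <- flag[!bad]; rname <- rname[!bad]
    pos <- pos[!bad]; cigar <- cigar[!bad]
  }
  if (!length(serial)) return(GenomicRanges::GRanges())
  w <- .cigarRefWidth(cigar)
  nh <- table(serial)
  nHitsOf <- stats::setNames(as.integer(nh), names(nh))
  n <- nHitsOf[as.character(serial)]
  totals <- unname(tagTotals(tags))[serial]
  GenomicRanges::GRanges(
    rname, IRanges::IRanges(pos, pos + w - 1L),
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    tagId = serial, nGenomicHits = unname(n),
    weight = totals / unname(n))
}
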