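#' Scan weighted tag hits for candidate piRNA cluster intervals
#'
#' Candidates are maximal runs of hits on one contig in which consecutive
#' hit start positions are at most \code{maxGap} apart. A run is kept when
#' it contains at least \code{minTags} distinct tags and at least
#' \code{minWeight} of summed hit weight. The candidate span runs from the
#' smallest member start to the largest member end.
#'
#' @param hits hit [GenomicRanges::GRanges] from [mapTags()] or
#'   [importAlignments()].
#' @param maxGap maximum distance between consecutive hit starts (bp).
#' @param minTags minimum number of distinct member tags.
#' @param minWeight minimum summed member weight.
#' @return a [GenomicRanges::GRanges] of candidate spans with a
#'   \code{members} metadata column ([IRanges::IntegerList] of indices into
#'   \code{hits}).
#' @export
scanCandidates <- function(hits, maxGap = 500L, minTags = 10L,
                           minWeight = 20) {
  if (!length(hits)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$members <- IRanges::IntegerList()
    return(out)
  }
  ord <- order(as.character(GenomicRanges::seqnames(hits)),
               GenomicRanges::start(hits))
  cn <- as.character(GenomicRanges::seqnames(hits))[ord]
  st <- GenomicRanges::start(hits)[ord]
  newRun <- c(TRUE, cn[-1] != cn[-length(cn)] |
                    diff(st) > maxGap)
  runId <- cumsum(newRun)
  keepRanges <- list(); keepMembers <- list()
  for (r in unique(runId)) {
    idx <- ord[runId == r]
    w <- sum(S4Vectors::mcols(hits)$weight[idx])
    nt <- length(unique(S4Vectors::mcols(hits)$tagId[idx]))
    if (nt >= minTags && w >= minWeight) {
      keepRanges[[length(keepRanges) + 1L]] <- data.frame(
        contig = as.character(GenomicRanges::seqnames(hits))[idx[1]],
        start = min(GenomicRanges::start(hits)[idx]),
        end = max(GenomicRanges::end(hits)[idx]))
      keepMembers[[length(keepMembers) + 1L]] <- idx
    }
  }
  if (!length(keepRanges)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$members <- IRanges::IntegerList()
    return(out)
  }
  df <- do.call(rbind, keepRanges)
  out <- GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(out)$members <- IRanges::IntegerList(keepMembers)
  out
}

# Per-hit feature vectors reused by the filters; computed once per call.
.hitFeatures <- function(hits, tags) {
  tagSeq <- SummarizedExperiment::rowData(tags)$sequence
  tagId <- S4Vectors::mcols(hits)$tagId
  s <- tagSeq[tagId]
  len <- nchar(s)
  list(
    weight = S4Vectors::mcols(hits)$weight,
    u1 = substring(s, 1L, 1L) == "T",
    a10 = len >= 10L & substring(s, 10L, 10L) == "A",
    len = len,
    plus = as.character(GenomicRanges::strand(hits)) == "+",
    tagId = tagId
  )
}

#' Apply the piRNA cluster acceptance filters to a candidate
#'
#' A candidate is accepted when its span is at least \code{minSize} bp, the
#' weighted fraction of member reads whose first base is U (T) or whose
#' tenth base is A reaches \code{minFrac1u10a}, and the weighted fraction
#' of member reads with typical piRNA length (within \code{typicalLen})
#' reaches \code{minFracLen}. Threshold equality passes (the thresholds are
#' minima). Metrics are reported regardless of the outcome.
#'
#' @param candidate a length-1 [GenomicRanges::GRanges] span.
#' @param memberHits the member hit [GenomicRanges::GRanges].
#' @param tags the [TagSet] the hits refer to.
#' @param minSize minimum span (bp), default 1000.
#' @param minFrac1u10a minimum weighted 1U-or-10A fraction, default 0.75.
#' @param minFracLen minimum weighted typical-length fraction, default 0.75.
#' @param typicalLen inclusive typical piRNA length range, default c(24, 35).
#' @return list with \code{accept} (logical) and the metrics \code{size},
#'   \code{frac1u10a}, \code{fracTypicalLen}, \code{nTags},
#'   \code{mainStrandFraction}.
#' @export
clusterFilters <- function(candidate, memberHits, tags, minSize = 1000L,
                           minFrac1u10a = 0.75, minFracLen = 0.75,
                           typicalLen = c(24L, 35L)) {
  if (!length(memberHits)) stop("memberHits must be non-empty")
  f <- .hitFeatures(memberHits, tags)
  W <- sum(f$weight)
  frac1u10a <- sum(f$weight[f$u1 | f$a10]) / W
  fracLen <- sum(f$weight[f$len >= typicalLen[1] &
                          f$len <= typicalLen[2]]) / W
  size <- GenomicRanges::width(candidate)
  plusFrac <- sum(f$weight[f$plus]) / W
  list(
    accept = size >= minSize && frac1u10a >= minFrac1u10a &&
             fracLen >= minFracLen,
    size = size,
    frac1u10a = frac1u10a,
    fracTypicalLen = fracLen,
    nTags = length(unique(f$tagId)),
    mainStrandFraction = max(plusFrac, 1 - plusFrac)
  )
}

#' Classify the transcriptional directionality of a cluster
#'
#' A cluster is monodirectional on its majority strand when the weighted
#' main-strand fraction reaches \code{minMainFrac} (default 0.75), and
#' bidirectional otherwise.
#'
#' @param memberHits member hit [GenomicRanges::GRanges] with \code{weight}.
#' @param minMainFrac weighted main-strand fraction required for a
#'   monodirectional call.
#' @return one of \code{"mono:+"}, \code{"mono:-"}, \code{"bi"}.
#' @export
classifyDirectionality <- function(memberHits, minMainFrac = 0.75) {
  if (!length(memberHits)) stop("memberHits must be non-empty")
  w <- S4Vectors::mcols(memberHits)$weight
  plusFrac <- sum(w[as.character(GenomicRanges::strand(memberHits)) == "+"]) /
    sum(w)
  mainFrac <- max(plusFrac, 1 - plusFrac)
  if (mainFrac < minMainFrac) return("bi")
  if (plusFrac >= 0.5) "mono:+" else "mono:-"
}

#' Call piRNA clusters from a weighted hit stream
#'
#' Composes the candidate scan, the acceptance filters and the
#' directionality classifier, and computes per-library weighted read mass
#' (each tag contributes \code{count / nGenomicHits} per placement). A
#' cluster is flagged expressed in a library when its weighted mass there
#' reaches \code{minExpr}.
#'
#' @inheritParams scanCandidates
#' @inheritParams clusterFilters
#' @param tags the [TagSet] the hits refer to.
#' @param minMainFrac see [classifyDirectionality()].
#' @param minExpr minimum per-library weighted mass for the expressed flag.
#' @return a [GenomicRanges::GRanges] of accepted clusters with metadata
#'   columns \code{id}, \code{size}, \code{directionality},
#'   \code{frac1u10a}, \code{fracTypicalLen}, \code{nTags},
#'   \code{mainStrandFraction}, one \code{weight.<library>} and one
#'   \code{expressed.<library>} column per library.
#' @export
callClusters <- function(hits, tags, maxGap = 500L, minTags = 10L,
                         minWeight = 20, minSize = 1000L,
                         minFrac1u10a = 0.75, minFracLen = 0.75,
                         typicalLen = c(24L, 35L), minMainFrac = 0.75,
                         minExpr = 5) {
  libs <- colnames(tags)
  emptyOut <- function() {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      id = character(), size = integer(), directionality = character(),
      frac1u10a = numeric(), fracTypicalLen = numeric(), nTags = integer(),
      mainStrandFraction = numeric())
    out
  }
  if (!length(hits)) return(emptyOut())
  cands <- scanCandidates(hits, maxGap = maxGap, minTags = minTags,
                          minWeight = minWeight)
  if (!length(cands)) return(emptyOut())

  counts <- tagCounts(tags)
  nHits <- S4Vectors::mcols(hits)$nGenomicHits
  tagId <- S4Vectors::mcols(hits)$tagId

  rows <- list(); ranges <- list()
  for (i in seq_along(cands)) {
    idx <- S4Vectors::mcols(cands)$members[[i]]
    mh <- hits[idx]
    met <- clusterFilters(cands[i], mh, tags, minSize = minSize,
                          minFrac1u10a = minFrac1u10a,
                          minFracLen = minFracLen, typicalLen = typicalLen)
    if (!met$accept) next
    libW <- colSums(counts[tagId[idx], , drop = FALSE] / nHits[idx])
    rows[[length(rows) + 1L]] <- c(
      list(size = met$size,
           directionality = classifyDirectionality(mh, minMainFrac),
           frac1u10a = met$frac1u10a, fracTypicalLen = met$fracTypicalLen,
           nTags = met$nTags, mainStrandFraction = met$mainStrandFraction),
      stats::setNames(as.list(libW), paste0("weight.", libs)),
      stats::setNames(as.list(libW >= minExpr), paste0("expressed.", libs)))
    ranges[[length(ranges) + 1L]] <- cands[i]
  }
  if (!length(rows)) return(emptyOut())
  out <- unlist(GenomicRanges::GRangesList(lapply(ranges, function(g) {
    S4Vectors::mcols(g) <- NULL; g
  })))
  md <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  ord <- order(as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out))
  out <- out[ord]; md <- md[ord, , drop = FALSE]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    id = paste0("cluster-", seq_along(out)), md, check.names = FALSE)
  out
}

#' Merge accepted clusters from parameter re-runs by interval union
#'
#' Overlapping accepted clusters produced by different parameter settings
#' are merged into their union span; when the originating \code{hits} and
#' \code{tags} are supplied, metrics and directionality are recomputed on
#' the member hits of each merged span.
#'
#' @param runs list of cluster [GenomicRanges::GRanges] from [callClusters()].
#' @param hits,tags optionally, the hit stream and [TagSet] used to
#'   recompute metrics for merged spans.
#' @param ... passed to [clusterFilters()] / [classifyDirectionality()]
#'   when recomputing.
#' @return a [GenomicRanges::GRanges] of merged spans.
#' @export
mergeClusterRuns <- function(runs, hits = NULL, tags = NULL, ...) {
  all <- unlist(GenomicRanges::GRangesList(lapply(runs, function(g) {
    S4Vectors::mcols(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  })))
  merged <- GenomicRanges::reduce(all, ignore.strand = TRUE)
  if (!is.null(hits) && !is.null(tags) && length(merged)) {
    md <- lapply(seq_along(merged), function(i) {
      ov <- GenomicRanges::findOverlaps(hits, merged[i], ignore.strand = TRUE)
      mh <- hits[S4Vectors::queryHits(ov)]
      met <- clusterFilters(merged[i], mh, tags, ...)
      data.frame(size = met$size, frac1u10a = met$frac1u10a,
                 fracTypicalLen = met$fracTypicalLen, nTags = met$nTags,
                 directionality = classifyDirectionality(mh),
                 mainStrandFraction = met$mainStrandFraction)
    })
    S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
      id = paste0("cluster-", seq_along(merged)), do.call(rbind, md))
  }
  merged
}

#' Write a cluster table as TSV (1-based inclusive coordinates)
#' @param clusters cluster [GenomicRanges::GRanges] from [callClusters()].
#' @param path output TSV path.
#' @export
writeClusterTsv <- function(clusters, path) {
  df <- data.frame(
    id = S4Vectors::mcols(clusters)$id,
    contig = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters),
    end = GenomicRanges::end(clusters),
    as.data.frame(S4Vectors::mcols(clusters)[, -1, drop = FALSE]),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clusters as BED6 (0-based half-open)
#' @inheritParams writeClusterTsv
#' @export
writeClusterBed <- function(clusters, path) {
  strandOf <- function(d) {
    ifelse(d == "mono:+", "+", ifelse(d == "mono:-", "-", "."))
  }
  if (!length(clusters)) {
    cat("", file = path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    name = S4Vectors::mcols(clusters)$id,
    score = 0L,
    strand = strandOf(S4Vectors::mcols(clusters)$directionality))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write clusters as GFF3
#' @inheritParams writeClusterTsv
#' @export
writeClusterGff3 <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(clusters)) {
    m <- S4Vectors::mcols(clusters)
    st <- ifelse(m$directionality == "mono:+", "+",
                 ifelse(m$directionality == "mono:-", "-", "."))
    writeLines(paste(
      as.character(GenomicRanges::seqnames(clusters)), "curupira",
      "piRNA_cluster", GenomicRanges::start(clusters),
      GenomicRanges::end(clusters), ".", st, ".",
      paste0("ID=", m$id, ";directionality=", m$directionality,
             ";frac_1u10a=", signif(m$frac1u10a, 4)),
      sep = "\t"), con)
  }
  invisible(path)
}
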