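#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAStringSet
NULL

#' Synthetic genome with planted ground truth
#'
#' Container for a simulated reference genome together with the ground-truth
#' features planted into it: piRNA clusters, miRNA loci, transposable-element
#' (TE) copies, per-contig copy-number multipliers describing B-chromosome
#' residency, and B-specific SNPs. Every downstream stage of the pipeline can
#' be scored against this truth.
#'
#' @slot genome [Biostrings::DNAStringSet] named contig sequences (ACGT only).
#' @slot clusters [GenomicRanges::GRanges] planted piRNA clusters with
#'   metadata columns \code{directionality} (\code{"mono:+"}, \code{"mono:-"}
#'   or \code{"bi"}), \code{strandFraction}, \code{u1Prob}, \code{a10Prob}
#'   and \code{bExclusive}.
#' @slot mirnas [GenomicRanges::GRanges] planted miRNA loci.
#' @slot teCopies [GenomicRanges::GRanges] planted TE copies with metadata
#'   columns \code{family}, \code{subclass}, \code{p}, \code{q} (realized
#'   transition/transversion proportions relative to the consensus).
#' @slot copyMultiplier named numeric, one entry per contig; 1 for
#'   A-complement contigs, >= 2 for B-resident contigs.
#' @slot snps data.frame of B-specific SNPs (contig, pos (1-based), ref, alt).
#' @slot seed integer seed that fully determines the genome.
#'
#' @seealso [simulateGenome()]
#' @export
setClass("GenomeTruth",
  slots = c(
    genome         = "DNAStringSet",
    clusters       = "GRanges",
    mirnas         = "GRanges",
    teCopies       = "GRanges",
    copyMultiplier = "numeric",
    snps           = "data.frame",
    seed           = "integer"
  )
)

setValidity("GenomeTruth", function(object) {
  msg <- character()
  g <- object@genome
  if (length(g) && (is.null(names(g)) || anyDuplicated(names(g))))
    msg <- c(msg, "contig names must be present and unique")
  lens <- stats::setNames(Biostrings::width(g), names(g))
  inBounds <- function(gr, what) {
    if (!length(gr)) return(character())
    sq <- as.character(seqnames(gr))
    bad <- !(sq %in% names(lens)) | start(gr) < 1 | end(gr) > lens[sq]
    if (any(bad)) paste0(what, " intervals outside contig bounds") else character()
  }
  msg <- c(msg, inBounds(object@clusters, "cluster"),
           inBounds(object@mirnas, "miRNA"),
           inBounds(object@teCopies, "TE copy"))
  cm <- object@copyMultiplier
  if (!all(names(g) %in% names(cm)))
    msg <- c(msg, "copyMultiplier must cover every contig")
  if (any(cm < 1))
    msg <- c(msg, "copyMultiplier must be >= 1 for every contig")
  if (nrow(object@snps) &&
      !all(c("contig", "pos", "ref", "alt") %in% colnames(object@snps)))
    msg <- c(msg, "snps must have columns contig, pos, ref, alt")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenomeTruth contig sequences
#' @param x,object a \code{GenomeTruth}
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @export
setMethod("genomeSeq", "GenomeTruth", function(x) x@genome)

#' @describeIn GenomeTruth planted piRNA clusters
#' @export
setGeneric("plantedClusters", function(x) standardGeneric("plantedClusters"))
#' @export
setMethod("plantedClusters", "GenomeTruth", function(x) x@clusters)

#' @describeIn GenomeTruth planted miRNA loci
#' @export
setGeneric("plantedMirnas", function(x) standardGeneric("plantedMirnas"))
#' @export
setMethod("plantedMirnas", "GenomeTruth", function(x) x@mirnas)

#' @describeIn GenomeTruth planted TE copies
#' @export
setGeneric("teCopies", function(x) standardGeneric("teCopies"))
#' @export
setMethod("teCopies", "GenomeTruth", function(x) x@teCopies)

#' @describeIn GenomeTruth per-contig copy-number multipliers
#' @export
setGeneric("copyMultiplier", function(x) standardGeneric("copyMultiplier"))
#' @export
setMethod("copyMultiplier", "GenomeTruth", function(x) x@copyMultiplier)

#' @describeIn GenomeTruth B-specific SNP truth table
#' @export
setGeneric("bSnps", function(x) standardGeneric("bSnps"))
#' @export
setMethod("bSnps", "GenomeTruth", function(x) x@snps)

setMethod("show", "GenomeTruth", function(object) {
  cat("GenomeTruth:", length(object@genome), "contigs,",
      sum(Biostrings::width(object@genome)), "bp\n")
  nb <- sum(object@copyMultiplier > 1)
  cat("  planted clusters:", length(object@clusters),
      "| miRNA loci:", length(object@mirnas),
      "| TE copies:", length(object@teCopies), "\n")
  cat("  B-resident contigs:", nb,
      "| B-specific SNPs:", nrow(object@snps),
      "| seed:", object@seed, "\n")
})

#' Collapsed small-RNA sequence tags
#'
#' A \code{TagSet} holds the unique small-RNA sequences (tags) obtained by
#' collapsing a read stream, with one count per sequencing library. It
#' extends [SummarizedExperiment::SummarizedExperiment]: rows are tags
#' (rowData column \code{sequence}), columns are libraries, and the single
#' \code{"counts"} assay stores per-library read counts.
#'
#' @seealso [collapseReads()], [tagSequences()], [tagTotals()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("TagSet", contains = "SummarizedExperiment")

setValidity("TagSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "TagSet requires a 'counts' assay")
  rd <- SummarizedExperiment::rowData(object)
  if (!"sequence" %in% colnames(rd))
    msg <- c(msg, "rowData must carry a 'sequence' column")
  else if (anyDuplicated(rd$sequence))
    msg <- c(msg, "tag sequences must be unique")
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TagSet from sequences and a count matrix
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of unique
#'   tag sequences.
#' @param counts integer matrix, one row per tag, one column per library.
#' @return a \code{TagSet}
#' @export
TagSet <- function(sequences, counts) {
  sequences <- as.character(sequences)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) != length(sequences))
    stop("counts must have one row per sequence")
  rownames(counts) <- paste0("tag", seq_along(sequences))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(sequence = sequences)
  )
  new("TagSet", se)
}

#' @describeIn TagSet tag sequences as a DNAStringSet
#' @param x a \code{TagSet}
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))
#' @export
setMethod("tagSequences", "TagSet", function(x) {
  s <- DNAStringSet(SummarizedExperiment::rowData(x)$sequence)
  names(s) <- rownames(x)
  s
})

#' @describeIn TagSet per-library count matrix
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))
#' @export
setMethod("tagCounts", "TagSet", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @describeIn TagSet total count per tag (sum over libraries)
#' @export
setGeneric("tagTotals", function(x) standardGeneric("tagTotals"))
#' @export
setMethod("tagTotals", "TagSet", function(x)
  rowSums(SummarizedExperiment::assay(x, "counts")))

setMethod("show", "TagSet", function(object) {
  cat("TagSet:", nrow(object), "unique tags over",
      ncol(object), "libraries (", sum(tagTotals(object)), "reads )\n")
  if (ncol(object))
    cat("  libraries:", paste(colnames(object), collapse = ", "), "\n")
})

#' Per-base read depth of one contig
#'
#' @slot contig contig name.
#' @slot depth [S4Vectors::Rle] of per-base read depth (length = contig
#'   length when known).
#' @slot sample sample label, conventionally \code{"B-"} or \code{"B+"}.
#' @slot totalMappedBases library-wide total of aligned bases, used to
#'   normalize depth between libraries of unequal size.
#' @seealso [depthProfile()], [coverageRatio()]
#' @export
setClass("DepthTrack",
  slots = c(contig = "character", depth = "Rle",
            sample = "character", totalMappedBases = "numeric")
)

setValidity("DepthTrack", function(object) {
  msg <- character()
  if (length(object@depth) && min(object@depth) < 0)
    msg <- c(msg, "depth must be non-negative")
  if (object@totalMappedBases < sum(object@depth))
    msg <- c(msg, "totalMappedBases cannot be smaller than the contig's own depth sum")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack [", object@sample, "] ", object@contig, ": ",
      length(object@depth), " bp, mean depth ",
      round(mean(object@depth), 2), "\n", sep = "")
})
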