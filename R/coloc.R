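#' Overlap in bp between two genomic intervals
#'
#' Strand-agnostic overlap \code{max(0, min(aEnd, bEnd) - max(aStart,
#' bStart) + 1)} on 1-based inclusive coordinates; zero across contigs.
#' Vectorized over pairs (shorter argument recycled).
#'
#' @param a,b [GenomicRanges::GRanges] of intervals, compared pairwise.
#' @return integer vector of overlap widths in bp.
#' @examples
#' a <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, 200))
#' b <- GenomicRanges::GRanges("c1", IRanges::IRanges(200, 300))
#' intervalOverlap(a, b)  # 1
#' @export
intervalOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) < n) a <- rep(a, length.out = n)
  if (length(b) < n) b <- rep(b, length.out = n)
  ov <- pmax(0L, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
                 pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
  ov[as.character(GenomicRanges::seqnames(a)) !=
     as.character(GenomicRanges::seqnames(b))] <- 0L
  ov
}

#' Classify contigs by miRNA/piRNA content and superposition
#'
#' Reproduces the genomic small-RNA Venn logic: a contig is counted as
#' \code{"both"} when it carries at least one miRNA locus and at least one
#' piRNA cluster, and as superposed when any miRNA/cluster pair on it
#' overlaps by at least 1 bp (strand-agnostic).
#'
#' @param mirnas miRNA locus [GenomicRanges::GRanges].
#' @param clusters piRNA cluster [GenomicRanges::GRanges].
#' @return list with \code{table} (data.frame: \code{contig},
#'   \code{class} in \{miRNA-only, piRNA-only, both-superposed,
#'   both-not-superposed\}) and \code{venn} (named counts:
#'   \code{mirnaOnly}, \code{clusterOnly}, \code{both},
#'   \code{bothSuperposed}, \code{bothNotSuperposed}, \code{total}).
#' @export
colocTable <- function(mirnas, clusters) {
  mC <- unique(as.character(GenomicRanges::seqnames(mirnas)))
  pC <- unique(as.character(GenomicRanges::seqnames(clusters)))
  contigs <- sort(union(mC, pC))
  if (!length(contigs)) {
    return(list(
      table = data.frame(contig = character(), class = character()),
      venn = c(mirnaOnly = 0L, clusterOnly = 0L, both = 0L,
               bothSuperposed = 0L, bothNotSuperposed = 0L, total = 0L)))
  }
  supContigs <- character(0)
  if (length(mirnas) && length(clusters)) {
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(mirnas, clusters,
                                  ignore.strand = TRUE, minoverlap = 1L))
    supContigs <- unique(as.character(
      GenomicRanges::seqnames(mirnas))[S4Vectors::queryHits(ov)])
  }
  cls <- ifelse(!(contigs %in% pC), "miRNA-only",
         ifelse(!(contigs %in% mC), "piRNA-only",
         ifelse(contigs %in% supContigs, "both-superposed",
                "both-not-superposed")))
  venn <- c(mirnaOnly = sum(cls == "miRNA-only"),
            clusterOnly = sum(cls == "piRNA-only"),
            both = sum(cls %in% c("both-superposed", "both-not-superposed")),
            bothSuperposed = sum(cls == "both-superposed"),
            bothNotSuperposed = sum(cls == "both-not-superposed"),
            total = length(contigs))
  list(table = data.frame(contig = contigs, class = cls,
                          stringsAsFactors = FALSE),
       venn = venn)
}

#' Read miRNA loci from BED6 or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' each converted to the internal 1-based convention at the boundary.
#'
#' @param path annotation file; format inferred from the extension.
#' @return a [GenomicRanges::GRanges] with a \code{name} column when the
#'   source provides one.
#' @export
readMirnaLoci <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    readBed6(path)
  } else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    GenomicRanges::granges(gr, use.mcols = FALSE)
    keep <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr), GenomicRanges::ranges(gr),
      strand = GenomicRanges::strand(gr))
    nm <- S4Vectors::mcols(gr)$ID
    if (!is.null(nm)) S4Vectors::mcols(keep)$name <- nm
    keep
  } else stop("unrecognized annotation format: ", path)
}

#' Curated miRNA/piRNA colocalization annotation for A. latifasciata
#'
#' Loads the packaged table of annotated miRNA loci and gonadal piRNA
#' clusters that share contigs of the *Astatotilapia latifasciata* genome
#' assembly (1-based inclusive coordinates; one row per miRNA locus, with
#' the co-resident cluster repeated where a contig carries several
#' miRNAs). One cluster record prints no transcription strand in the
#' source annotation and is stored as missing.
#'
#' @param path optional override of the packaged TSV.
#' @return list with \code{mirnas} and \code{clusters}
#'   ([GenomicRanges::GRanges], clusters de-duplicated) and \code{pairs}
#'   (the raw per-row data.frame).
#' @export
colocAnnotation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "alat_mirna_pirna_coloc.tsv",
                        package = "curupira", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  mirnas <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$mirna_start, df$mirna_end),
    strand = df$mirna_strand, name = df$mirna_id)
  cl <- df[!duplicated(df[c("contig", "cluster_id")]), , drop = FALSE]
  clusters <- GenomicRanges::GRanges(
    cl$contig, IRanges::IRanges(cl$cluster_start, cl$cluster_end),
    name = as.character(cl$cluster_id),
    transcription = cl$transcription_strand,
    expression = cl$expression)
  list(mirnas = mirnas, clusters = clusters, pairs = df)
}

#' Write a colocalization table as TSV
#' @param coloc result of [colocTable()].
#' @param path output path.
#' @export
writeColocTsv <- function(coloc, path) {
  utils::write.table(coloc$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
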