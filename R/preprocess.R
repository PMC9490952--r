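#' Read small-RNA FASTQ files, one per library
#'
#' @param files named character vector of FASTQ paths; names are library
#'   labels (conventionally \code{"FB-"}, \code{"FB+"}, \code{"MB-"},
#'   \code{"MB+"}). Quality strings are ignored. U is stored as T.
#' @return a [Biostrings::DNAStringSet] with a \code{library} metadata
#'   column.
#' @export
readSmallRnaFastq <- function(files) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    stop("'files' must be named by library")
  parts <- lapply(seq_along(files), function(i) {
    r <- Biostrings::readDNAStringSet(files[i], format = "fastq")
    S4Vectors::mcols(r) <- S4Vectors::DataFrame(
      library = rep(names(files)[i], length(r)))
    r
  })
  out <- do.call(c, parts)
  out
}

#' Filter small-RNA reads by length
#'
#' Keeps reads whose length lies in \code{[minLen, maxLen]}, the mature
#' piRNA size range (defaults 24-35 nt). Order is preserved and the
#' operation is idempotent.
#'
#' @param reads a [Biostrings::DNAStringSet] (metadata columns preserved).
#' @param minLen,maxLen inclusive length bounds in nt.
#' @return the filtered [Biostrings::DNAStringSet].
#' @examples
#' r <- Biostrings::DNAStringSet(c(strrep("A", 23), strrep("A", 24)))
#' length(lengthFilter(r))  # 1
#' @export
lengthFilter <- function(reads, minLen = 24L, maxLen = 35L) {
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  reads[Biostrings::width(reads) >= minLen &
        Biostrings::width(reads) <= maxLen]
}

#' Collapse reads to unique sequence tags with per-library counts
#'
#' One tag is produced per distinct sequence; its count vector records how
#' many reads carried that sequence in each library, and the grand total of
#' counts equals the number of input reads (after discarding reads that
#' contain N, whose tag identity would be ambiguous). Tags are ordered by
#' decreasing total count, ties broken by sequence.
#'
#' @param reads a [Biostrings::DNAStringSet] with a \code{library} metadata
#'   column (or supply \code{libraries}).
#' @param libraries optional character vector of per-read library labels.
#' @return a [TagSet].
#' @export
collapseReads <- function(reads, libraries = NULL) {
  if (is.null(libraries)) libraries <- S4Vectors::mcols(reads)$library
  if (is.null(libraries)) libraries <- rep("all", length(reads))
  s <- as.character(reads)
  keep <- !grepl("N", s, fixed = TRUE)
  s <- s[keep]; libraries <- as.character(libraries)[keep]
  if (!length(s)) {
    return(TagSet(character(0),
                  matrix(integer(0), 0, length(unique(libraries)),
                         dimnames = list(NULL, unique(libraries)))))
  }
  tab <- table(sequence = s, library = libraries)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(NULL, colnames(tab)))
  seqs <- rownames(tab)
  ord <- order(-rowSums(counts), seqs)
  TagSet(seqs[ord], counts[ord, , drop = FALSE])
}

#' Per-library read-length histogram
#'
#' @param reads a [Biostrings::DNAStringSet] with a \code{library} metadata
#'   column (or supply \code{libraries}).
#' @param libraries optional character vector of per-read library labels.
#' @return data.frame with columns \code{library}, \code{length},
#'   \code{count}; per-library counts sum to per-library read totals.
#' @export
lengthHistogram <- function(reads, libraries = NULL) {
  if (is.null(libraries)) libraries <- S4Vectors::mcols(reads)$library
  if (is.null(libraries)) libraries <- rep("all", length(reads))
  if (!length(reads))
    return(data.frame(library = character(), length = integer(),
                      count = integer()))
  df <- as.data.frame(table(library = as.character(libraries),
                            length = Biostrings::width(reads)),
                      stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  out <- data.frame(library = df$library,
                    length = as.integer(df$length),
                    count = as.integer(df$Freq))
  out[order(out$library, out$length), , drop = FALSE]
}

#' Write a TagSet as FASTA plus a per-library count sidecar
#'
#' FASTA headers follow the \code{>tag{serial}-{total}} convention so that
#' external aligners' query names remain resolvable to tags (see
#' [importAlignments()]).
#'
#' @param tags a [TagSet].
#' @param fastaPath output FASTA path.
#' @param tsvPath output TSV path (tag, sequence, one column per library).
#' @return invisibly, the two paths.
#' @export
writeTagSet <- function(tags, fastaPath, tsvPath) {
  seqs <- tagSequences(tags)
  names(seqs) <- paste0("tag", seq_along(seqs), "-", tagTotals(tags))
  Biostrings::writeXStringSet(seqs, fastaPath)
  df <- data.frame(tag = rownames(tags),
                   sequence = SummarizedExperiment::rowData(tags)$sequence,
                   tagCounts(tags), check.names = FALSE)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fastaPath, tsv = tsvPath))
}

#' Read a TagSet back from its TSV sidecar
#' @param tsvPath path written by [writeTagSet()].
#' @return a [TagSet].
#' @export
readTagSet <- function(tsvPath) {
  df <- utils::read.table(tsvPath, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  libs <- setdiff(colnames(df), c("tag", "sequence"))
  TagSet(df$sequence, as.matrix(df[, libs, drop = FALSE]))
}
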