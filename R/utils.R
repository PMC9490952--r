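# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
SRNA_GROUPS <- c("FB-", "FB+", "MB-", "MB+")

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All simulator operations route their
# randomness through this so seeds are explicit arguments, never global state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result in the positive 32-bit integer range.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483562L) + 1L
}

revCompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# BED6 writer/reader; BED is 0-based half-open, internal GRanges 1-based.
writeBed6 <- function(gr, path, name = NULL, score = 0L) {
  if (!length(gr)) {
    cat("", file = path)
    return(invisible(path))
  }
  if (is.null(name)) {
    name <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
            else paste0("feature", seq_along(gr))
  }
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    name  = name,
    score = score,
    strand = st,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

readBed6 <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6) ifelse(df[[6]] == ".", "*", df[[6]]) else "*"
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                               strand = strand)
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  gr
}

writeFastqFile <- function(reads, path) {
  stopifnot(is(reads, "DNAStringSet"))
  if (length(reads)) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
  } else {
    cat("", file = path)  # valid empty FASTQ
  }
  invisible(path)
}
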