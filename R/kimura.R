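#' Parse a RepeatMasker .out annotation file
#'
#' Reads the classic whitespace-separated RepeatMasker \code{.out} dialect
#' (two header lines plus a blank line, then one row per repeat match) and
#' returns the matches in the internal convention: [GenomicRanges::GRanges]
#' (1-based inclusive), with \code{"C"} orientation mapped to the minus
#' strand and the class/family string reduced to one of the major TE
#' classes \code{DNA}, \code{LINE}, \code{SINE}, \code{LTR} or
#' \code{Other}.
#'
#' @param path path to a RepeatMasker \code{.out} file.
#' @return a [GenomicRanges::GRanges] with metadata columns \code{score},
#'   \code{divergencePct}, \code{repeatName}, \code{classFamily},
#'   \code{teClass}.
#' @export
parseRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  isData <- function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    length(tok) > 0 && grepl("^\\d+$", tok[1])
  }
  first <- which(vapply(lines, isData, logical(1)))[1]
  if (is.na(first)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      score = integer(), divergencePct = numeric(),
      repeatName = character(), classFamily = character(),
      teClass = character())
    return(gr)
  }
  rows <- lines[first:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  toks <- strsplit(trimws(rows), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 14 | nt > 16)
  if (length(bad))
    stop("malformed RepeatMasker row at line ", first + bad[1] - 1L,
         ": expected 14-16 columns, found ", nt[bad[1]])
  get <- function(i) vapply(toks, `[[`, character(1), i)
  strandRaw <- get(9)
  if (!all(strandRaw %in% c("+", "C")))
    stop("unexpected orientation column value: ",
         strandRaw[!strandRaw %in% c("+", "C")][1])
  classFamily <- get(11)
  teClass <- sub("/.*$", "", classFamily)
  teClass[!teClass %in% c("DNA", "LINE", "SINE", "LTR")] <- "Other"
  GenomicRanges::GRanges(
    get(5),
    IRanges::IRanges(as.integer(get(6)), as.integer(get(7))),
    strand = ifelse(strandRaw == "C", "-", "+"),
    score = as.integer(get(1)),
    divergencePct = as.numeric(get(2)),
    repeatName = get(10),
    classFamily = classFamily,
    teClass = teClass)
}

#' Classify piRNA mass by transposable-element class
#'
#' Assigns each hit to the overlapping TE annotation with the largest
#' overlap (ties broken by leftmost annotation), then sums weighted piRNA
#' mass (tag count / genomic hits, per library) within each major TE
#' class. Hits overlapping no annotation count as \code{"non-TE"}.
#'
#' @param hits hit [GenomicRanges::GRanges] from [mapTags()].
#' @param annotations TE annotation [GenomicRanges::GRanges] from
#'   [parseRepeatMaskerOut()] (needs a \code{teClass} metadata column).
#' @param tags the [TagSet] the hits refer to.
#' @return data.frame with columns \code{library}, \code{teClass},
#'   \code{mass}, \code{pct} (percent of the library's total piRNA mass).
#' @export
classifyPirnaTe <- function(hits, annotations, tags) {
  libs <- colnames(tags)
  counts <- tagCounts(tags)
  tagId <- S4Vectors::mcols(hits)$tagId
  nH <- S4Vectors::mcols(hits)$nGenomicHits
  libW <- counts[tagId, , drop = FALSE] / nH

  assigned <- rep("non-TE", length(hits))
  if (length(annotations) && length(hits)) {
    ov <- GenomicRanges::findOverlaps(hits, annotations,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(hits)[q],
        GenomicRanges::ranges(annotations)[s]))
      # largest overlap wins; ties -> leftmost (then first) annotation
      ord <- order(q, -w, GenomicRanges::start(annotations)[s], s)
      q <- q[ord]; s <- s[ord]
      best <- !duplicated(q)
      assigned[q[best]] <- S4Vectors::mcols(annotations)$teClass[s[best]]
    }
  }
  out <- do.call(rbind, lapply(libs, function(lb) {
    tot <- sum(libW[, lb])
    m <- tapply(libW[, lb], assigned, sum)
    data.frame(library = lb, teClass = names(m), mass = as.numeric(m),
               pct = if (tot > 0) 100 * as.numeric(m) / tot else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Kimura two-parameter distance
#'
#' Closed form \deqn{K = -\tfrac12 \ln\big((1 - 2p - q)\sqrt{1 - 2q}\big)}
#' for transition proportion \code{p} and transversion proportion \code{q}.
#' Valid only where \code{1 - 2p - q > 0} and \code{1 - 2q > 0}; beyond
#' that the divergence saturates and the distance is undefined.
#'
#' @param p transition proportion(s).
#' @param q transversion proportion(s).
#' @return substitutions per site, \code{K >= 0}.
#' @examples
#' kimura2p(0.10, 0.05)  # 0.1702
#' @export
kimura2p <- function(p, q) {
  if (any(p < 0) || any(q < 0)) stop("p and q must be non-negative")
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  if (any(a <= 0) || any(b <= 0))
    stop("divergence beyond model domain (need 1 - 2p - q > 0 and 1 - 2q > 0)")
  -0.5 * log(a * sqrt(b))
}

#' Kimura divergence of a TE copy against its consensus
#'
#' Counts transitions and transversions over an aligned copy/consensus
#' pair. Gap columns (\code{-} in either sequence) are stripped pairwise
#' first; only positions where both bases are in ACGT are used. With
#' \code{excludeCpG}, positions falling in consensus CpG dinucleotides are
#' skipped, a site mask approximating the conventional CpG correction of
#' repeat-landscape pipelines.
#'
#' @param copy,consensus aligned sequences (character or
#'   [Biostrings::DNAString]) of equal length.
#' @param excludeCpG skip consensus CpG dinucleotide positions.
#' @return list of class \code{"KimuraEstimate"}: \code{p}, \code{q},
#'   \code{K} (\code{NA} with \code{saturated = TRUE} when the divergence
#'   exceeds the model domain), \code{nSites}, \code{cpgExcluded}.
#' @examples
#' alignmentDivergence("GAAAAAAAAT", "AAAAAAAAAA")  # p = q = 0.1
#' @export
alignmentDivergence <- function(copy, consensus, excludeCpG = FALSE) {
  a <- strsplit(toupper(as.character(copy)), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(as.character(consensus)), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("copy and consensus must be aligned to equal length")
  gap <- a == "-" | b == "-"
  a <- a[!gap]; b <- b[!gap]
  use <- a %in% BASES & b %in% BASES
  if (excludeCpG && length(b) >= 2) {
    cpg <- logical(length(b))
    isCG <- which(b[-length(b)] == "C" & b[-1] == "G")
    cpg[isCG] <- TRUE; cpg[isCG + 1L] <- TRUE
    use <- use & !cpg
  }
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0) stop("zero usable aligned sites")
  mism <- a != b
  ts <- sum(mism & isTransition(a, b))
  tv <- sum(mism) - ts
  p <- ts / n; q <- tv / n
  # beyond the model domain the distance saturates and is undefined
  K <- if (1 - 2 * p - q > 0 && 1 - 2 * q > 0) kimura2p(p, q) else NA_real_
  structure(list(p = p, q = q, K = K, saturated = is.na(K), nSites = n,
                 cpgExcluded = excludeCpG),
            class = "KimuraEstimate")
}

#' @export
print.KimuraEstimate <- function(x, ...) {
  cat(sprintf(
    "KimuraEstimate: p = %.4f, q = %.4f, K = %s (%d sites%s)\n",
    x$p, x$q,
    if (x$saturated) "saturated" else sprintf("%.4f", x$K), x$nSites,
    if (x$cpgExcluded) ", CpG excluded" else ""))
  invisible(x)
}

#' Repeat landscape: aligned bp binned by Kimura divergence
#'
#' Each TE copy contributes its aligned length to the divergence bin
#' \code{floor(100 K / binWidth) * binWidth}, clamped at \code{maxBin}, so
#' the total binned mass equals the total aligned bp exactly.
#'
#' @param estimates data.frame with columns \code{family}, \code{K}
#'   (substitutions/site) and \code{alignedBp}.
#' @param binWidth bin width in percent divergence (default 1).
#' @param maxBin clamp bins at this percent divergence (default 50).
#' @return data.frame with columns \code{family}, \code{bin} (lower edge,
#'   percent), \code{bp}.
#' @export
teLandscape <- function(estimates, binWidth = 1, maxBin = 50) {
  if (is.null(estimates) || !nrow(estimates))
    return(data.frame(family = character(), bin = numeric(),
                      bp = numeric()))
  stopifnot(all(c("family", "K", "alignedBp") %in% colnames(estimates)))
  bin <- pmin(floor(100 * estimates$K / binWidth) * binWidth, maxBin)
  agg <- stats::aggregate(
    list(bp = estimates$alignedBp),
    by = list(family = estimates$family, bin = bin), FUN = sum)
  agg[order(agg$family, agg$bin), , drop = FALSE]
}

#' Compare B- and B+ repeat landscapes
#'
#' Normalizes each landscape by its assembly size (total bp), joins the
#' two per family and bin, and flags bins where the B+ assembly carries
#' disproportionate mass: normalized B+ mass exceeding \code{fold} times
#' the B- mass while reaching \code{minMass}. Such low-divergence excess
#' marks TE families amplified on the B chromosome.
#'
#' @param bMinus,bPlus landscape data.frames from [teLandscape()] built
#'   with the same binning.
#' @param totalBpBminus,totalBpBplus assembly sizes used for
#'   normalization; default: the landscape's own total.
#' @param fold flag bins with normalized B+ mass > \code{fold} times B-
#'   (default 1.5).
#' @param minMass minimum normalized B+ mass for a flag (default 1e-4).
#' @return data.frame with columns \code{family}, \code{bin},
#'   \code{normBminus}, \code{normBplus}, \code{diff} (B+ minus B-),
#'   \code{flagged}.
#' @export
compareLandscapes <- function(bMinus, bPlus, totalBpBminus = NULL,
                              totalBpBplus = NULL, fold = 1.5,
                              minMass = 1e-4) {
  bw <- function(x) if (nrow(x) >= 2) min(diff(sort(unique(x$bin)))) else NA
  w1 <- bw(bMinus); w2 <- bw(bPlus)
  if (!is.na(w1) && !is.na(w2) && w1 != w2)
    stop("landscapes use different binnings")
  if (is.null(totalBpBminus)) totalBpBminus <- sum(bMinus$bp)
  if (is.null(totalBpBplus)) totalBpBplus <- sum(bPlus$bp)
  keys <- unique(rbind(bMinus[c("family", "bin")],
                       bPlus[c("family", "bin")]))
  if (!nrow(keys))
    return(data.frame(family = character(), bin = numeric(),
                      normBminus = numeric(), normBplus = numeric(),
                      diff = numeric(), flagged = logical()))
  lookup <- function(ls, tot) {
    i <- match(paste(keys$family, keys$bin), paste(ls$family, ls$bin))
    ifelse(is.na(i), 0, ls$bp[i]) / max(tot, 1)
  }
  nm <- lookup(bMinus, totalBpBminus)
  np <- lookup(bPlus, totalBpBplus)
  out <- data.frame(family = keys$family, bin = keys$bin,
                    normBminus = nm, normBplus = np, diff = np - nm,
                    flagged = np > fold * nm & np >= minMass,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kimura landscape of the planted TE copies of a synthetic genome
#'
#' Convenience wrapper: computes copy-versus-consensus divergence for every
#' planted TE copy (via [alignmentDivergence()] on the realized sequences)
#' and bins the result. For the B+ assembly each copy's aligned bp is
#' multiplied by its contig's copy-number multiplier, reflecting the extra
#' B-resident copies present in that assembly.
#'
#' @param truth a [GenomeTruth] with planted TE copies.
#' @param teLibrary the consensus [Biostrings::DNAStringSet] used when
#'   planting.
#' @param assembly \code{"B-"} (each copy once) or \code{"B+"} (copies on
#'   multiplier-m contigs counted m times).
#' @param binWidth,maxBin see [teLandscape()].
#' @return a landscape data.frame.
#' @export
truthLandscape <- function(truth, teLibrary, assembly = c("B-", "B+"),
                           binWidth = 1, maxBin = 50) {
  assembly <- match.arg(assembly)
  te <- teCopies(truth)
  if (!length(te))
    return(data.frame(family = character(), bin = numeric(),
                      bp = numeric()))
  genome <- genomeSeq(truth)
  copySeq <- hitSequences(te, genome)
  fam <- S4Vectors::mcols(te)$family
  est <- do.call(rbind, lapply(seq_along(te), function(i) {
    kd <- alignmentDivergence(copySeq[i], as.character(teLibrary[[fam[i]]]))
    data.frame(family = fam[i], K = kd$K, alignedBp = kd$nSites)
  }))
  if (assembly == "B+") {
    m <- copyMultiplier(truth)[as.character(GenomicRanges::seqnames(te))]
    est$alignedBp <- est$alignedBp * unname(m)
  }
  teLandscape(est, binWidth = binWidth, maxBin = maxBin)
}
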