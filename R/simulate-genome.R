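#' Simulate a reference genome with planted ground-truth features
#'
#' Generates a random ACGT genome and plants piRNA clusters, miRNA loci and
#' transposable-element copies at known coordinates, records per-contig
#' copy-number multipliers describing B-chromosome residency, and places
#' B-specific SNPs on B-resident contigs. The same seed always reproduces
#' the genome byte for byte.
#'
#' Planted clusters are genomic intervals from which the small-RNA simulator
#' later draws piRNA reads; the cluster sequence itself is ordinary random
#' genome, because the 5'U bias is realized at read-placement time (see
#' [simulateSrnaLibrary()]). A cluster on a contig with multiplier > 1 is
#' marked B-exclusive by default: B- libraries will not express it.
#'
#' @param nContigs number of contigs.
#' @param contigLength length of each contig in bp (scalar or vector).
#' @param clusterSpec \code{NULL} or a data.frame with columns \code{contig},
#'   \code{start}, \code{end} (1-based inclusive) and optionally
#'   \code{directionality} (\code{"mono:+"}, \code{"mono:-"}, \code{"bi"};
#'   default \code{"mono:+"}), \code{strandFraction} (default 0.95 for mono,
#'   0.5 for bi), \code{u1Prob} (default 0.9), \code{a10Prob} (default 0.3),
#'   \code{bExclusive} (default: contig has multiplier > 1).
#' @param mirnaSpec \code{NULL} or a data.frame with columns \code{contig},
#'   \code{start}, \code{end}, and optionally \code{strand}.
#' @param teLibrary \code{NULL} or a named [Biostrings::DNAStringSet] of TE
#'   consensus sequences; required when \code{teSpec} is given.
#' @param teSpec \code{NULL} or a data.frame with columns \code{contig},
#'   \code{start}, \code{family} (name into \code{teLibrary}), and optionally
#'   \code{subclass}, \code{pTarget}, \code{qTarget} (defaults 0.05, 0.025):
#'   each row overwrites the genome at \code{start} with the consensus
#'   mutated away at the target transition/transversion proportions.
#' @param bContigs named numeric vector of copy-number multipliers (>= 2)
#'   for B-resident contigs; all other contigs get multiplier 1.
#' @param nSnpsPerBContig number of B-specific SNPs placed uniformly on each
#'   B-resident contig.
#' @param seed integer seed (required).
#' @return a [GenomeTruth] object.
#' @examples
#' truth <- simulateGenome(2, 10000, seed = 1)
#' genomeSeq(truth)
#' @export
simulateGenome <- function(nContigs, contigLength, clusterSpec = NULL,
                           mirnaSpec = NULL, teLibrary = NULL, teSpec = NULL,
                           bContigs = NULL, nSnpsPerBContig = 0L, seed) {
  stopifnot(nContigs >= 1, all(contigLength >= 1))
  lens <- rep_len(as.integer(contigLength), nContigs)
  contigNames <- paste0("contig", seq_len(nContigs))
  names(lens) <- contigNames

  multiplier <- stats::setNames(rep(1, nContigs), contigNames)
  if (!is.null(bContigs)) {
    if (is.null(names(bContigs)) || !all(names(bContigs) %in% contigNames))
      stop("bContigs must be named by contig")
    if (any(bContigs < 1)) stop("copy multipliers must be >= 1")
    multiplier[names(bContigs)] <- bContigs
  }

  checkSpec <- function(spec, what) {
    if (is.null(spec) || !nrow(spec)) return(NULL)
    stopifnot(all(c("contig", "start", "end") %in% colnames(spec)))
    if (!all(spec$contig %in% contigNames))
      stop(what, " refers to unknown contigs")
    bad <- spec$start < 1 | spec$end > lens[spec$contig] | spec$start > spec$end
    if (any(bad))
      stop(what, " interval out of contig bounds: row ", which(bad)[1])
    spec
  }
  clusterSpec <- checkSpec(clusterSpec, "clusterSpec")
  mirnaSpec <- checkSpec(mirnaSpec, "mirnaSpec")

  clusters <- GenomicRanges::GRanges()
  if (!is.null(clusterSpec)) {
    n <- nrow(clusterSpec)
    dirn <- if ("directionality" %in% colnames(clusterSpec))
      clusterSpec$directionality else rep("mono:+", n)
    if (!all(dirn %in% c("mono:+", "mono:-", "bi")))
      stop("directionality must be one of mono:+, mono:-, bi")
    sf <- if ("strandFraction" %in% colnames(clusterSpec))
      clusterSpec$strandFraction else ifelse(dirn == "bi", 0.5, 0.95)
    clusters <- GenomicRanges::GRanges(
      clusterSpec$contig,
      IRanges::IRanges(clusterSpec$start, clusterSpec$end),
      directionality = dirn,
      strandFraction = sf,
      u1Prob = if ("u1Prob" %in% colnames(clusterSpec))
        clusterSpec$u1Prob else rep(0.9, n),
      a10Prob = if ("a10Prob" %in% colnames(clusterSpec))
        clusterSpec$a10Prob else rep(0.3, n),
      bExclusive = if ("bExclusive" %in% colnames(clusterSpec))
        clusterSpec$bExclusive else multiplier[clusterSpec$contig] > 1,
      name = paste0("pi-cluster-", seq_len(n))
    )
    # overlapping planted clusters on the same strand are a planting error
    byStrand <- split(seq_along(clusters),
                      S4Vectors::mcols(clusters)$directionality != "mono:-")
    for (idx in byStrand) {
      if (length(idx) > 1) {
        hits <- GenomicRanges::findOverlaps(clusters[idx],
                                            drop.self = TRUE,
                                            ignore.strand = TRUE)
        if (length(hits) > 0)
          stop("planted clusters overlap on the same strand")
      }
    }
  }

  mirnas <- GenomicRanges::GRanges()
  if (!is.null(mirnaSpec)) {
    mirnas <- GenomicRanges::GRanges(
      mirnaSpec$contig,
      IRanges::IRanges(mirnaSpec$start, mirnaSpec$end),
      strand = if ("strand" %in% colnames(mirnaSpec)) mirnaSpec$strand else "+",
      name = paste0("mirna-", seq_len(nrow(mirnaSpec)))
    )
  }

  withSeed(seed, {
    seqs <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1))

    # plant TE copies (mutated consensus overwrites the random background)
    teGr <- GenomicRanges::GRanges()
    if (!is.null(teSpec) && nrow(teSpec)) {
      if (is.null(teLibrary) || !length(teLibrary))
        stop("teLibrary must be non-empty when planting TE copies")
      stopifnot(all(c("contig", "start", "family") %in% colnames(teSpec)))
      if (!all(teSpec$family %in% names(teLibrary)))
        stop("teSpec families missing from teLibrary")
      pT <- if ("pTarget" %in% colnames(teSpec)) teSpec$pTarget
            else rep(0.05, nrow(teSpec))
      qT <- if ("qTarget" %in% colnames(teSpec)) teSpec$qTarget
            else rep(0.025, nrow(teSpec))
      rows <- vector("list", nrow(teSpec))
      for (i in seq_len(nrow(teSpec))) {
        cons <- as.character(teLibrary[[teSpec$family[i]]])
        L <- nchar(cons)
        s <- teSpec$start[i]; e <- s + L - 1L
        if (s < 1 || e > lens[teSpec$contig[i]])
          stop("teSpec interval out of contig bounds: row ", i)
        mut <- mutateTeCopy(cons, pT[i], qT[i],
                            seed = childSeed(seed, paste0("te", i)))
        substr(seqs[teSpec$contig[i]], s, e) <- mut$sequence
        rows[[i]] <- data.frame(
          contig = teSpec$contig[i], start = s, end = e,
          family = teSpec$family[i],
          subclass = if ("subclass" %in% colnames(teSpec))
            teSpec$subclass[i] else teSpec$family[i],
          p = mut$p, q = mut$q, stringsAsFactors = FALSE)
      }
      tedf <- do.call(rbind, rows)
      teGr <- GenomicRanges::GRanges(
        tedf$contig, IRanges::IRanges(tedf$start, tedf$end),
        family = tedf$family, subclass = tedf$subclass,
        p = tedf$p, q = tedf$q,
        name = paste0("te-copy-", seq_len(nrow(tedf))))
    }

    # B-specific SNPs: uniform positions on B-resident contigs, alt != ref
    snps <- data.frame(contig = character(), pos = integer(),
                       ref = character(), alt = character(),
                       stringsAsFactors = FALSE)
    bNames <- names(multiplier)[multiplier > 1]
    if (nSnpsPerBContig > 0 && length(bNames)) {
      rows <- lapply(bNames, function(cn) {
        pos <- sort(sample.int(lens[cn], nSnpsPerBContig))
        ref <- substring(seqs[cn], pos, pos)
        alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
        data.frame(contig = cn, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
      })
      snps <- do.call(rbind, rows)
      rownames(snps) <- NULL
    }

    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- contigNames
    new("GenomeTruth", genome = genome, clusters = clusters,
        mirnas = mirnas, teCopies = teGr, copyMultiplier = multiplier,
        snps = snps, seed = as.integer(seed))
  })
}

#' Mutate a TE consensus at controlled transition/transversion proportions
#'
#' Introduces exactly \code{round(pTarget * L)} transitions and
#' \code{round(qTarget * L)} transversions at distinct sites of a consensus
#' sequence (no site is hit twice, so realized proportions are the exact
#' counted mismatch proportions). Used to plant TE copies whose Kimura
#' divergence is known by construction.
#'
#' @param consensus character or [Biostrings::DNAString] consensus sequence,
#'   length >= 50, ACGT only.
#' @param pTarget,qTarget target transition / transversion proportions;
#'   \code{pTarget + qTarget} must be < 0.75.
#' @param seed integer seed.
#' @return list with \code{sequence} (character, same length as input),
#'   \code{p}, \code{q} (realized proportions).
#' @examples
#' mutateTeCopy(strrep("ACGT", 25), 0.10, 0.05, seed = 3)[c("p", "q")]
#' @export
mutateTeCopy <- function(consensus, pTarget, qTarget, seed) {
  consensus <- as.character(consensus)
  L <- nchar(consensus)
  if (L < 50) stop("consensus length must be >= 50")
  if (pTarget < 0 || qTarget < 0 || pTarget + qTarget >= 0.75)
    stop("mutation rates out of range: need p >= 0, q >= 0, p + q < 0.75")
  nP <- round(pTarget * L)
  nQ <- round(qTarget * L)
  ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (!all(ch %in% BASES)) stop("consensus must be over ACGT")
  withSeed(seed, {
    sites <- if (nP + nQ > 0) sample.int(L, nP + nQ) else integer()
    tsSites <- sites[seq_len(nP)]
    tvSites <- sites[nP + seq_len(nQ)]
    transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
    ch[tsSites] <- transitionOf[ch[tsSites]]
    tvOf <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
    if (length(tvSites))
      ch[tvSites] <- vapply(ch[tvSites],
                            function(b) sample(tvOf[[b]], 1),
                            character(1), USE.NAMES = FALSE)
    list(sequence = paste(ch, collapse = ""), p = nP / L, q = nQ / L)
  })
}

#' Write a GenomeTruth bundle to disk
#'
#' Writes the genome FASTA plus plain-text truth files: BED6 for clusters,
#' miRNA loci and TE copies (0-based half-open), and TSVs for copy-number
#' multipliers and B-specific SNPs.
#'
#' @param truth a [GenomeTruth].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
exportTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    clusters = file.path(dir, "clusters_truth.bed"),
    mirnas = file.path(dir, "mirnas_truth.bed"),
    te = file.path(dir, "te_copies_truth.bed"),
    multipliers = file.path(dir, "copy_multipliers.tsv"),
    snps = file.path(dir, "b_specific_snps.tsv")
  )
  Biostrings::writeXStringSet(genomeSeq(truth), paths["genome"])
  writeBed6(plantedClusters(truth), paths["clusters"])
  writeBed6(plantedMirnas(truth), paths["mirnas"])
  writeBed6(teCopies(truth), paths["te"])
  utils::write.table(
    data.frame(contig = names(copyMultiplier(truth)),
               multiplier = unname(copyMultiplier(truth))),
    paths["multipliers"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bSnps(truth), paths["snps"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a truth BED6 file back as a GRanges
#'
#' Inverse of the BED6 truth writer used by [exportTruth()]; converts the
#' 0-based half-open records back to the internal 1-based convention.
#'
#' @param path BED6 file path.
#' @return a [GenomicRanges::GRanges].
#' @export
readTruthBed <- function(path) readBed6(path)
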