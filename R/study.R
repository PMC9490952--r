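#' Construct the standard synthetic study genome
#'
#' Builds the package's reference study condition: a 10-contig genome
#' (50 kb contigs) with five planted piRNA clusters — two of them on
#' B-resident contigs with copy-number multiplier 3 (and therefore
#' B-exclusive in expression), three monodirectional and two
#' bidirectional — together with miRNA loci (two of them inside clusters)
#' and B-specific SNPs on the B-resident contigs. All coordinates are
#' fixed; only the sequence content depends on the seed.
#'
#' @param seed integer seed.
#' @param nContigs,contigLength genome dimensions.
#' @param bMultiplier copy-number multiplier of the two B-resident contigs.
#' @param snpsPerBContig B-specific SNPs per B-resident contig.
#' @param u1Prob,a10Prob planted base-bias probabilities.
#' @return a [GenomeTruth].
#' @export
studyTruth <- function(seed, nContigs = 10L, contigLength = 50000L,
                       bMultiplier = 3, snpsPerBContig = 5L,
                       u1Prob = 0.9, a10Prob = 0.3) {
  stopifnot(nContigs >= 7, contigLength >= 20000)
  sizes <- c(1500L, 8000L, 2500L, 4500L, 6000L)
  dirn <- c("mono:+", "bi", "mono:-", "mono:+", "bi")
  clusterSpec <- data.frame(
    contig = paste0("contig", 1:5),
    start = 10001L,
    end = 10000L + sizes,
    directionality = dirn,
    strandFraction = ifelse(dirn == "bi", 0.5, 0.95),
    u1Prob = u1Prob, a10Prob = a10Prob,
    stringsAsFactors = FALSE)
  mirnaSpec <- data.frame(
    contig = c("contig6", "contig6", "contig7", "contig7",
               "contig8", "contig9", "contig3", "contig4"),
    start = c(5001L, 18001L, 8001L, 16001L, 12001L, 15001L,
              11001L, 12001L),
    end = c(5080L, 18080L, 8080L, 16080L, 12080L, 15080L,
            11080L, 12080L),
    strand = c("+", "-", "+", "+", "-", "+", "+", "-"),
    stringsAsFactors = FALSE)
  simulateGenome(
    nContigs = nContigs, contigLength = contigLength,
    clusterSpec = clusterSpec, mirnaSpec = mirnaSpec,
    bContigs = stats::setNames(rep(bMultiplier, 2),
                               c("contig1", "contig2")),
    nSnpsPerBContig = snpsPerBContig, seed = seed)
}
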