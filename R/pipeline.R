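# Flat key=value run configuration with documented keys and defaults.
.configDefaults <- function() {
  list(
    n_contigs = 10L, contig_length = 50000L, b_multiplier = 3,
    snps_per_b_contig = 5L,
    srna_reads = 200000L, u1_prob = 0.9, a10_prob = 0.3,
    noise_frac = 0, mirna_frac = 0.3,
    wgs_depth = 20, read_length = 100L, error_rate = 0,
    max_gap = 500L, min_tags = 10L, min_weight = 20,
    min_size = 1000L, min_frac_1u10a = 0.75, min_frac_len = 0.75,
    min_main_frac = 0.75, min_expr = 5, max_hits = 100L,
    ratio_threshold = 2,
    cq_samples_per_group = 4L, cq_sigma = 0.15, n_perm = 2000L
  )
}

#' Read a flat key=value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Unknown keys are rejected. Missing keys take the documented defaults
#' (see \code{curupira:::.configDefaults()} for the full list).
#'
#' @param path config file path, or \code{NULL} for pure defaults.
#' @return named list of parameters with class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (l in lines) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("cannot parse config line: '", l, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
      cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val)
                    else as.numeric(val)
    }
  }
  structure(cfg, class = "RunConfig")
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage end to end on the standard synthetic study:
#' genome simulation with planted truth, four gonadal small-RNA libraries,
#' length filtering and tag collapsing, exact mapping, piRNA cluster
#' calling, B-/B+ WGS simulation with coverage-ratio B-contig detection
#' and B-specific SNP calling, miRNA/piRNA colocalization, and
#' delta-delta-Cq gene-dose quantification with a permutation test. All
#' stage outputs are written as plain-text tables under \code{outDir};
#' re-running with the same config and seed reproduces them byte for byte.
#' Every parameter and an md5 checksum of every output lands in
#' \code{run_log.txt}.
#'
#' @param config a \code{RunConfig} from [readRunConfig()] (or \code{NULL}
#'   for defaults).
#' @param outDir output directory.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return invisibly, a list of in-memory stage results (\code{truth},
#'   \code{tags}, \code{clusters}, \code{ratios}, \code{bClusters},
#'   \code{variants}, \code{coloc}, \code{gdr}, \code{permP}, plus the
#'   written \code{paths}).
#' @export
runAll <- function(config = NULL, outDir, seed) {
  if (is.null(config)) config <- readRunConfig(NULL)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  say <- function(...) writeLines(paste0(...), logCon)
  say("curupira run-all")
  say("seed = ", seed)
  for (k in names(config)) say(k, " = ", config[[k]])

  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  truth <- stage("simulate-genome", studyTruth(
    seed = childSeed(seed, "genome"),
    nContigs = config$n_contigs, contigLength = config$contig_length,
    bMultiplier = config$b_multiplier,
    snpsPerBContig = config$snps_per_b_contig,
    u1Prob = config$u1_prob, a10Prob = config$a10_prob))
  truthPaths <- exportTruth(truth, file.path(outDir, "truth"))

  reads <- stage("simulate-srna", {
    parts <- lapply(SRNA_GROUPS, function(g)
      simulateSrnaLibrary(truth, g, nReads = config$srna_reads,
                          u1Prob = config$u1_prob,
                          a10Prob = config$a10_prob,
                          noiseFrac = config$noise_frac,
                          mirnaFrac = config$mirna_frac,
                          seed = childSeed(seed, paste0("srna", g))))
    do.call(c, parts)
  })

  tags <- stage("preprocess", collapseReads(lengthFilter(reads)))
  tagPaths <- writeTagSet(tags, file.path(outDir, "tags.fasta"),
                          file.path(outDir, "tags.tsv"))
  utils::write.table(lengthHistogram(lengthFilter(reads)),
                     file.path(outDir, "length_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mapped <- stage("map", mapTags(tags, buildGenomeIndex(truth),
                                 maxHits = config$max_hits))

  clusters <- stage("call-clusters", callClusters(
    mapped$hits, tags, maxGap = config$max_gap,
    minTags = config$min_tags, minWeight = config$min_weight,
    minSize = config$min_size, minFrac1u10a = config$min_frac_1u10a,
    minFracLen = config$min_frac_len, minMainFrac = config$min_main_frac,
    minExpr = config$min_expr))
  writeClusterTsv(clusters, file.path(outDir, "clusters.tsv"))
  writeClusterBed(clusters, file.path(outDir, "clusters.bed"))
  writeClusterGff3(clusters, file.path(outDir, "clusters.gff3"))

  blres <- stage("blocate", {
    simM <- simulateWgs(truth, "B-", meanDepth = config$wgs_depth,
                        readLength = config$read_length,
                        errorRate = config$error_rate,
                        seed = childSeed(seed, "wgsB-"))
    simP <- simulateWgs(truth, "B+", meanDepth = config$wgs_depth,
                        readLength = config$read_length,
                        errorRate = config$error_rate,
                        seed = childSeed(seed, "wgsB+"))
    lens <- stats::setNames(Biostrings::width(genomeSeq(truth)),
                            names(genomeSeq(truth)))
    ratios <- coverageRatioTable(simP$placements, simM$placements, lens,
                                 threshold = config$ratio_threshold)
    bcl <- flagBIntervals(ratios, clusters,
                          threshold = config$ratio_threshold)
    pP <- alignmentPileup(simP$reads, simP$placements, genomeSeq(truth))
    pM <- alignmentPileup(simM$reads, simM$placements, genomeSeq(truth))
    vars <- bSpecificVariants(pP, pM)
    list(ratios = ratios, bClusters = bcl, variants = vars)
  })
  utils::write.table(blres$ratios, file.path(outDir, "coverage_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(blres$variants,
                     file.path(outDir, "b_specific_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  coloc <- stage("coloc", colocTable(plantedMirnas(truth), clusters))
  writeColocTsv(coloc, file.path(outDir, "coloc.tsv"))

  quant <- stage("quant", {
    cq <- simulateCqTable(nPerGroup = config$cq_samples_per_group,
                          mode = "gdr", sigma = config$cq_sigma,
                          seed = childSeed(seed, "cq"))
    gdr <- geneDoseRatio(cq, "target", "reference")
    pt <- permutationTest(gdr$gdr, gdr$b_status,
                          nPerm = config$n_perm,
                          seed = childSeed(seed, "perm"))
    list(gdr = gdr, permP = pt$p)
  })
  utils::write.table(quant$gdr, file.path(outDir, "gdr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, logPath)
  for (f in sort(outputs))
    say("output ", sub(paste0("^", outDir, "/?"), "", f), " md5 ",
        unname(tools::md5sum(f)))
  say("permutation p (GDR ~ B status) = ", quant$permP)
  say("done")

  invisible(list(truth = truth, tags = tags, clusters = clusters,
                 ratios = blres$ratios, bClusters = blres$bClusters,
                 variants = blres$variants, coloc = coloc,
                 gdr = quant$gdr, permP = quant$permP,
                 paths = c(truthPaths, tagPaths, outDir = outDir)))
}
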