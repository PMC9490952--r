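#' Read a qPCR Cq table
#'
#' Expected TSV columns: \code{sample_id}, \code{sex} (F/M),
#' \code{b_status} (B-/B+), \code{tissue}, \code{gene}, then one or more
#' replicate columns \code{cq_rep1}, \code{cq_rep2}, ...
#'
#' @param path TSV path.
#' @return data.frame with a computed \code{cq} column (arithmetic mean of
#'   replicates) alongside the metadata columns.
#' @export
readCqTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  reps <- grep("^cq_rep", colnames(df), value = TRUE)
  if (!length(reps)) stop("no cq_rep* replicate columns found")
  cqm <- as.matrix(df[, reps, drop = FALSE])
  if (any(!is.na(cqm) & (cqm <= 0 | cqm >= 45)))
    stop("Cq values must lie in (0, 45)")
  df$cq <- rowMeans(cqm, na.rm = TRUE)
  df
}

#' Delta-Cq: target minus reference quantification cycle
#' @param targetCq,referenceCq quantification cycles (vectorized).
#' @return \code{targetCq - referenceCq}.
#' @export
deltaCq <- function(targetCq, referenceCq) targetCq - referenceCq

#' Relative quantity by the delta-delta-Cq method
#'
#' \deqn{ratio = E^{-(\Delta Cq_{sample} - \Delta Cq_{calibrator})}}
#' with amplification efficiency factor \code{E} (2 = perfect doubling per
#' cycle). Invariant to any constant shift applied to all Cq values.
#'
#' @param sampleDeltaCq,calibratorDeltaCq delta-Cq values.
#' @param efficiency amplification factor per cycle, > 1 (default 2).
#' @return relative quantity ratio(s).
#' @examples
#' relativeQuantity(5, 3)  # 2^-2 = 0.25
#' @export
relativeQuantity <- function(sampleDeltaCq, calibratorDeltaCq,
                             efficiency = 2) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  efficiency^-(sampleDeltaCq - calibratorDeltaCq)
}

#' Gene dose ratio (GDR) from genomic qPCR
#'
#' Computes, for every sample, the relative genomic quantity of a target
#' gene against a single-copy reference gene, calibrated on the mean
#' delta-Cq of the B- group, so B- samples center at GDR 1 and a
#' duplicated target in B+ samples doubles their GDR.
#'
#' @param cq data.frame as returned by [readCqTable()] (needs columns
#'   \code{sample_id}, \code{b_status}, \code{gene}, \code{cq}).
#' @param targetGene,referenceGene gene labels in the \code{gene} column.
#' @param efficiency amplification factor, default 2.
#' @return data.frame: \code{sample_id}, \code{sex} (if present),
#'   \code{b_status}, \code{gdr}; samples lacking the reference gene are
#'   skipped with a warning.
#' @export
geneDoseRatio <- function(cq, targetGene, referenceGene, efficiency = 2) {
  t <- cq[cq$gene == targetGene, , drop = FALSE]
  r <- cq[cq$gene == referenceGene, , drop = FALSE]
  i <- match(t$sample_id, r$sample_id)
  if (any(is.na(i))) {
    warning("skipping sample(s) without reference gene: ",
            paste(t$sample_id[is.na(i)], collapse = ", "))
    t <- t[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
  }
  if (!nrow(t)) stop("no samples with both target and reference gene")
  dcq <- deltaCq(t$cq, r$cq[i])
  bm <- t$b_status == "B-"
  if (!any(bm)) stop("no B- calibrator samples")
  calib <- mean(dcq[bm])
  out <- data.frame(sample_id = t$sample_id,
                    b_status = t$b_status,
                    gdr = relativeQuantity(dcq, calib, efficiency),
                    stringsAsFactors = FALSE)
  if ("sex" %in% colnames(t)) out <- cbind(out, sex = t$sex)
  out
}

#' Relative expression table by delta-delta-Cq
#'
#' Like [geneDoseRatio()] but for expression data: each sample's delta-Cq
#' (target minus reference-gene Cq) is calibrated on the mean delta-Cq of
#' the \code{calibratorGroup} (default the B- samples).
#'
#' @inheritParams geneDoseRatio
#' @param calibratorGroup b_status label of the calibrator group.
#' @return data.frame with \code{sample_id}, \code{b_status},
#'   \code{relExpr} (and \code{sex} if present).
#' @export
relativeExpression <- function(cq, targetGene, referenceGene,
                               calibratorGroup = "B-", efficiency = 2) {
  out <- geneDoseRatio(cq, targetGene, referenceGene, efficiency)
  names(out)[names(out) == "gdr"] <- "relExpr"
  out
}

#' Two-sided permutation test for a difference in group means
#'
#' Tests the absolute difference of group means by label permutation.
#' In the default Monte-Carlo mode the p-value is
#' \code{(1 + #permuted |dMean| >= observed) / (1 + nPerm)}, deterministic
#' given \code{seed}. With \code{exhaustive = TRUE} all assignments of the
#' observed group sizes are enumerated and the count runs over every
#' assignment (including the observed one).
#'
#' @param values numeric measurements.
#' @param groups two-level grouping vector (e.g. B status or sex).
#' @param nPerm number of Monte-Carlo permutations (default 10000).
#' @param seed integer seed (required unless exhaustive).
#' @param exhaustive enumerate all assignments instead of sampling.
#' @return list: \code{p}, \code{observed} (|difference of means|),
#'   \code{nPerm} (permutations or assignments used).
#' @export
permutationTest <- function(values, groups, nPerm = 10000L, seed = NULL,
                            exhaustive = FALSE) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  g1 <- which(groups == lv[1])
  if (!length(g1) || length(g1) == length(values))
    stop("both groups must be non-empty")
  obs <- abs(mean(values[g1]) - mean(values[-g1]))
  n <- length(values); n1 <- length(g1)
  statOf <- function(idx1) {
    s1 <- sum(values[idx1])
    abs(s1 / n1 - (sum(values) - s1) / (n - n1))
  }
  if (exhaustive) {
    comb <- utils::combn(n, n1)
    s1 <- colSums(matrix(values[comb], nrow = n1))
    stats <- abs(s1 / n1 - (sum(values) - s1) / (n - n1))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + ncol(comb))
    return(list(p = p, observed = obs, nPerm = ncol(comb)))
  }
  if (is.null(seed)) stop("seed is required for Monte-Carlo permutation")
  withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      if (statOf(sample.int(n, n1)) >= obs - 1e-12) cnt <- cnt + 1L
    }
    list(p = (1 + cnt) / (1 + nPerm), observed = obs, nPerm = nPerm)
  })
}

#' Simulate a qPCR Cq table with known group effects
#'
#' Generates per-sample Cq values for a target and a reference gene under
#' the standard exponential-amplification model
#' \code{Cq = base - log2(quantity) + noise}. In \code{"gdr"} mode the
#' quantity is genomic copy number (\code{copiesBminus} vs
#' \code{copiesBplus}); in \code{"expression"} mode it is transcript
#' abundance with a \code{log2FoldBplus} effect in B+ samples. Gaussian
#' technical noise (sd \code{sigma}, default 0.15 cycles) is added per
#' measurement.
#'
#' @param nPerGroup samples per (sex, B status) group (default 4).
#' @param mode \code{"gdr"} or \code{"expression"}.
#' @param copiesBminus,copiesBplus relative target copy numbers in
#'   \code{"gdr"} mode (defaults 1 and 2: one extra copy).
#' @param log2FoldBplus B+ expression effect in \code{"expression"} mode.
#' @param baseCqTarget,baseCqReference baseline Cq values.
#' @param sigma technical noise sd in cycles.
#' @param seed integer seed.
#' @return data.frame in the long format of [readCqTable()] (with
#'   \code{cq} already averaged over \code{nReplicates = 1}).
#' @export
simulateCqTable <- function(nPerGroup = 4L, mode = c("gdr", "expression"),
                            copiesBminus = 1, copiesBplus = 2,
                            log2FoldBplus = 1, baseCqTarget = 24,
                            baseCqReference = 20, sigma = 0.15, seed) {
  mode <- match.arg(mode)
  grid <- expand.grid(sex = c("F", "M"), b_status = c("B-", "B+"),
                      rep = seq_len(nPerGroup), stringsAsFactors = FALSE)
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      id <- paste0(g$sex, sub("B", "b", g$b_status), "_", g$rep)
      qty <- if (mode == "gdr") {
        if (g$b_status == "B+") copiesBplus else copiesBminus
      } else {
        if (g$b_status == "B+") 2^log2FoldBplus else 1
      }
      data.frame(
        sample_id = id, sex = g$sex, b_status = g$b_status,
        tissue = "gonad",
        gene = c("target", "reference"),
        cq = c(baseCqTarget - log2(qty) + stats::rnorm(1, 0, sigma),
               baseCqReference + stats::rnorm(1, 0, sigma)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
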