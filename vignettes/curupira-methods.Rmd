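---
title: "Methods: piRNA cluster discovery and B-chromosome location"
author: "curupira authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA cluster discovery and B-chromosome location}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curupira)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. No empirical claim is made here beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The inference chain

The package answers two linked questions about a gonadal small-RNA
dataset from a species with a supernumerary (B) chromosome: *where are the
piRNA clusters in the reference assembly*, and *which of them are carried
on the B chromosome*, given that the B has no assembly of its own and can
only be seen as duplicated sequence in carrier (B+) genomic reads.

### 1.1 Tags and multi-mapper weighting

Reads are first restricted to the mature piRNA length range, 24–35 nt,
then collapsed to unique sequence tags; a tag keeps one count per library
(`FB-`, `FB+`, `MB-`, `MB+`: sex crossed with B status). Mapping reports
*all* genomic placements of a tag at its best stratum (exact placements
when any exist; optionally 1-mismatch placements otherwise), and the tag's
read count is spread uniformly over its `n` placements, so each hit
carries weight `count / n`. Summed weights therefore conserve read counts
exactly — the invariant the test suite checks — and repetitive tags do not
inflate any single locus. Tags with more than `maxHits = 100` placements
are hyper-repetitive and dropped entirely; the cap is configurable.

Assumption: piRNAs match their source locus exactly. The default
`maxMismatch = 0` encodes that; the 1-mismatch stratum exists for external
alignments produced by production aligners with laxer defaults.

### 1.2 Cluster calling

The scanner builds maximal runs of hits on a contig in which consecutive
hit starts are at most `maxGap = 500` bp apart, and keeps runs with at
least `minTags = 10` distinct tags and `minWeight = 20` summed weight. A
run is accepted as a piRNA cluster iff

* its span is at least **1000 bp**,
* the weighted fraction of member reads whose first base is U or whose
  tenth base is A is at least **0.75**, and
* the weighted fraction with typical piRNA length (24–35 nt) is at least
  **0.75**.

These three thresholds are the published acceptance criteria of
proTRAC-style cluster prediction; threshold equality passes because they
are phrased as minima. The internal locus-finding of proTRAC (a
sliding-window read-density model with a p-value machinery) is *not*
reproduced: the gap-based scanner is the simplest mechanism that exposes
the three printed criteria, all of its parameters are explicit, and its
behaviour is exactly testable. The cost of that simplicity is noise
robustness: uniformly scattered background reads denser than one per
`maxGap` will chain into contig-sized candidates that then fail the
signature filters, so on noisy data the scanner should be run after
depth-of-coverage thresholding (raise `minWeight`) or with a smaller
`maxGap`. This is a known limitation, not an accident.

Directionality is the weighted main-strand fraction: `mono:+` or `mono:-`
at ≥ 0.75, `bi` below. Bidirectional clusters are reported as single
intervals, not split by strand, matching how dual-strand clusters are
conventionally tabulated. A cluster is "expressed" in a library when its
weighted mass there reaches `minExpr = 5` reads. Accepted clusters from
re-runs under different parameters can be merged by interval union
(`mergeClusterRuns()`), with metrics recomputed on the merged span.

### 1.3 Coverage-ratio B location

For each contig the mean read depth of the B+ and B− genomic libraries is
normalized by the library's total mapped bases and divided:

$$ r = \frac{\bar d_{B+} / T_{B+}}{\bar d_{B-} / T_{B-}} $$

Contigs with `r > 2` (strict) are putative B-resident sequence — the
duplicated-copy signal — and clusters on them become B candidates. The
flag is decided at *contig* level (the whole contig is the duplication
unit in a fragmented assembly); per-interval ratios are available for
inspection. A zero B− mean yields an infinite ratio carried with an
explicit marker.

Total-mapped-bases normalization makes the rule robust to unequal
sequencing depth, with one caveat the package states openly: when the
B-resident excess is a *large* fraction of all sequence, the B+ library
spreads its reads over a larger effective genome, deflating all
normalized ratios by the factor (genome size)/(effective B+ genome size).
In a real genome the B chromosome is a small fraction and the factor is
close to 1; in a deliberately B-heavy synthetic genome (e.g. 2 of 10
contigs at multiplier 3) unit contigs sit near 0.71 and multiplier-3
contigs near 2.14 — still correctly flagged at the strict > 2 threshold.
The package's calibration checks therefore use a genome whose B excess is
realistically small (one multiplier-3 contig among 12), where unit
contigs are expected at 0.857 and the B contig at 2.57.

The ratio is a qualitative indicator of B residency, not a copy-number
estimate, and the package deliberately reports ratios rather than copy
counts.

### 1.4 B-specific SNPs

A site is B-specific when both libraries reach `minDepth = 5`, the
alternative allele reaches frequency `minAltBplus = 0.2` in B+ reads and
stays at or below `maxAltBminus = 0.02` in B− reads. Polymorphisms seen in
both libraries are ordinary A-complement SNPs and are excluded. The three
thresholds are package defaults exposed as arguments — the corresponding
manual inspection step they replace has no published parameters. Pileups
are summarized as mismatch-site tallies plus coverage, which stays small
at any depth when errors are rare; plain site-tally data frames are
accepted too.

### 1.5 Kimura divergence landscapes

TE copies are dated by the Kimura two-parameter distance from their family
consensus, \(K = -\tfrac12\ln\big((1-2p-q)\sqrt{1-2q}\big)\), with `p` and
`q` the per-site transition and transversion proportions over aligned
ACGT/ACGT columns (gap columns stripped pairwise). Beyond the model domain
(`1 − 2p − q ≤ 0` or `1 − 2q ≤ 0`) the distance saturates: `kimura2p()`
raises an error, and `alignmentDivergence()` reports `K = NA` with a
`saturated` flag so that pipelines over arbitrary pairs do not abort. An
optional CpG mask skips consensus CpG dinucleotide positions — a site-mask
approximation of the weighted CpG correction used by repeat-landscape
pipelines, chosen because the plain form is exactly testable and the
landscapes are used comparatively.

A landscape assigns each copy's aligned bp to the divergence bin
`floor(100 K)` (width 1 %, clamped at 50 %), so binned mass equals total
aligned bp exactly. B−/B+ comparison normalizes each landscape by its
assembly size and flags bins where B+ mass exceeds 1.5× the B− mass with
at least `minMass = 1e-4` normalized mass — the "young-copy excess"
signature of families amplified on the B.

### 1.6 ΔΔCq quantification

Relative quantity is \(E^{-(\Delta Cq_{sample} - \Delta Cq_{calib})}\)
with the amplification factor fixed at `E = 2` (100 % efficiency) unless
configured; replicate Cq values are arithmetically averaged before ΔCq,
the standard practice. Gene dose ratios calibrate each sample against the
mean ΔCq of the B− group, so B− centers at GDR 1 and a duplicated target
doubles the B+ GDR. Group effects (B status, sex) are tested by a
two-sided permutation test on the absolute difference of group means:
Monte-Carlo p = (1 + #{permuted ≥ observed}) / (1 + nPerm), deterministic
under its seed, or exhaustive enumeration of all assignments for the
small cohorts typical of qPCR. The permutation test replaces a parametric
gamma-GLM analysis on purpose: it needs no distributional assumption,
its null calibration is checked empirically in the acceptance suite
(type-I error within [0.03, 0.07] at α = 0.05 over 1000 null cohorts),
and it preserves the significance decision the analysis needs.

## 2. The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which every downstream claim is verified.

**What it emulates.** Four gonadal sRNA libraries with a 28–29 nt piRNA
length mode (default profile over 26–31 nt) and a 21–22 nt miRNA mode;
5′U and 10A base biases at planted probabilities (defaults 0.9 and 0.3);
mono- and bidirectional clusters (main-strand fraction 0.95 and 0.5);
B−/B+ WGS read sets in which B-resident contigs carry a copy-number
multiplier ≥ 2 and B-specific SNPs whose alt allele appears in B+ reads at
frequency (m−1)/m; TE copies mutated from consensus at exact counted
transition/transversion proportions (`round(rate × length)` sites, no site
hit twice).

Two design choices deserve emphasis:

* **Bias by placement, not by editing.** A piRNA read's 5′U is realized by
  drawing its start from genomic positions whose strandwise base is T
  (with probability `u1Prob`; from non-T starts otherwise, so the realized
  fraction is exact). Reads therefore remain exact genomic substrings and
  the whole chain — simulate, collapse, map at zero mismatches, call —
  closes without any sequence mismatch artifacts.
* **Noise-free defaults.** `noiseFrac` (uniform random genomic fragments)
  and the WGS `errorRate` default to 0, isolating method behaviour from
  noise-model choices; both are configurable and exercised in unit tests.

**What it does not emulate.** Quality scores and sequencing-error
profiles, adapter remnants, PCR duplicates, paired ends, read-length
artifacts, assembly gaps and Ns (the alphabet is strict ACGT), pericentric
repeat structure, and real TE nesting. Passing the recovery tests
therefore demonstrates correctness of the *inference chain* under its
stated assumptions, not robustness to every artifact of real libraries.

**Determinism.** Every simulator takes an explicit seed, draws from one
seeded generator per call, and restores the caller's RNG state; identical
arguments give byte-identical FASTA/FASTQ/SAM output. Pipeline stages
derive child seeds from the master seed by a fixed hash.

## 3. Problem sizes and numerical choices

The standard synthetic study (`studyTruth()`) is a 10 × 50 kb genome with
five planted clusters of 1.5–8 kb (three mono, two bi), two of them on
multiplier-3 B contigs, four libraries of 2×10⁵ reads and 20× WGS — sizes
chosen so the full chain, including the acceptance script, completes in
about a minute on a single CPU while leaving thousands of distinct tags
per cluster. Other fixed choices:

* Coordinates are 0-based half-open internally wherever BED is involved
  and 1-based inclusive in every human-facing table, matching how
  published colocalization tables print intervals; BED and GFF3 parsers
  convert at the boundary.
* Interval superposition means ≥ 1 bp overlap, strand-agnostic (sense and
  antisense miRNAs both occur inside clusters of either transcription
  strand).
* TE-class assignment for a read: largest overlap, ties to the leftmost
  annotation — deterministic output.
* Threshold comparisons: cluster criteria are minima (≥ passes), the
  coverage-ratio flag is strict (> 2), permutation p-values use the
  add-one formula; exhaustive enumeration counts the observed assignment
  among its peers.
* The packaged colocalization annotation stores one record with a missing
  transcription strand, as printed in its source; parsers keep it `NA`
  rather than guessing.

## 4. Known limitations

* The gap-based scanner is not a density model; heavy uniform background
  merges candidates (see §1.2).
* No ping-pong 5′-overlap (z-score) or phasing analysis; directionality
  is the only transcription-structure call.
* Coverage ratios are qualitative; no copy-number or breakpoint model.
* The Kimura estimator trusts its input alignment; it does not realign,
  and the CpG option is a site mask, not the weighted correction.
* ΔΔCq assumes a constant amplification efficiency per run; no standard
  curve estimation is provided.
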