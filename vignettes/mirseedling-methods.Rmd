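---
title: "Models and methods behind mirseedling"
author: "mirseedling authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirseedling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseedling)
```

`mirseedling` turns the analysis used to profile miRNAs in cumin
(*Cuminum cyminum*) seedlings — a species without a sequenced genome —
into a self-contained, deterministic R pipeline. This vignette explains
each model, the parameters that matter, the numerical choices, and what
the synthetic-data tests do and do not establish about real data.

## Preprocessing

Reads pass through a fixed cascade: 3′ adapter trimming, quality
filtering, length bounds, collapsing into unique tags, and ncRNA
subtraction. Every read ends in exactly one terminal accounting category,
so the categories always sum to the input — a property the tests enforce
rather than assume.

* **Adapter trimming** scans for the leftmost position where a prefix of
  the 3′ adapter covers the read's tail with at least `min_overlap = 8`
  aligned bases and a mismatch rate ≤ 0.1. Reads with no detectable
  adapter are kept and flagged `untrimmed`: a full-length insert with a
  short or absent adapter is still a usable tag, and the flag lets the
  accounting report both conventions. The default adapter is the QIAseq
  miRNA 3′ adapter used for this library type.
* **Quality**: the published filter is stated only as "< Q30". We
  interpret it as *mean* read Phred < 30, the common small-RNA
  convention; a per-base rule at Q30 would discard most reads of
  otherwise high quality and is not what sRNA workbenches do by default.
  Reads containing N are discarded (configurable).
* **Length bounds** of 16–40 nt apply to the *post-trim* insert.
* **ncRNA subtraction** removes a tag iff it (or its reverse complement)
  is an exact substring of any reference sequence. No mismatch tolerance
  is published for this step; exactness makes the partition reproducible
  and is checked against planted contaminants.

## Conserved miRNA classification

The homology rule in the source workflow is "maximum of a single
mismatch". We implement it literally: a tag is conserved iff some
equal-length mature reference entry is within Hamming distance 1 (U/T
unified). Among qualifying references the hit with fewest mismatches
wins; remaining ties go to the lexicographically smallest reference id,
so classification is independent of reference file order. This replaces
the original BLASTn step: BLAST's heuristics, E-values and
length-mismatched local alignments are not reproducible from the stated
criterion, whereas equal-length Hamming matching is exactly the stated
criterion. Consequently E-values are not reported, and the published
summary table's occasional length-mismatched query/reference rows cannot
arise under our stricter rule — a documented deviation.

Names follow the `cci-` convention: the reference id minus its species
prefix. When two distinct tag sequences map to the same local name, the
lowest-mismatch tag keeps the plain name and later ones get a numeric
suffix.

The counting unit throughout is the *distinct tag with a qualifying
hit*. The source study reports several incompatible conserved totals
(142, 349, 353) whose units cannot be reconciled from the text; we
define ours explicitly and leave the discrepancy alone.

## Folding model and MFEI

Precursor structures are predicted by a Zuker-style dynamic program
under a reduced nearest-neighbour model: stacking energies for the six
allowed pair types (AU, UA, GC, CG, GU, UG), hairpin/bulge/internal
loop penalties by size, an affine multibranch cost, minimum hairpin loop
of 3 nt, no pseudoknots, no dangling ends, no coaxial stacking, 37 °C.
Parameters live in plain TSV tables under `inst/extdata/` and can be
overridden.

Numerical choices:

* Energies are handled in **integer tenths of kcal/mol**, so the DP, the
  traceback re-scorer (`structure_energy()`) and the exhaustive
  enumeration oracle agree exactly rather than to floating-point
  tolerance.
* Interior loops are capped at 30 unpaired nt in the search (the
  standard restriction); penalties beyond tabulated sizes extrapolate
  logarithmically, so any structure can still be scored.
* Ties in the traceback prefer leaving positions unpaired, making the
  reported structure deterministic across platforms.

Because this model is deliberately smaller than the full Turner model
used by folding web servers (whose settings for the original analysis
are unpublished), absolute MFE values differ from the published
per-precursor numbers. The package therefore anchors its verification on
the *formula and thresholds* — `AMFE = |MFE|/length × 100`,
`MFEI = AMFE / GC%`, acceptance at MFEI ≥ 0.70 — and on the statistics
of the published MFEI column (mean 0.98, SD 0.14, range 0.70–1.41),
which are recomputed from the bundled table. MFEI is reported as a
positive magnitude, matching how the published table prints it.

## Novel-miRNA discovery

Tags unexplained by homology are mapped to user-supplied contigs by
exact full-length search on both strands (tags hitting more than 20 loci
are treated as repetitive and dropped). Around each locus, candidate
precursor windows extend the tag by every combination of flank extents
from the grid {0, 20, 50, 100, 150, 250} nt, clipped to contig bounds —
a transparent, configurable replacement for the unpublished excision
heuristic of the original toolchain.

Each window is folded and accepted iff, in order: (a) the mature lies
entirely on one arm, (b) ≥ 14 mature bases are paired, (c) ≤ 4 mature
positions are unpaired against the star region and the largest
asymmetric bulge is ≤ 2, (d) MFEI ≥ 0.70, (e) the terminal loop is
≥ 3 nt. Only the MFEI rule is stated numerically in the source; (b),
(c) and (e) follow standard plant miRNA annotation practice and are
fully configurable through `precursor_criteria()`. The first failed rule
is recorded as the rejection reason.

Per tag, the accepted candidate with the highest MFEI wins (ties to the
shortest window). Candidates whose chosen windows overlap on a contig —
typically the mature and star arms of the same stem-loop — collapse to
the best-supported tag, so each hairpin yields one call. Calls are named
`cci-miRN1…` in descending read-count order (the published table's
ordering principle is not stated; this is our convention), with the arm
suffix taken from the fold geometry, and mature sequences reported in
the RNA alphabet.

## Target prediction

The expectation score follows the published conventions of the plant
target-prediction tool family the original study used: per-position
penalties of 1 (mismatch), 0.5 (G:U wobble) and 2 (gap), doubled within
the seed (miRNA positions 2–13 from the 5′ end), with sites reported at
expectation ≤ 5 and at most one bulged gap. The tool's exact
configuration is not published, so every constant is explicit in
`target_scheme()`. Query miRNAs are gated at read count ≥ 5, the stated
copy-number rule. Scanning evaluates every ungapped window plus every
single-gap variant and reports the best site per cluster of overlapping
candidates; a brute-force enumeration oracle checks the scan exactly.
Duplex stability is the sum of stacking energies over adjacent paired
columns of the antiparallel duplex (no intramolecular structure), the
weight used for network edges. A central mismatch at positions 9–11 is
annotated as translational inhibition rather than filtered.

The original study's target counts (3037/1959/1078) depend on an
unnamed transcript library and are not reproducible; the transcript set
is an explicit input here.

## qPCR quantification

Relative expression is `2^(−ΔCt)` against the endogenous control (U6 by
default), with amplification efficiency fixed at 2 but overridable.
Technical replicates are averaged *before* sample-level statistics — the
common convention; the source does not specify. The SD is taken over
per-sample `2^(−ΔCt)` values. `fold_change()` provides the ΔΔCt ratio
between conditions for reuse, though the source study is
single-condition.

## Synthetic data: what it emulates, what it does not

The generator plants stem-loop precursors (random matures with a 24-nt
modal length, star arm = reverse complement with a configurable number
of pair-breaking substitutions, pairing-poor loop, flanking extension
stem), structureless decoy loci, log-normal tag abundances
(`meanlog = 2.3`, `sdlog = 1.6` by default, giving a few
high-abundance tags and a long tail down to 1–2 copies like the
published read-count columns), adapter-bearing reads, optional
substitution errors, ncRNA contaminants sliced from a decoy reference,
and transcripts with target sites edited to score an exact designed
expectation. Every feature is recorded in a truth table, and all
generators are bit-reproducible under a fixed seed. Default star
mismatches are 2: a perfect duplex would make the mature tag match both
genomic strands and leave the strand call ambiguous.

What passing these tests shows: the algorithms implement their stated
rules exactly (oracle equivalence), conserve reads, and recover planted
signal perfectly under clean conditions. What they do not show:
performance on real libraries with sequencing-error structure, isomiR
heterogeneity, UMI duplication (out of scope), repetitive genomes, or
folding landscapes where the reduced energy model diverges from the full
Turner model. The problem sizes used by the test suite and acceptance
script — 100 folding oracle sequences of 15–25 nt, 500 mutated tags vs
a 200-entry reference, a 5-precursor/50-decoy genome, 50 scan-oracle
pairs on 120-nt transcripts, ~10⁴ simulated reads — were chosen so the
enumeration oracles stay exhaustive while exercising every code path.

## Known limitations

* Absolute folding energies are model-dependent; only MFEI-based
  decisions and published-table statistics are claimed.
* Hairpin-arm geometry is derived from the single MFE structure; near-MFE
  alternative folds are not considered (no partition function).
* Conserved counting follows the distinct-tag unit; published totals
  with other (unstated) units are not reproduced.
* The interface is R functions and `run_pipeline()`; there is no shell
  entry point, as the package is meant to be driven from R scripts and
  documents.
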