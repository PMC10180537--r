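# mirseedling

Plant small-RNA processing, microRNA discovery and target analysis in R.

`mirseedling` reimplements, as a reusable and fully tested R package, the
analysis workflow behind the cumin (*Cuminum cyminum*) seedling miRNA
profile (small-RNA library SRA **SRP376517**): cumin has no sequenced
genome, so its miRNAs are identified by homology to known plant mature
miRNAs plus hairpin-structure evidence on user-supplied contigs, and their
targets by plant-style complementarity scoring over a user-supplied
transcript set.

The package is tidyverse-native: every stage takes a data frame and
returns a tibble, results chain with the pipe, fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## What it computes

* **Preprocessing** (`run_preprocess()`): 3′ adapter trimming, mean-Q30
  quality filter, 16–40 nt length bounds, read collapsing into counted
  unique tags, exact-match ncRNA subtraction, Table-1-style read
  accounting and the unique-tag length distribution.
* **Conserved miRNAs** (`classify_conserved()`): equal-length
  Hamming matching of tags against a mature plant miRNA reference with at
  most one mismatch, `cci-` naming, family summaries.
* **Novel miRNAs** (`call_novel()`): exact mapping of unexplained tags to
  contigs, precursor-window excision on a flank grid, minimum-free-energy
  folding under a reduced nearest-neighbour model (Rcpp dynamic program),
  and acceptance by hairpin geometry plus the **minimal folding free
  energy index**

  `MFEI = (|MFE| / length × 100) / GC%  ≥ 0.70`

  with AMFE = |MFE|/length × 100. The MFEI threshold separates miRNA
  precursors (≈0.7–1.4) from tRNA (~0.64), rRNA (~0.59) and mRNA
  (0.62–0.66).
* **Targets** (`predict_targets()`): position-weighted expectation score
  (mismatch 1, G:U wobble 0.5, gap 2, doubled in seed positions 2–13,
  sites reported at expectation ≤ 5) for queries with read count ≥ 5,
  plus the intermolecular duplex MFE.
* **Network** (`build_network()`): MFE-weighted bipartite miRNA–target
  edges, degree summaries, annotation-category percentages, SIF export.
* **qPCR** (`relative_expression()`): 2^(−ΔCt) relative expression
  normalised to U6, technical replicates collapsed first.
* **Synthetic data** (`make_genome()`, `simulate_reads()`,
  `make_transcriptome()`, `make_ct_table()`): deterministic generators
  with truth tables so the whole pipeline is testable offline.

## Worked example

A fully synthetic run — plant three precursors in a toy genome, sequence
them, and rediscover them:

```r
library(mirseedling)

gen  <- make_genome(n_precursors = 3, n_decoys = 12,
                    contig_len = 3000, n_contigs = 2, seed = 305)
sim  <- simulate_reads(gen$truth, error_rate = 0, star_fraction = 0.1,
                       seed = 306)
prep <- run_preprocess(sim$reads, preprocess_config())
prep
#> Small-RNA preprocessing result
#>   reads in: 118, clean unique tags: 6
#>   modal tag length: 20 nt (33.33% of clean tags)

novel <- call_novel(prep$tags, gen$contigs)
novel[, c("name", "sequence", "length", "read_count", "strand", "mfei")]
#> # A tibble: 3 × 6
#>   name         sequence                 length read_count strand  mfei
#>   <chr>        <chr>                     <int>      <int> <chr>  <dbl>
#> 1 cci-miRN1-5p UCAGAUUAUACUGCGGAUAU         20         60 -       1.45
#> 2 cci-miRN2-5p GAAAGACUGUAUGUCAGGCGG        21         40 +       1.34
#> 3 cci-miRN3-3p CUUUCACGGAUUCACAUUGUUUUA     24          7 +       1.54
```

Each row is a called novel miRNA: its mature sequence (RNA alphabet), the
collapsed read support, the genomic strand of its precursor, and the
precursor's MFEI — all three planted hairpins are recovered, with the
correct strands and arms, and every MFEI clears the 0.70 acceptance
threshold. The bundled published summary tables are available as
`cumin_conserved_table()` and `cumin_novel_table()`.

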