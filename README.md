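# tefam

Transposable-element (TE) family enrichment from ChIP-seq data, with
ambiguously mapping reads retained and a background model learned from
the input control.

## Why

Reads from young TE subfamilies align to many near-identical copies.
Discarding these multimappers underestimates the signal at exactly the
families of interest, and a uniform genome-shuffle null misjudges
families that sit in biased chromatin. `tefam` addresses both:

* **Fractional counting.** A read with `N_r` mappings and length `L_r`
  contributes, for every mapping `i` and every TE copy `k` it overlaps,

  ```
  C_K = sum_k sum_r sum_i  l(k, r_i) / (N_r * L_r)
  ```

  where `l(k, r_i)` is the overlap in bases. A unimapper fully inside a
  copy contributes 1; a multimapper spreads a total weight of 1 across
  its loci.

* **Input-conditioned background.** The input control defines a
  per-nucleotide sampling distribution `p_n = cov_n / cov_c`, where
  `cov_n` is the ambiguity-weighted coverage (`1/N_r` per covering
  mapping). Simulated input libraries of the ChIP sample's exact size are
  drawn by picking a position from `p_n`, picking a read mapping there
  with probability `1/(cov_n N_r)`, and re-centering all of that read's
  mappings on the drawn position. `N` simulations (default 100) give an
  empirical P-value (fraction of simulations with a count at least the
  sample's; `p < 0.01` flags enrichment) and a fold-change (sample count
  over mean simulated count) per family.

The package also provides RepeatMasker annotation processing (class
filtering, merging of overlapping/adjacent copies, a 50-copy eligibility
threshold), data-derived artifact-window masking (sliding windows
100/50, 99.997th percentile of non-zero counts per chromosome and
genome), a uniform-shuffle baseline for bias comparison, and a synthetic
fixture generator with known multimapping structure so the entire tool
is testable without downloads.

## Worked example

A fully synthetic experiment: six TE families planted on a 100 kb
genome (three with identical copies, three at 4% divergence), an input
library with blocky accessibility bias, and a ChIP sample carrying a
3-fold enrichment at family `TE1`.

```r
library(tefam)

spec   <- fixture_spec(seed = 42)                   # default study conditions
fx     <- generate_genome_and_annotation(spec)
input  <- generate_mapping_library(fx, "input")     # 20,000 reads
sample <- generate_mapping_library(fx, "sample")    # 10,000 reads, 3x at TE1

fx$annotation
#> TEAnnotation: 48 merged copies, 6 families (level = name)
input
#> MappingLibrary: 20000 reads, 26913 mappings (1.35 per read), 1 chromosomes

res <- run_enrichment(sample, input, fx$annotation, N = 100, seed = 7)
res[order(-res$fold_change)][, 1:7]
#>    family_id n_copies sample_count background_mean fold_change pvalue enriched
#> 1:       TE1        8       580.92        205.9102   2.8212298   0.00     TRUE
#> 2:       TE3        8       276.36        271.1868   1.0190761   0.37    FALSE
#> 3:       TE4        8       162.30        164.0980   0.9890431   0.53    FALSE
#> 4:       TE2        8       134.52        137.5282   0.9781267   0.57    FALSE
#> 5:       TE6        8       241.62        250.6368   0.9640244   0.76    FALSE
#> 6:       TE5        8       195.44        202.7674   0.9638630   0.70    FALSE
```

The planted family is recovered at fold-change 2.82 (the nominal 3x is
slightly diluted by library-size renormalisation) with an empirical
P-value of 0 — i.e. below the 1/N floor, printed as `<0.01` in the TSV
report written by `write_results(res, "results.tsv")`. All other
families sit at fold-change ~1 and are not flagged.

Real data enter through `load_mappings()` (SAM/BAM produced by a mapper
reporting **all** mappings, e.g. `bwa mem -a`; for reads under 30 bp
lower the score threshold, e.g. `-T 25`), `apply_standard_filters()`
(chrM/scaffold removal, `N_r` recomputed) and optionally
`downsample_reads()` (20M default), with annotations from
`parse_repeatmasker()` + `filter_te_records()` + `merge_family_copies()`.
A thin command-line front end (`exec/tefam`, installed to
`system.file("exec", "tefam", package = "tefam")`) exposes the same
pipeline as `annotate`, `ingest`, `mask`, `count`, `enrich`,
`uniform-bg` and `fixtures` subcommands.

See the vignette (`vignettes/te-family-enrichment.Rmd`) for the model,
its assumptions, and all numerical conventions.

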