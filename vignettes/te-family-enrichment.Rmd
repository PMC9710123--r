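---
title: "Estimating ChIP-seq enrichment at transposable-element families with an input-based simulated background"
author: "tefam maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TE family enrichment methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tefam)
library(data.table)
```

## The problem

Transposable elements (TEs) make up large fractions of mammalian genomes,
and many carry transcription-factor binding sites or chromatin marks that
ChIP-seq can in principle detect. Two features of TE biology defeat the
standard peak-calling workflow:

* **Ambiguous mapping.** Copies of a young TE subfamily are nearly
  identical, so a short read from one copy aligns equally well to many.
  Discarding these multimappers systematically underestimates the signal
  at exactly the families of most interest; assigning them arbitrarily
  (e.g. keeping one alignment) misplaces it.
* **Non-uniform background.** Chromatin accessibility, fragmentation and
  amplification biases make the expected read density strongly
  position-dependent. A null model that scatters reads uniformly across
  the genome therefore produces both false positives (families that
  merely sit in accessible chromatin) and false negatives (families whose
  input coverage is already high).

`tefam` addresses both at the level of TE *families and subfamilies*
rather than individual copies: the quantity of interest is the aggregate
read mass a family attracts, compared with what matched simulated input
libraries attract.

## Counting with ambiguity weights

Each read \(r\) has \(N_r\) reported mappings (primary plus secondary) and
length \(L_r\). For a family with merged copy set \(K\), the count is

\[
C_K \;=\; \sum_{k \in K}\; \sum_{r}\; \sum_{i=1}^{N_r}
  \frac{l_{k,r_i}}{N_r\, L_r},
\]

where \(l_{k,r_i}\) is the number of reference bases of the \(i\)-th
mapping of \(r\) overlapping copy \(k\). A unimapper fully inside one
copy contributes exactly 1; a 4-way multimapper spreads a total weight of
1 over its four loci; partially overlapping mappings contribute the
overlapping fraction. Two consequences used as test invariants: over an
annotation whose families tile the genome, \(\sum_K C_K\) equals the
number of reads; and duplicating every read doubles every \(C_K\).

Overlap lengths use the mapping's *reference* span (CIGAR walk), so
soft-clipped bases never contribute, while the denominator keeps the full
read length.

## The input-based background

From the input-control library we build an ambiguity-weighted coverage:
position \(n\) receives \(1/N_r\) from every mapping covering it, giving
\(\mathrm{cov}_n\), and \(p_n = \mathrm{cov}_n / \mathrm{cov}_c\) per
chromosome \(c\), with zero probability outside the covered ("effective")
genome. Chromosomes are chosen with weight
\(w_c \propto \mathrm{cov}_c\), which makes genome-wide draw frequencies
proportional to \(\mathrm{cov}_n\) — the only choice consistent with a
single genome-wide normalisation.

A simulated read is produced by:

1. drawing a position from \(p_n\) (inverse transform);
2. drawing one of the reads mapping there with probability
   \(p_r = (\mathrm{cov}_n N_r)^{-1}\) (these sum to 1 at every effective
   position by construction);
3. shifting *all* of that read's mappings by the same offset so the drawn
   position becomes the selected mapping's center
   (center of a span-\(s\) mapping is \(\mathrm{start} +
   \lfloor (s-1)/2 \rfloor\); the left-of-center convention for even
   spans is arbitrary but fixed);
4. truncating mappings pushed partially out of chromosome bounds and
   dropping ones pushed entirely out (the selected mapping always retains
   at least one base, so library sizes are preserved).

This is repeated once per read of the ChIP-seq sample, yielding a
simulated input library of the same size; `N` such libraries (default
100) give, per family, an empirical P-value
\(p = \#\{ C_K^{sim} \ge C_K^{sample}\} / N\) (ties count against the
sample) and a fold-change
\(\mathrm{FC} = C_K^{sample} / \overline{C_K^{sim}}\). Families with
\(p < 0.01\) are flagged enriched. No multiple-testing correction and no
library-size normalisation are applied: sizes are matched by
construction.

### An algebraic shortcut in the simulator

Steps 1–2 jointly assign probability
\((1/N_r)\big/\sum_c \mathrm{cov}_c\) to every (mapping, base) pair of
the input library. `simulate_library()` therefore draws a mapping piece
with weight \(\mathrm{span}/N_r\) and a uniform base inside it — the same
distribution with no per-draw interval query. The position-first chain
remains available through `sample_position()` /
`sample_read_at_position()`, and the acceptance test compares the
empirical joint distribution of that public chain against the closed
form (total-variation distance below 0.01 at \(6 \times 10^5\) draws);
the two routes are algebraically identical, which the null-calibration
test confirms for the fast path.

Masked regions (below) are removed from the pieces before weighting, so
masked bases are sampled with probability exactly zero.

## Annotation processing

RepeatMasker annotations (UCSC `rmsk` table, native `.out`, or a BED
dialect with `name:family:class` name encoding) are reduced to TEs by
discarding simple repeats, satellites, low-complexity runs, structural
RNA classes and explicit artefacts; class "Unknown" is retained.
Counting operates at a configurable level: repeat *name* (subfamily,
default) or *family*. Within a family, overlapping and immediately
adjacent copies (zero gap in half-open coordinates — the only
parameter-free reading of "immediately adjacent") are merged; copies of
different families are never merged, so a base may legitimately belong to
two families and the counting formula then credits both. Statistics are
reported for families with at least 50 merged copies by default; counts
are computed for all families and filtered at reporting time. Strand is
ignored throughout, as the counting formula is strand-free.

## Artifact windows

Heterochromatic satellite regions can show extreme, artifactual coverage.
`detect_artifact_windows()` counts mappings in sliding windows (100 bp,
step 50 by default; a mapping counts in every window it overlaps),
computes the 99.997th percentile of the *non-zero* window counts once per
chromosome and once genome-wide (linear interpolation between order
statistics, `quantile` type 7 — the convention must be fixed for
reproducibility), and flags windows exceeding *both* thresholds (the
conservative reading; a union mode is available). Flagged windows are
unioned into a mask that removes the corresponding positions from the
background model and, by default, from the counted annotation as well.
Because window counts are mapping-level, loci inside families of many
identical copies stack their multimappers and can legitimately reach the
percentile — the same signature as satellite regions; masking both is the
intended behaviour, and the downstream fold-changes are insensitive to
the small annotated area this removes. Whether the thresholds generalise
beyond the genome they were derived on is a user decision.

## The uniform-shuffle baseline

For bias comparisons, `uniform_background_counts()` relocates every
mapping uniformly (chromosome chosen proportionally to the number of
placements that keep the mapping fully inside), and counts mappings per
family at the binary, unweighted level, mirroring the naive
shuffle-then-intersect null. On fixtures where input coverage is
concentrated in one family, this baseline expects several-fold fewer
reads at that family than the input-conditioned background — the
false-negative mechanism — and conversely flags multimapper-rich
families spuriously because their observed mapping-level counts are
inflated \(N_r\)-fold.

## The synthetic-data generator

`fixture_spec()` / `generate_genome_and_annotation()` /
`generate_mapping_library()` build fully deterministic fixtures: a random
background sequence with planted TE families whose copies are exact
duplicates (0% divergence) or carry per-copy point substitutions. A read
drawn fully inside one of \(m\) sequence-identical copies receives the
homologous mapping in all \(m\) (so \(N_r = m\) by construction); a read
window covering a substituted site maps only to compatible copies;
everything else is a unimapper. The input read density is a blocky Gamma
random field (block 1 kb, shape 5, mean 1), emulating smooth
accessibility/amplification bias; the sample density multiplies it by a
per-family fold over every start whose read overlaps an enriched copy —
fragment-level enrichment, so the advertised fold is delivered at the
count level, not only for fully internal reads. The generator emits
mappings directly (optionally as SAM round-trippable through the loader);
it does not model base qualities, sequencing errors or paired ends, and
its divergence model is point substitutions only — so passing tests
demonstrate correctness of the counting and background machinery, not
robustness to alignment artefacts in real data.

Default conditions: one 100 kb chromosome; six families of eight 250 bp
copies (three identical, three at 4% divergence); 50 bp reads; 20,000
input reads; 10,000 sample reads; a 3-fold plant at the first family.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GRanges conversion
  happens at module boundaries. Coverage uses run-length encoding, so
  chromosomes up to \(2.5\times10^8\) bp cost memory proportional to the
  number of coverage runs, not positions.
* `N_r` is recomputed after the chrM/scaffold filters (the counting and
  background formulas operate on the filtered universe); the filter logs
  how many mappings it removed so this is auditable.
* Empirical P-values of 0 are reported numerically as 0 and labelled
  `<1/N` in the report text column.
* Zero background mean: FC is 1 if the sample count is also 0, otherwise
  `Inf` with an `unstable` flag (families supported by very few copies).
* Ties in the report ordering are broken alphabetically by family id;
  reports are byte-reproducible for identical inputs and seed, and
  simulation iteration `i` uses the RNG substream `seed + i`, so any
  execution order gives identical results.
* The ambiguity classification uses strict `> 90%` dominance in every
  provided library (the stricter of the two published wordings), with an
  inclusive `>=` switch.

## Problem sizes used in the test-suite and acceptance script

Oracle comparisons run on 50–60 kb genomes with a few thousand reads,
where brute-force per-base loops are exact and fast. Null calibration
uses 200 independent runs of N = 100 simulations at 400-read sample size
on a 20 kb, 8-family genome — small enough to repeat hundreds of times,
large enough that every family is hit in every simulation. The
planted-enrichment check uses the generator defaults above. The artifact
check plants a 10,000-read stack in a 1,000,000-read library on 5 Mb so
that, as in real input libraries, the artifact is a small fraction of
the total mass, and uses 24-copy families so the fold-change comparison
is not noise-limited. These sizes are the package's chosen study
conditions; all thresholds (FC in [2.4, 3.6], null fraction in
[0.02, 0.10], TV < 0.01, FC shift < 5%) are fixed independently of them.

## Limitations

* Single-end data only; duplicate removal, trimming and mapping happen
  upstream (the mapper must report all mappings, e.g. `bwa mem -a`).
* Enrichment is per family/subfamily, never per individual copy.
* No GC or mappability correction, and no external blacklists: the only
  masking is the data-derived artifact mask.
* The empirical P-value floor is 1/N; with the default N = 100 the
  smallest reportable non-zero P is 0.01.
* `Inf` fold-changes at zero-background families indicate too little
  annotation support, not infinite enrichment.
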