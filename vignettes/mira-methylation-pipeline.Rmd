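---
title: "Methods: MIRA-chip methylation peak calling, differential analysis and bisulfite verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIRA-chip methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirachip)
```

## The measurement and the model

MIRA (methylated-CpG island recovery assay) enriches the methylated
fraction of sonicated genomic DNA with the MBD2b/MBD3L1 methyl-CpG binding
complex. Hybridizing the enriched fraction against input DNA on a tiling
microarray of CpG islands and gene promoters turns regional DNA
methylation into elevated per-probe log2(MIRA/input) ratios over runs of
adjacent probes. The pipeline in this package takes such two-channel probe
intensities to differential methylation verdicts in five deterministic
steps:

1. **Loess dye-bias correction, per array.** With
   $M = \log_2(\mathrm{MIRA}/\mathrm{input})$ and
   $A = \tfrac12\log_2(\mathrm{MIRA}\cdot\mathrm{input})$, a robust local
   regression of $M$ on $A$ is fitted per array and subtracted:
   the normalized ratio is $M - \hat f(A)$. Two-colour arrays show smooth
   intensity-dependent dye bias, which is exactly what an MA-loess
   removes; we use `limma::loessFit`, the standard implementation.
2. **Quantile normalization across all arrays of the experiment**
   (controls included), so every sample shares the distribution given by
   the across-sample mean of order statistics; ranks within a sample are
   preserved and ties receive the mean of their tied reference values
   (`limma::normalizeQuantiles(ties = TRUE)`).
3. **Positive probes.** A probe is positive when its normalized log2
   ratio exceeds 2-fold enrichment: $\log_2$ ratio $> 1$, strictly.
4. **Peak calling.** A methylation peak is a run of at least 4 positive
   probes within one tiled region, tolerating at most one gap, where a
   gap is a single negative probe strictly interior to the run.
5. **Differential calling.** For a treated/control pair, every candidate
   peak footprint is scored in both samples by its mean normalized log2
   ratio; a peak is hypermethylated when
   $\bar M_{treated} - \bar M_{control} > \log_2 3$ and hypomethylated
   when the difference is below $-\log_2 3$, strictly. No p-values are
   attached: the rule is a fixed effect-size threshold, and we keep it
   that way deliberately.

Called or differential peaks are annotated against promoter windows
(−2400 bp to +600 bp around the TSS, strand-aware, clipped at 0) and CpG
islands by ≥1 bp half-open interval overlap.

## Peak-rule semantics: the decisions that were genuinely open

The verbal rule "at least four consecutive positive probes with either
one gap or no gaps" leaves several cases undefined; the package fixes
them explicitly, and all are configurable:

* **A gap is one probe.** Two adjacent negative probes always terminate a
  run, whatever the gap budget. Gap probes do not count toward the four
  positives, but do not reset the count either.
* **Boundaries are positive.** A peak never starts or ends on a gap
  probe.
* **The peak mean includes gap probes**: `mean_log2_ratio` averages over
  *all* member probes. The alternative (positives only) biases the
  average upward in exactly the peaks that needed the gap.
* **Maximality and non-overlap.** Admissible runs can overlap (e.g.
  `P P N P P N P P` contains two overlapping 4-positive/1-gap windows),
  so "report all maximal runs" and "peaks never overlap" conflict. We
  emit left to right: each peak is the longest admissible run starting at
  the leftmost positive probe not already consumed. Every emitted peak is
  maximal and no two overlap. The test suite checks this against an
  independent exhaustive oracle that enumerates *all* admissible
  intervals and applies leftmost-then-longest selection.
* **Runs never cross region boundaries**, and adjacent probes more than
  `max_spacing` (default 500 bp) apart never share a run, so a "peak"
  cannot stitch together unrelated tiled fragments.

Similarly for the differential step: scoring only the treated sample's
peaks cannot see the *loss* of a control-only peak, so candidates are the
union of both samples' peaks, with overlapping footprints merged on their
union before scoring. Antisymmetry follows: swapping treated and control
maps every hypermethylation call to a hypomethylation call with negated
difference, exactly.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 1.0 | log2 ratio | "above 2-fold" on the log2 scale; strict |
| `min_positive` | 4 | probes | the consecutive-positive rule |
| `max_gaps` | 1 | probes | single-probe gap tolerance |
| `max_spacing` | 500 | bp | run continuity guard; tiling is ~100 bp |
| `delta_threshold` | log2(3) ≈ 1.585 | log2 ratio | differential effect floor; strict |
| `loess_span` | 0.3 | fraction of probes | common two-colour practice; window wide enough to smooth over enriched runs |
| `loess_iterations` | 3 | — | robustifying reweighting against enrichment outliers |
| promoter window | −2400/+600 | bp | the span the array tiles around each TSS |
| `min_conversion` | 0.95 (QC); 0 in the report | fraction | conversion filter; off when reproducing unfiltered clone figures |

## What the simulator emulates, and what it does not

`sim_config()` + `simulate_experiment()` generate the study conditions
end to end: alternating CpG-island and promoter regions tiled by 50-bp
probes every 100 bp; a lognormal input-channel baseline (log2 mean 10,
sd 1.5); shared methylation peaks in a random subset of regions with a
2.0 log2-unit enrichment (3.0 in the differential-recovery experiments);
per-probe Gaussian log2 noise (sd 0.25 by default); a smooth quadratic
dye bias in centred $A$ added to the MIRA channel; replicate samples
sharing the truth peak structure; and injected differential peaks —
hypermethylation as treated-only peaks, hypomethylation as shared peaks
withdrawn from the treated group.

Two generator choices deserve their rationale on record:

* **A minority of regions is methylated (`peak_density = 0.15`).**
  MA-loess presumes that the bulk of probes carry no signal. In an early
  design with ~25% of probes under peaks, the robust fit visibly absorbed
  about half of the peak elevation, because enriched probes (which sit
  ~effect/2 higher in $A$) dominated the upper loess windows. In a normal
  somatic methylome most CpG islands — and almost all promoter islands —
  are unmethylated, so a minority density is also the realistic setting.
  With 15% of regions methylated and a baseline $A$ spread of 1.5, the
  fitted trend tracks the unenriched majority at every intensity.
* **The lognormal baseline is a stand-in.** Nothing is claimed about the
  true raw-intensity distribution of NimbleGen scanners; the pipeline
  only consumes ratios and ranks, which is why a lognormal baseline
  suffices for testing.

Not modeled: scanner saturation, spatial artifacts, probe
cross-hybridization, sequence-dependent pulldown efficiency, PCR bias in
the bisulfite arm. Passing tests therefore demonstrate the *pipeline
logic* — normalization behaviour, the peak and differential rules, exact
bookkeeping — not robustness to every artifact of real array data.

One global seed drives a per-stage derived seed (`split_seed`), so the
design, the truth methylome, each sample, and each clone set are
independently reproducible; identical configurations reproduce outputs
bit for bit.

## The bisulfite arm

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while 5-methylcytosine resists. The toolkit applies this in silico
(`bisulfite_convert`, per-cytosine success probability
`conversion_rate`), analyzes COBRA cleavability — a TaqαI site TCGA
survives conversion iff its CpG is methylated, cuts falling at the T/C
boundary, fragment lengths always summing to the amplicon length — and
calls clones against the amplicon by gapless full-length alignment (both
orientations tried). At each CpG cytosine: C ⇒ methylated, T ⇒
unmethylated, anything else missing. Conversion efficiency is the T
fraction at non-CpG cytosines. Gapless alignment suffices because clones
are PCR products of a fixed amplicon; an indel-containing read fails the
unexplained-mismatch threshold (default 10%) and is rejected by name
rather than realigned. Only the top strand is modeled.

Percent methylation is `100 · methylated / (methylated + unmethylated)`
over the clone set, missing calls excluded; it is invariant to clone
order and duplication. A conversion-efficiency filter (default 0.95) is
available but disabled in the report pipeline, since published clone
percentages are typically unfiltered.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open internally; BED is written
  unshifted; GFF-style output would add 1 to starts on write.
* All threshold comparisons ("above", "more than") are strict
  inequalities; the boundary value is never called.
* Quantile normalization resolves within-sample ties by averaging the
  tied reference values. Its idempotence holds to 1e-9; rank invariance
  is tested in the form that is actually true — the reference itself
  moves when a sample is transformed, but the assignment by rank does
  not.
* Loess requires at least `ceiling(4/span)` probes and refuses
  non-positive intensities; samples are refused by the positivity step
  until normalized.
* Empty inputs degrade explicitly: zero peak-density truth sets, empty
  flag vectors, empty comparison lists and header-only lollipop output
  are all defined, and configuration errors (zero regions, probabilities
  outside [0, 1], motifs without a CpG) fail fast with named messages.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: 200-region arrays (~2,200
probes) for differential recovery and the 20-seed null experiment; 1,000
random flag vectors (lengths 1–40) against the exhaustive peak oracle;
5,000 probes for the loess trend check; 100 random amplicons for the
bisulfite round trip; 50 clones × 38 CpGs per group for the clone
percentages. The genome-scale counts of a real ~28,000-island array
depend on the deposited raw data and on normalization minutiae no method
section records, and are not a target of this package's tests.

## Known limitations

* The per-array loess and pooled quantile steps assume comparable global
  methylation between samples; a treatment that shifted methylation
  genome-wide would be partially normalized away — a known property of
  this class of pipeline, not a defect of the implementation.
* The differential rule is single-pair and deterministic; replicate
  variance only becomes visible by running all pairwise treated-control
  comparisons and inspecting the spread of their counts.
* Bottom-strand bisulfite analysis is available only by supplying the
  reverse-complemented amplicon; primer design and amplicon boundaries
  are the user's input.
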