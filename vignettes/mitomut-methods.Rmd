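---
title: "Methods: mtDNA heteroplasmy quantification for mutator-mouse cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA heteroplasmy quantification for mutator-mouse cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomut)
```

## The problem

Mice homozygous for a proofreading-deficient mitochondrial polymerase
gamma allele (Polg "mutator" mice) accumulate random point mutations in
mitochondrial DNA. Because oocyte mtDNA passes through a sharp germline
bottleneck each generation, mutations arising in the maternal line can
drift to high heteroplasmy and are then seen at similar frequencies in
every organ of the offspring, while somatic mutations stay private to an
organ and mostly at low frequency. This package implements the readout
side of such studies: given per-site allele-count tables from deep
sequencing of enriched mtDNA, it computes mutation-frequency statistics,
classifies substitutions under the vertebrate mitochondrial genetic
code, maps confirmed human pathogenic mtDNA mutations onto the mouse
genome, and compares genotype groups. A forward simulator of the
generative process supplies ground truth so that every stage is testable
without touching real sequencing data.

## The core statistic

The total mtDNA mutation frequency of a sample is

$$ f = 100 \times
   \frac{\text{base calls differing from the reference}}
        {\text{total base calls}} \;[\%], $$

computed over all sequenced positions. Decisions embedded in
`total_mutation_frequency()` and `region_mutation_frequency()`:

* **Zero-depth positions** contribute to neither numerator nor
  denominator: the statistic counts sequenced bases, and coverage is
  reported separately in the QC block (`qc_metrics()`).
* **Multi-allelic sites** contribute all non-reference base calls, not
  just the major alternative allele — the statistic counts mismatching
  bases, not variants.
* **Indels are kept out** of both numerator and denominator and are
  reported separately (`indel_frequency()`). Insertion-supporting reads
  are counted in the base-call depth at their anchor position and again
  in `ins`; deletion-supporting reads are not base calls, so the
  deletion denominator is `sum(depth) + sum(del)`.
* Per-region frequencies apply the same formula restricted to a gene's
  positions; the depth-weighted mean of the per-class frequencies over
  the class partition reproduces the total exactly (enforced to 1e-12
  relative tolerance in the tests).

Counting of non-synonymous and pathogenic-homologous variants uses a
**strict** per-site frequency threshold: a variant counts only when its
alternative-allele frequency *exceeds* the threshold (default 1%),
matching the convention that variants are quantified where the mutation
frequency exceeded 1%. The threshold applies to the per-site allele
frequency, not to the genome-wide statistic.

## Effect annotation

Substitutions in protein genes are classified by locating the codon from
the record's start and strand, translating reference and mutated codon
with NCBI translation table 2 (vertebrate mitochondrial: `ATA` = Met,
`TGA` = Trp, `AGA`/`AGG` = stop), and comparing amino acids. Stop gain
and stop loss count as non-synonymous — the binary classification has no
third class. Minus-strand genes are read on the reverse complement;
annotations always store reference-strand coordinates and reverse
complementation happens only at translation time.

Real mitochondrial genomes contain overlapping genes (ATP8/ATP6,
ND4L/ND4, ND5/ND6) and genes ending on an incomplete stop codon
completed by polyadenylation. The package resolves overlaps to the
**first record in file order** (warned once when the annotation is
built) and flags incomplete protein records instead of rejecting them; a
variant in the trailing partial codon of such a record is classified
`NA` with a warning rather than guessed.

Frequency histograms (`frequency_histogram()`) use decile bins with a
`(threshold, 10]` first bin, i.e. `(1,10], (10,20], ..., (90,100]` at
the default threshold. The exact bin edges of published histograms are
not standardized; decile bins make the >10% band — the signature of
germline-drifted variants — directly readable.

## Cross-species pathogenic liftover

Confirmed pathogenic human mtDNA mutations (MITOMAP-style catalog,
`load_pathogenic_catalog()`, default status filter `"Cfrm"`) are mapped
onto the mouse genome gene by gene: each ortholog pair is extracted on
its coding strand, globally aligned, and aligned positions are converted
back to reference-strand coordinates (`build_homology_map()`,
`lift_position()`). Since exactly two sequences are aligned per region,
a deterministic pairwise Needleman–Wunsch global alignment with affine
gaps replaces a multiple-alignment program; scoring defaults are match
+2, mismatch −1, gap open −5, gap extend −1. At the ≥85–90% nucleotide
identity of mitochondrial orthologs the optimal alignment is effectively
unambiguous — the tests verify that halving or doubling the gap-open
penalty does not move the focal ATP6 mapping. The alignment itself is
delegated to `Biostrings::pairwiseAlignment()`; an amino-acid-level
alignment cross-check was considered and omitted — the nucleotide
alignment is authoritative, and at ortholog identity levels a codon-space
alignment cannot disagree with it where it matters.

A catalog variant scores a hit when (i) its human position has a non-gap
mouse image, (ii) the mouse variant at that position exceeds the
frequency threshold, and (iii) under the default `"position+allele"`
mode, the mouse alternative allele equals the catalog alternative after
strand normalization. A `"position_only"` mode is available because
"homologous mutation" is not always defined down to the allele; the
default is allele-strict, consistent with the classic human
T8993C/mouse T8393C correspondence (T>C in both species). Sites where
the mouse reference already differs from the human reference are
recorded and excluded by default (`include_ref_mismatch = TRUE` to keep
them): a homologous mutation is ill-defined where the ancestral base
already changed.

The packaged ortholog fixture (`synthetic_ortholog_pair()`) is a
code-generated synthetic stand-in that reproduces the real coordinate
geometry (human ATP6 at 8527–9207, mouse at 7927–8607, both with the
focal T at in-gene position 467, i.e. human m.8993 / mouse m.8393) with
~92% gene-body identity and a strand-reversed ND6 pair containing a
length difference. Users with the real references can run the same code
path on them unchanged.

## The simulator and its defaults

`sim_config()` encodes the emulated study conditions; the defaults are
fixed and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 16299 bp | mouse mtDNA length |
| `generation_count` | 0 (G1) / 10 (G≥10 preset) | maternal transmissions through mutator dams |
| `mu_germline` | wt 0.1, het 0.1, hom 80 | new germline point mutations per transmission |
| `bottleneck_size` | 20 | effective segregating mtDNA copies per transmission |
| `selection_s` | 0 | per-generation transmission penalty on non-synonymous variants |
| `mu_somatic` | wt 2, het 2, hom 300 | organ-private somatic mutations |
| `somatic_freq_mean` | 0.02 | mean somatic heteroplasmy (truncated exponential) |
| `indel_fraction` | 0.02 | share of new mutations that are 1-bp indels |
| `depth_mean` | 2000× | Poisson read depth per site |
| `error_rate` | 0.004 | per-base-call error probability |

Rationale. The error floor `100·e` puts wild-type samples at ~0.4%
total frequency, inside the 0.3–0.7% band wild-type organs show in this
assay. The homozygous germline rate and bottleneck were chosen so that
ten transmissions add ≈ `10 × 80 / 20 = 40` heteroplasmy units
(≈ 0.25%), bringing the homozygous mutator total to ≈ 0.67%, about 1.7×
wild type — the upper end of the reported mutator excess — while
producing germline variants above 10% heteroplasmy only in
multi-generation lines, as observed. The heterozygote germline rate
defaults to the wild-type rate because heterozygous dams empirically
transmit wild-type-like mtDNA; the mechanism is unresolved, so the rate
is an explicit parameter rather than an assumption baked into the code.
`selection_s` defaults to 0 because non-synonymous variants demonstrably
accumulate past the germline filter at these frequencies; the parameter
exists (with a tested monotonicity property) for sensitivity analyses.
The indel share keeps realized indel frequencies far more than 40-fold
below point-mutation frequencies. A transition bias toggle exists but
defaults to off: no mutation spectrum is imposed.

Model structure. Germline drift is a single effective bottleneck per
transmission: each variant's heteroplasmy is resampled as
`Binomial(N_b, h)/N_b`; new mutations enter at `1/N_b` (one copy among
the segregating units — the minimal non-arbitrary choice). Variants
drifting to 0 are lost; variants fixing at 1 become reference
replacements of that maternal line and leave the heteroplasmic variant
set (they are kept in `attr(, "fixed")` for inspection). Selection, when
enabled, down-weights a non-synonymous variant's frequency to
`h(1-s)/(1-sh)` before resampling. Somatic variants are drawn per organ
on top of the shared germline set, with truncated-exponential
heteroplasmies — a one-parameter law that yields the observed
many-low/few-high pattern; no somatic frequency law is claimed by the
data this emulates. Sequencing is Poisson depth with uniform base-flip
errors; indel-supporting reads follow the count-table conventions above.

Reproducibility: all randomness flows from one root seed through named
substreams per stage, mouse, and organ (`substream` hashing), so cohorts
are reproducible regardless of organ order, and a G1/G≥10 contrast with
a shared seed differs only in the germline stage.

What the simulator does **not** emulate: read-level artifacts (mapping
error, strand bias, quality-dependent errors, NUMT contamination),
mtDNA copy-number dynamics, large deletions, paternal leakage, and any
intracellular population dynamics beyond the effective bottleneck.
Passing recovery tests on simulated cohorts therefore validates the
estimator arithmetic and the pipeline plumbing — not robustness to
real-data artifacts, which the upstream pileup generation must handle.

## Group comparison

`tukey_kramer()` runs the all-pairs comparison after a one-way ANOVA:
pooled error mean square with `N − k` degrees of freedom, pairwise
studentized-range statistics with the Kramer unequal-`n` adjustment, and
p-values from the studentized-range distribution (`ptukey`). For `k = 2`
the studentized range equals `√2·|t|` exactly, so the p-value is
computed through the t distribution — the same quantity at better
numerical accuracy. Reported group dispersions are sample standard
deviations (`n − 1`), the convention behind "mean ± SD" at `n = 4`. No
multiplicity correction is applied across organs or metrics beyond
Tukey–Kramer within each panel, matching per-panel testing practice.
The suite checks the `k = 2` t-test identity to 1e-9, agreement with a
direct double-integral evaluation of the studentized-range distribution
to 1e-6, and the familywise type-I error rate (0.05 within Monte-Carlo
error over 2000 null cohorts).

The clonal-expansion helpers connect histochemistry to bulk sequencing:
if a fraction `c` of cells (e.g. the COX−/SDH+ fraction) carries a
variant at within-cell heteroplasmy `h`, bulk tissue reads out
`100·c·h` percent (`expected_bulk_frequency()`; 38% of cells at 50%
heteroplasmy → 19%). The inverse (`detectable_heteroplasmy()`) caps at
1 with an infeasibility flag — a bulk frequency above `100·c` cannot be
explained by any heteroplasmy confined to that cell fraction.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere internally ("m.8993"
  style); BED input is converted on read. Annotations may not wrap the
  origin: no mouse mitochondrial gene spans it, and linear intervals
  keep the logic simple.
* Count tables must satisfy `A + C + G + T = depth` per row; readers
  reject violations rather than coercing. Positions absent from a count
  file are filled as zero-depth rows (and therefore drop out of the
  statistic).
* No default depth floor is applied — filtering silently would bias the
  statistic; a threshold is available where variants are counted.
* The `(1,10]` histogram bin is left-open: a variant at exactly the
  threshold does not count, consistent with the strict "exceeds"
  convention.
* Ties in the alignment dynamic program are resolved by
  `Biostrings::pairwiseAlignment()`'s deterministic traceback; at
  ortholog identity levels the optimum is unique (tested), so the
  tie-break never decides a mapping that matters.

## Problem sizes used by the tests

The packaged suite simulates at full genome length (16,299 bp) and
2000× depth where recovery precision is the point, and at reduced sizes
(150–6000 bp genomes, tens of replicates) for distributional and
property checks; the acceptance script runs a 12-mouse single-organ
cohort at full size plus 100 paired generation-contrast replicates.
These sizes give Monte-Carlo standard errors comfortably below the
tested tolerances while keeping a laptop run in minutes.

## Known limitations

* The pipeline starts from allele-count tables; pileup construction
  (mapping and base-quality filtering, NUMT avoidance) is upstream and
  unspecified here — two pipelines with different pileup filters will
  legitimately disagree at the error-floor level.
* Heteroplasmy calling applies no error-correction model; at the
  default floor, variants below ~0.01% per site are indistinguishable
  from noise, which is why thresholded counts use 1%.
* The indel model is 1-bp events only; large deletions, common in some
  mutator phenotypes, are out of scope.
* `cohort_report()` compares groups per organ and metric; it does not
  model organ or mouse as random effects.
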