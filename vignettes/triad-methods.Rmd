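---
title: "Triad construction and its background models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triad construction and its background models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadr)
library(dplyr)
```

## The problem

All-to-all RNA–chromatin interactome protocols (RADICL-seq, GRID-seq,
Red-C) ligate RNAs to nearby chromatin and sequence the chimeras. The
resulting contact lists are dominated by two noise sources: contacts of
abundant protein-coding transcripts with no regulatory role, and a steep
decline of contact density with genomic distance from the source gene
("RD-scaling", approximately a power law), produced by nascent transcripts
and diffusion from the transcription site. Peak callers suppress part of
this, but an individual surviving contact still carries little evidence of
function.

`triadr` adds orthogonal evidence: if a protein binds both the RNA (a
RIP/fRIP/eCLIP peak on the transcript) and the DNA locus (a ChIP-seq peak),
the contact is far more plausibly protein-mediated. The intersection of the
three interval datasets is the *triad*.

## The assembly rule and its parameters

`build_triads()` emits a triad for contact *c* and protein *P* iff

1. the DNA part of *c* intersects an extended ChIP peak of *P* by at least
   `min_overlap` bp, and
2. the RNA part of *c* intersects an extended protein–RNA peak of *P*
   annotated to the same gene by at least `min_overlap` bp.

Tunable parameters, all surfaced as function arguments and pipeline config
fields:

| parameter | default | units | rationale |
|---|---|---|---|
| `pd_ext` | 2000 | bp/side | restriction sites occur roughly every 256 bp; ±2 kb recovers ligation offsets between the observed and true contact locus |
| `pr_ext` | 100 | bp toward 3′ | the RNA 3′ end is what ligates to DNA; extension is strand-aware (`end` on `+`, `start` on `−`) |
| `min_overlap` | 19 | bp | below ~19 bp most intersections are incidental adjacency of dense interval sets rather than co-location |
| `ratio_related` | 0.8 | fraction | the 4:1 related:unrelated resampling ratio of the protein–RNA null |
| `n_reps` | 10000 | replicates | full-scale null; desk-scale runs use 200 |

When several peaks on a side satisfy the threshold, the one with maximal
overlap is recorded, ties broken by smaller start coordinate. This makes
output deterministic for fixed input, which we prioritise over any attempt
to weight multiple supporting peaks.

Each triad's significance summary is the harmonic mean of the three peak
q-values (HMQ). The harmonic mean is dominated by its smallest element, so
one highly significant peak cannot be washed out by two marginal ones, yet
`min(q) ≤ HMQ ≤ max(q)` always holds (asserted in the test suite).

RNA identity matching on the protein–RNA side uses annotated gene IDs, not
raw genomic overlap alone: protein–RNA peaks arrive annotated to genes, and
gene IDs are the stable join key across datasets.

## Coordinates and labels

All coordinates are 0-based half-open (BED convention); readers pass BED
files through unchanged and the narrowPeak reader converts `-log10(q)` from
column 9. Interval overlap of half-open intervals is
`max(0, min(ends) − max(starts))`, zero across chromosomes; abutting
intervals share nothing.

A peak's compartment or state label is defined by the label of the track
interval containing its midpoint. The midpoint rule is stable under the
symmetric peak extensions used everywhere, and avoids double-labelling
peaks that straddle a boundary. Track gaps get the reserved label `"."` and
are excluded from enrichment denominators.

## The two permutation nulls

The question the background model answers: would this many triads arise if
the protein's binding tracks had no relationship to the contacts? Contacts
themselves are never shuffled — RD-scaling and chromatin-accessibility
biases make any contact randomisation unfaithful — so both protein tracks
are randomised around the fixed contacts.

**ChIP shift.** One signed shift per chromosome per replicate, magnitude
uniform on {1, 3, 5, 7, 10} Mb, sign uniform, applied with toroidal wrap at
chromosome ends (wrap conserves peak count where truncation would not).
The A/B compartment annotation of every peak is preserved: open chromatin
is over-represented in interactome data, and destroying the compartment
profile would make the null trivially easy to beat. A peak whose shifted
midpoint lands in the opposite compartment is relocated to the nearest
same-type compartment interval — placed fully inside it when it fits
(start clamped to `[a, b − width]`), midpoint-centred with overhang when
the interval is narrower than the peak, ties broken toward the smaller
coordinate. Chromosomes shorter than every magnitude fall back to the
wrapped draw; chromosomes lacking a required compartment type keep the
wrapped position with a warning. The suite asserts exact conservation of
peak count, widths, chromosome assignment and per-peak labels over 20
seeds.

**Protein–RNA resample.** Proteins are represented by their RNA
repertoires; distance is one minus the Jaccard index of repertoires. For
each target protein the "related" pool is the closest tercile of the other
proteins (plus the protein itself) and everything else is "unrelated"; per
biotype with `n_b` original peaks, `round(0.8·n_b)` are drawn with
replacement from the related pool and the remainder from the unrelated
pool. Output size and biotype histogram equal the original exactly, and at
most 20% of peaks (plus less than one peak of rounding slack per biotype)
come from unrelated proteins. A pool lacking a biotype donates its quota to
the other pool with a warning.

The phrase "top third of all distances" admits two readings; relatedness
built from *smallest* distances is the only one under which the related
pool consists of proteins sharing many RNA partners, so the closest tercile
is the default, with `side = "farthest"` available for the literal reading.

The empirical p-value is the add-one permutation estimator
`(1 + #{sim ≥ obs}) / (n_reps + 1)`, which is never zero and is the
standard finite-sample-valid choice.

## Downstream statistics

* **cis/trans shift** (`cis_trans_shift_test()`): per-RNA trans fractions
  before and after filtering, compared by a two-sided Wilcoxon signed-rank
  test, exact when magnitudes are untied, zero differences dropped. The
  pairing unit is the RNA; per-chromosome pairing is conceivable but the
  RNA is the biological unit whose contact repertoire the filter changes.
* **RD-scaling weights** (`scaling_weights()`): distance is from the
  DNA-part midpoint to the nearest gene edge (zero inside the gene), binned
  geometrically (default 1 kb → 100 Mb, factor 2, plus a leading [0, 1 kb)
  bin). The weight `N/(L·ΣN)·1e9` is a per-bp density rescaled so that
  `Σ weight·L = 1e9` identically — an algebraic conservation asserted on
  random inputs.
* **State enrichment** (`state_distribution()`, `chisq_state_test()`): the
  expected proportions come from the protein's own ChIP peak distribution,
  so the test asks whether triad construction *re-weights* the protein's
  loci, not whether the protein prefers certain states. Expected categories
  below 5 merge into `"other"` (standard χ² validity rule). Both
  count-weighted (midpoints; default for testing) and bp-weighted modes are
  provided, since either weighting of DNA parts is defensible.
* **Specificity** (`common_specific_split()`, `fisher_specificity()`):
  RNAs in triads with ≥20 distinct proteins are "common"; the 2×2 table of
  specific/common × ChIP-overlap/no-overlap is tested two-sided by Fisher's
  exact test, degenerate margins returning p = 1 with a warning.
* **Fold change** (`pr_fold_change()`): the 0.01 pseudo-count is added to
  the count *fractions*, not the raw counts — the reading that keeps the
  ratio dimensionless, bounded, and equal to 1 for genes absent from both
  replicates.
* **Cross-protocol consistency** (`cross_experiment_consistency()`):
  kernel-based track correlation is out of scope here, so consistency uses
  a transparent substitute: DNA parts extended ±500 kb, 10-kb binned
  coverage, centered 50-bin sliding Pearson windows, consistency threshold
  0.5 — all configurable. This is *not* equivalent to kernel correlation;
  it identifies the same qualitative objects (regions where both coverage
  tracks co-vary) with simpler, testable semantics. Zero-variance windows
  have no defined correlation and are skipped. Percentages print with
  round-half-even to two decimals and trailing zeros trimmed.

## The synthetic generator

`synth_generate()` emulates the structure the method assumes: alternating
A/B megabase compartments; block-sampled grouped chromatin states;
an mRNA-dominant RNA roster (default 70% mRNA); cis contact distances drawn
with density ∝ d^−α (α = 1 by default — the decline is well attested, its
exponent is not, so the flattest power law is the conservative choice) and
trans contacts uniform elsewhere; ChIP peaks placed with 2× per-bp odds in
A; q-values uniform on (0.001, 0.05). Planted triads place a contact, a
covering ChIP peak, a covering protein–RNA peak and a covering RNA–DNA
peak in mutual overlap ≥19 bp by construction, recorded in a truth table.
With `noise = FALSE` only planted support is emitted, so the pipeline must
reproduce the truth table exactly (recall = precision = 1, asserted over a
20-seed sweep).

What the generator does **not** emulate: peak-caller artefacts, replicate
structure, chromatin-accessibility bias of the contacts themselves,
read-level noise, biotype-specific contact behaviour, and realistic
chromosome size heterogeneity. Passing tests therefore demonstrate the
correctness and calibration of the *pipeline machinery*, not performance
on real interactome data.

## Numerical choices and degenerate inputs

* Peak relocation and midpoints use integer rounding (round-half-even);
  relocated peaks are re-clamped to chromosome bounds.
* `filter_rd_by_peaks()` attaches the q-value of the best-overlapping
  RNA–DNA peak; contacts entering `build_triads()` without a `q_bardic`
  column get 1, keeping HMQ defined and conservative.
* Empty peak lists, empty pools, empty margins, zero-variance windows and
  gap midpoints all have defined behaviour (identity, fallback with
  warning, p = 1, skip, default label) rather than errors, except where an
  error is the only honest answer (unknown chromosome, unstranded 3′
  extension, q ≤ 0, trans contact in a scaling computation).
* Jaccard similarity of two empty RNA sets is 0 by convention (logged).

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
genomes of a few 20-Mb chromosomes, tens of proteins, hundreds to a few
thousand peaks and contacts, 200 null replicates where the full method
would use 10 000. These sizes exercise every code path (including
compartment relocation and pool fallbacks) while keeping the whole suite
in the low minutes; all thresholds, extensions and ratios are identical to
the full-scale defaults.

## Known limitations

* The windowed-correlation consistency measure is a stated substitute for
  kernel track correlation, with different edge behaviour near chromosome
  ends.
* The relocation rule concentrates peaks at compartment boundaries when
  shifts frequently cross compartments; with megabase compartments and
  megabase shifts this affects a small minority of peaks per replicate.
* Ties in the protein distance matrix make the related tercile inclusive
  (every protein at the threshold distance is related); with saturated RNA
  repertoires (every protein binding every RNA) the unrelated pool is
  empty and the resample degenerates to related-only draws, with warnings.
* Ortholog conservation, peak calling, and segmentation model training are
  out of scope; their outputs are inputs here.
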