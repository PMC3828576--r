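---
title: "Methods: windowed analysis of protein disorder, recombination and G+C content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed analysis of protein disorder, recombination and G+C content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrscape)
```

## The quantities and the model

`idrscape` works at two resolutions. Per protein, a disorder predictor has
already assigned each residue a binary call; a **disordered segment** is a
maximal run of disordered calls, and only segments of length L ≥ 30
residues count in genome-scale statistics — shorter runs are structural
loops rather than bona fide disordered regions, and every threshold in the
package defaults to this value (`min_len = 30`) while remaining settable.
Per genome window, four aggregates are formed: the segment frequency
(L ≥ 30 segments per ORF), the disordered-residue frequency (residues
inside such segments over all residues of the window's ORFs), the
G+C_disordered frequency (G+C bases under those segments over total gene
length), and the recombination rate in cM/Mb.

The statistical layer treats windows as sampling units. Pearson
correlations relate any two window statistics, with the p-value from the
usual t transform `t = r * sqrt((n-2)/(1-r^2))` and the figure-band
convention `***`/`**`/`*` for p < 0.005 / 0.01 / 0.05 (strict
inequalities: p = 0.005 earns `**`). The multiple regression is an
ordinary least-squares fit of disordered-residue frequency on
G+C_disordered frequency and recombination rate, evaluated by sequential
ANOVA; we use the residue-based (not segment-based) disorder response
there because it shares the per-base denominator of the G+C predictor.
Both statistic families are first-class outputs since the windowed
correlation figures use segment frequency while the regression uses
residue frequency. Spatial non-independence of adjacent windows is
deliberately not modelled; p-values are nominal in that respect.

Key assumptions: one protein per gene (inputs must be pre-collapsed to a
single transcript); strand never enters any statistic; all coordinates are
converted once, on reading, to 0-based half-open intervals, so interval
arithmetic carries no ±1 bookkeeping.

## Domain-relative classification

Disordered residues of proteins that carry at least one annotated
structural domain are labelled `in_domain`, `linker` (between two
domains), `nterm` (before the first domain) or `cterm` (after the last).
Three choices here were genuinely open and are fixed as follows:

- **Overlapping domain annotations are merged** (union) before
  classification, so no residue is counted twice.
- **Classification is per residue, not per segment**: a segment spanning a
  domain boundary contributes residues to both classes.
- **Double normalisation** in the summary table: in-domain/outside
  percentages are fractions of *all* disordered residues, while the
  linker/N-term/C-term trio are fractions of the *outside-domain*
  disordered residues, so each trio sums to 100% on its own. This is the
  only reading under which such per-chromosome tables are internally
  consistent.
- By default **all** disordered residues are classified, not only those in
  L ≥ 30 segments; the `min_seg_len` argument of
  `classify_disordered_residues()` restricts to long segments for the
  alternative reading. The L ≥ 30 filter always applies to window and
  conservation statistics.

## Paralogue conservation and location classes

A pair of homologous proteins "conserves disorder" when both members have
the same number of L ≥ 30 segments — strict equality, since disorder is
gained or lost segment-wise; `count_tolerance` relaxes this if desired.
Pairs are stratified by the chromosomal position of their *anchor* member
(the member with a locus on the analysed genome): class A within a 0.5 Mb
centromeric window (`centromeric_radius = 250` kb each side), class B
within the proximal quarter of the arm measured from the window edge
(`proximal_fraction = 0.25`), class C beyond. The B/C boundary has no
canonical value; 0.25 was chosen once as a reasonable arm split and is
exposed as a parameter. Centromere positions are a required input — they
are genome metadata the package cannot infer.

## G+C partitioning and the enrichment test

Per gene, `gc_total` counts G+C over the whole CDS, `gc_disordered` over
the nucleotides spanning L ≥ 30 segments (residue *i* maps to nucleotides
`3i..3i+2`; a trailing stop codon is always ordered), and
`gc_ordered = gc_total − gc_disordered` exactly. The G+C_disordered
frequency divides by the **CDS nucleotide length** — the natural
denominator for a base count. `N` bases count as non-GC. Genes whose CDS
is neither 3L nor 3L+3 nucleotides are excluded with a warning rather than
failing the run, since real annotations contain glitches.

The enrichment test contrasts, per gene, the G+C percentage of the
disordered region with that of the ordered region. The default is a
**paired** Student's t on the per-gene differences — the two regions come
from the same gene, so pairing is the statistically natural choice — with
`paired = FALSE` available. A Shapiro–Wilk statistic on the differences is
reported alongside as the normality check; it never gates the test. When
every difference is zero the test degenerates to t = 0, p = 1 by
convention. Cohort-level G+C tables are emitted in both possible readings
(per-gene means and pooled base counts) by `gc_summary()`.

## Windows, assignment and dispersion

Fixed windows tile each chromosome at 0.5 Mb (last window truncated); map
windows coincide exactly with the genetic-map fragments, which is the mode
used whenever recombination enters, and map fragments are taken at face
value from the input with no size assumption. A gene belongs to the unique
window containing its midpoint `floor((start+end)/2)` — midpoint
assignment avoids double-counting boundary-spanning genes, and the
half-open convention sends a midpoint sitting exactly on a boundary to the
upper window. Windows with zero genes have undefined (not zero)
frequencies and are excluded from correlations and regressions: a 0/0
segment frequency is not evidence of anything.

The index of dispersion is the variance-to-mean ratio of **counts of
disorder-carrying genes per fixed 0.5 Mb window**, per chromosome. A
literal variance/mean of base-pair coordinates is dimensionally unusable;
counts per window are the standard dispersion test for spatial
randomness (VMR = 1 under Poisson placement, > 1 when clustered).

Annotation-term enrichment uses the one-sided hypergeometric upper tail
per term with Bonferroni correction by default (the conservative choice
when "corrected p-values" are reported without a method), Benjamini–
Hochberg selectable.

## The synthetic generator

`simulate_bundle()` emits a complete input bundle — protein and CDS FASTA,
mask FASTA, domain TSV, GFF3 loci, genetic map, centromeres, pair list —
plus the ground truth that generated it. The generative chain is:

1. per-window genetic length cM ~ Gamma(shape 2, scale 2), one window
   designated a hotspot per chromosome (×5);
2. per gene, the number of long disordered segments ~
   Poisson(λ₀ + β_rec · rate) with λ₀ = 0.3 segments and β_rec = 0.05
   segments per cM/Mb; segment lengths are 30 + Geometric(mean 20) —
   only the ≥ 30 threshold matters downstream, so the tail shape is a
   free choice; segments are placed with at least one ordered residue
   between them so emitted runs are exactly the intended maximal runs,
   and short (< 30) disordered loops are sprinkled into ordered stretches
   for realism;
3. disordered residues are drawn from the disorder-prone alphabet
   {R, G, A, P} with GC-maximal codons at a rate calibrated so per-gene
   G+C rises by δ_gc = 0.08 per unit disordered fraction; ordered
   residues draw uniform amino acids with codons mixed to hit a baseline
   G+C of 0.45, jittered per gene (sd 0.03) so the disorder–G+C relation
   is noisy rather than mechanical;
4. paralogue partners duplicate the anchor's mask with a location-class-
   dependent probability (0.85 centromeric, 0.65 on arms), else gain or
   lose exactly one long segment.

Setting β_rec = 0 and δ_gc = 0 yields an exact null in which disordered
and ordered residues are identically distributed.

The default genome is 2 chromosomes × 6 Mb = 24 windows of 0.5 Mb with 50
genes each (1200 genes, mean protein 300 residues) — large enough for the
windowed statistics to stabilise, small enough that a full
simulate-plus-analyse cycle takes ~2 s, so the test suite runs 100-seed
ensembles and the acceptance script 50-seed ensembles comfortably.
Conservation recovery uses 5000 pairs, where the binomial standard error
on a 64% rate is ~0.7%.

What the generator does *not* emulate: gene structure (no introns, UTRs or
alternative transcripts), sequence evolution, realistic domain/disorder
co-placement, interpolated recombination between map fragments, and — most
importantly — the noise level of real predictors. Real disorder calls and
real maps are far noisier, so windowed correlations on real genomes are
much weaker than the near-deterministic couplings recovered from the
simulator (pipeline r ≈ 0.98, regression r² ≈ 1 under defaults). Passing
tests therefore demonstrate correctness of the machinery and calibration
of its null, not the effect sizes to expect from real data.

## Numerical and degenerate-input conventions

- Readers are strict: duplicate FASTA IDs, non-contiguous `.diso`
  numbering, unknown mask symbols or strand characters, overlapping map
  intervals and negative cM are errors naming the offender; touching
  half-open map intervals are legal.
- Pearson correlation refuses n < 3 or zero-variance input by name;
  regression refuses rank-deficient designs and n ≤ 3.
- Shapiro–Wilk inputs are subsampled to 5000 values (the statistic's
  implementation limit); diagnostics are always reported, never used to
  drop results.
- Ties and duplicated values in correlation inputs are kept as-is.
- A genome-level "average r" is ambiguous (mean of per-chromosome
  coefficients vs pooled windows); `correlate_windows()` emits both rows.

## Known limitations

Window statistics ignore spatial autocorrelation, so nominal p-values are
anti-conservative for closely linked windows. The conservation score
compares segment *counts* only, not positions or lengths. The regression
inherits collinearity between the G+C_disordered frequency and the
disorder response — both scale with disordered content — which is
intrinsic to these variable definitions and is why the recombination term
should be interpreted only after the G+C term (sequential ANOVA order).
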