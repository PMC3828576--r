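# idrscape

Chromosomal landscapes of intrinsic protein disorder, genetic recombination
and G+C content.

## The problem

A sizeable fraction of plant proteins carry **intrinsically disordered
regions** — stretches of residues with no stable three-dimensional
structure. Long disordered segments (≥ 30 contiguous disordered residues)
are not uniformly scattered across a genome: their frequency along
chromosomes tracks the local **meiotic recombination rate** (cM/Mb from
empirical genetic maps) and the **G+C content** of the encoding genes,
plausibly because GC-biased gene conversion at recombining sites favours
the GC-rich codons of disorder-prone amino acids (Arg, Gly, Ala, Pro).
`idrscape` is a toolkit for quantifying these relationships in any genome
for which you have per-residue disorder predictions (e.g. DISOPRED-style
output), gene coordinates, a genetic map, domain annotations and
paralogue/orthologue pair lists.

The core quantities, per genome window *w* (either fixed 0.5 Mb tiles or
the empirically mapped chromosome fragments):

- **segment frequency** — number of disordered segments of length L ≥ 30
  over the number of ORFs in *w*;
- **disordered-residue frequency** — residues inside such segments over all
  residues of the ORFs in *w*;
- **G+C_disordered frequency** — G+C bases spanning the disordered segments
  of a gene over the gene length, summed over *w*;
- **recombination rate** — genetic length of the map fragment divided by
  its physical size (cM/Mb).

On top of these the package provides: per-residue classification of
disorder relative to annotated structural domains (in-domain / linker /
N-terminal / C-terminal); conservation of disordered-segment counts across
paralogue pairs, stratified by distance from the centromere (classes A/B/C);
the three-way G+C partition G+C_total = G+C_disordered + G+C_ordered with a
paired *t* enrichment test; Pearson correlations with the `***`/`**`/`*`
significance bands (p < 0.005 / 0.01 / 0.05); variance-to-mean dispersion
indices of disorder-carrying genes; an OLS multiple regression of disorder
on G+C and recombination with sequential ANOVA and residual diagnostics;
and hypergeometric annotation-term enrichment.

Because the real inputs are bulky external datasets, the package ships a
**synthetic-genome simulator** (`simulate_bundle()`) that emits every input
file format with known ground-truth couplings, so the entire pipeline is
testable end to end.

## Worked example

```r
library(idrscape)

bundle <- simulate_bundle(simulation_config(seed = 1))
res <- run_analysis(bundle)
res
#> idrscape analysis
#>   2152 disordered segments across 24 windows
#>   segment frequency vs recombination: pooled r = 0.988 (***)
#>   conservation: 66.7% of 1000 pairs
#>   G+C enrichment of disordered regions: +8.20% (p = 0)
#>   regression r^2 = 1.000 (gc p = 1.31e-38, rec p = 0.147)

res$correlations$disorder_vs_rec
#> # A tibble: 4 × 5
#>   chromosome              r     n         p stars
#>   <chr>               <dbl> <int>     <dbl> <chr>
#> 1 chr1                0.988    12  1.87e- 9 ***
#> 2 chr2                0.989    12  1.10e- 9 ***
#> 3 pooled              0.988    24  1.67e-19 ***
#> 4 mean_of_chromosomes 0.989    24 NA        <NA>

generics::tidy(res$regression)
#> # A tibble: 3 × 6
#>   term         estimate std.error statistic  p.value   anova.p
#>   <chr>           <dbl>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 (Intercept) -0.000437  0.00132     -0.331 7.44e- 1 NA
#> 2 gc           1.95      0.0402      48.5   4.76e-23  1.31e-38
#> 3 rec         -0.000239  0.000159    -1.50  1.47e- 1  1.47e- 1
```

Reading the output: the simulated genome couples the expected number of
long disordered segments per gene to the window recombination rate
(`beta_rec = 0.05` segments per cM/Mb by default) and the gene G+C to its
disordered fraction (`delta_gc = 0.08`), and the pipeline recovers both —
a strongly positive windowed correlation between segment frequency and
cM/Mb, and a regression in which the G+C term carries the signal while the
recombination term adds nothing once G+C is in the model. Conservation:
86.7% of centromere-proximal (class A) pairs keep their segment count
versus ~65% on the arms, matching the class-dependent generating
probabilities (0.85 / 0.65 / 0.65). Per-chromosome variance-to-mean ratios
of disorder-carrying genes per 0.5 Mb window are ~3, i.e. clustered, not
Poisson.

Real data enter through the readers: `read_protein_fasta()`,
`read_cds_fasta()`, `read_disorder_masks()` (DISOPRED `.diso` or a
two-symbol mask FASTA), `read_domains()`, `read_gene_loci()` (GFF3 or TSV),
`read_genetic_map()`, `read_pairs()`, `read_centromeres()` — assemble their
outputs into a list with the same element names as a simulated bundle and
call `run_analysis()`, or call the stage functions directly.

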