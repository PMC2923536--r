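# tillingr

Design and evaluation of TILLING (Targeting Induced Local Lesions In
Genomes) reverse-genetics screens on EMS-mutagenized plant populations.

EMS (ethyl methane sulfonate) alkylates guanine at the O6 position, so it
induces almost exclusively G:C→A:T transitions. That single chemical fact
drives everything a screen designer needs to know:

* **Which coding changes are reachable.** On the sense strand every lesion
  reads as G→A or C→T, so only 96 of the 64×3 codon positions of the
  standard genetic code can mutate at all (8 codons contain no G or C).
  `tillingr` enumerates all 96 changes and classifies each as silent,
  mis-sense or nonsense; `profile_cds()` does the same along any coding
  sequence so the amplicon window with the most stop-codon potential can be
  chosen.
* **How dense the mutations are.** A screen of *N* plants over an amplicon
  of *L* bp yielding *m* mutations estimates one mutation per
  *L·N/m* bp, conventionally rendered "1/X kb". Because EMS hits only G/C
  sites, density scales with GC content:
  `bp_norm = bp · GC_amplicon / GC_reference` puts assays of different GC
  on a common footing, and genome size over bp-per-mutation extrapolates
  the per-plant mutation load.
* **What a screen will return.** With *E* mutations expected in the
  screened fragment and a fraction *f* of mutable coding positions giving
  stops (*f* = 5/96 under the census), the chance of recovering at least
  one nonsense allele is `1 − (1 − f)^E`. Summing per-plant loads over the
  population and dividing by the genome's G/C site count gives the
  saturation — the fraction of mutable sites segregating somewhere in the
  population — and `0.5^g` tracks load decay over backcross generations.
* **Whether the estimators can be trusted.** A forward simulator
  (`mutagenize_population()`, `detect_screen()`, `recovery_experiment()`)
  draws an M2 population with per-G/C-site Bernoulli mutations, a
  configurable heterozygous:homozygous ratio, 8-fold one-dimensional
  pooling and reduced detection near amplicon ends, so every estimator is
  validated by parameter recovery against known truth.

## Worked example

The package ships the raw columns of eight TILLING assays on a *Brassica
rapa* M2 population (six amplicons screened at 0.3% EMS, two at 0.4%):

```r
library(tillingr)

print(code_spectrum())
#> EMS mutation spectrum of the standard genetic code
#>   codons unaffected (no G/C): 8 of 64 (12.5%)
#>   mutable G/C positions:      96
#>     silent:    33
#>     mis-sense: 58 (26 distinct substitutions, 9 at conservative sites)
#>     nonsense:   5

summarize_assays(example_assays())
#> TILLING assay summary (normalized values at 35% genome GC / 41% exon GC)
#>         gene ems_pct length_bp gc_pct mutations screened  load load_norm density density_norm expected_per_kb expected_per_kb_norm
#>   BraA.RPL.a     0.3      1007     47        21      768 13577     10111    1/37         1/49             188                  164
#>   BraA.RPL.b     0.3      1072     45       149     4608 15082     11730    1/33         1/43             208                  190
#>   ...
#>
#> Dose-group averages:
#>  ems_pct n_assays  load load_norm density density_norm expected_per_kb expected_per_kb_norm
#>      0.3        6 12814      9693    1/44         1/56             177                  157
#>      0.4        2 10106      7717    1/51         1/67              47                   42
```

Reading the 0.3% row block: the six assays average one mutation per 44 kb
raw (1/56 kb after normalization to the 35% GC genome average), which over
a 500 Mbp genome means ~12,800 mutations per plant (~9,700 normalized).
Design quantities follow directly:

```r
p_at_least_one_nonsense(68.2)                      # 0.974 — a 68.2-mutation
                                                   # screen almost surely
                                                   # yields a stop allele
saturation_fraction(c(9693, 7717), c(6912, 2304))  # 0.484 — about half of
                                                   # all genomic G/C sites
                                                   # mutated in the population
backcross_load(10000, 10)                          # 9.77 — ten backcrosses
                                                   # reduce the load to ~10
```

A command-line driver wraps the same functions
(`inst/scripts/tilling-cli.R`): `spectrum`, `profile`, `density`, `design`,
`saturation`, `backcross`, `simulate`, `recover`.

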