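---
title: "EMS mutation spectra, screen design and simulation-based validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMS mutation spectra, screen design and simulation-based validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillingr)
```

## The model

TILLING screens recover point mutations in a gene of interest from a
chemically mutagenized population. `tillingr` models the whole chain for
EMS mutagenesis in a diploid plant population:

1. **Mutation chemistry.** EMS alkylates the O6 position of guanine, which
   mispairs on replication; essentially all induced changes are G:C→A:T
   transitions. We adopt this as exact: the simulator never mutates an A/T
   site, and the genetic-code census considers only G→A and C→T changes on
   the sense strand. An antisense lesion (C→T on the other strand) is the
   same genomic event seen from the complementary strand and is not counted
   twice.
2. **Coding consequences.** Enumerating G→A/C→T at every position of all 64
   codons (standard code, translation table 1) gives 96 possible changes:
   33 silent, 58 mis-sense (26 distinct amino-acid substitutions) and 5
   nonsense. The five stop routes are the first positions of CAA, CAG and
   CGA and either G of TGG. Stop→stop changes (TAG→TAA, TGA→TAA) leave the
   product unchanged and are classed silent; this convention is required
   for the 33/58/5 partition to be a partition of 96.
3. **Density estimation.** An assay screening `screened` plants over
   `length_bp` and detecting `mutations` estimates
   `bp_per_mutation = length_bp * screened / mutations`. Zero detected
   mutations make the density undefined and raise a classed error rather
   than returning infinity.
4. **GC normalization.** Since only G/C sites mutate, expected mutations
   per bp are proportional to GC content, so
   `bp_norm = bp * gc_from / gc_to`. This is exact under the per-site
   model, and is what makes assays on 41–48% GC amplicons comparable with a
   35% GC genome average.
5. **Design formulas.** With `E` mutations expected in a fragment and each
   independently nonsense with probability `f`, the probability of at
   least one stop allele is `1 - (1 - f)^E`; `f` defaults to the census
   value 5/96 and can be replaced by a CDS-specific fraction from
   `profile_cds()`. Population saturation is the summed mutation count
   over all plants divided by the genome's G/C site count
   (`genome_size * genome_gc / 100`); an optional Poisson occupancy
   correction `1 - exp(-lambda)` accounts for two hits landing on the same
   site. Backcross load decay is `0.5^generations`.

## Parameters and defaults

`population_constants()` fixes the extrapolation background: genome size
5×10⁸ bp, genome GC 35%, coding fraction 0.11, exon GC 41% — the values
appropriate for *Brassica rapa*, the system the packaged fixture comes
from. All are overridable per call and from the CLI.

The similarity scheme behind `conservative_sites` is a genuinely open
choice: there is no canonical partition of the amino acids into
"chemically similar" groups. We default to
{ILVM} {FYW} {KRH} {DE} {ST} {NQ} {AG} {C} {P} and expose the grouping as
an argument; under this default 9 of the 58 mis-sense sites are
conservative. Counts under any other published grouping can be obtained by
passing it in, and no downstream quantity depends on the choice.

## Rounding and table conventions

Internal values are never rounded; display rounding is half-up
(`floor(x + 0.5)`), not R's round-half-even, because screen tables in this
field are produced with spreadsheet-style rounding (e.g. a dose-group mean
load of 7716.5 prints as 7717). Two further conventions in
`summarize_assays()` exist to match how such tables are conventionally
assembled: the GC-normalized per-plant load is derived from the already
rounded raw load, and dose-group averages are unweighted means of the
rounded per-assay display values. Densities render as "1/X kb" with
X = bp/1000 rounded half-up.

The packaged eight-assay fixture stores only raw columns; every derived
cell is recomputed. Against the originally reported version of this table
our recomputation differs in three cells, which we treat as printing slips
there rather than conventions to emulate: a density of "1/358" where the
raw columns give 57,658 bp ≈ 1/58, and two expected-yield cells (209 where
the raw columns give 208.49, and 191 where they give 191.58) that no
uniform rounding rule reproduces alongside the other fourteen.

## What the simulator emulates

`sim_config()` defaults describe a desk-scale version of a high-density
M2 population:

* reference: 5 Mb i.i.d. sequence at 35% GC (1/100 of the 500 Mb genome;
  the full size is configuration, not default);
* mutation model: each G/C site mutates independently per plant with rate
  10,000/(5×10⁸ × 0.35) ≈ 5.7×10⁻⁵, so a plant's genome-equivalent load is
  ~10,000 regardless of reference scale;
* zygosity: each mutation is heterozygous with probability r/(r+1),
  r = 12.1 by default — the ratio is an *input* reproducing what M2
  screens of this type observe, not an emergent property of a simulated
  M1→M2 selfing scheme;
* pooling: one-dimensional pools of 8, each plant in exactly one pool,
  remainder plants in one short final pool (6,912 plants → 864 pools, i.e.
  nine 96-well plates);
* detection: every true mutation in the screened amplicon is detected
  independently; sensitivity is a step function — `edge_sensitivity`
  within 100 bp of either amplicon end, 1 elsewhere — because mutations
  near the primers are systematically under-called on capillary traces.
  A linear-ramp edge model and a heterozygote allele-dilution penalty are
  available but off by default: pooled heteroduplex detection shows no
  appreciable interior loss, and a homozygous mutant in an 8-pool still
  forms heteroduplex against seven wild-type lines, so both het and hom
  mutations are detectable. `calibrate_edge_sensitivity(0.2, 5/617)`
  solves the step model for the edge sensitivity (~0.033) that makes 5 of
  617 detections fall within the end zones of a 1 kb amplicon.

What it does **not** emulate: M1 raceme chimerism and sterility selection
(which plausibly shift the het:hom ratio between doses), linkage and
non-uniform local GC, nuclease biochemistry, false positives (taken as
zero), and fitness effects of the mutations themselves. Parameter-recovery
results therefore validate the estimators under the stated model, not the
wet-lab pipeline.

## Numerical and validation choices

* The load estimator recovered from a simulated assay is linear in the
  detected count and hence exactly unbiased; the bp-per-mutation estimator
  is a reciprocal and carries O(1/m) small-sample bias, so recovery checks
  compare it through pooled counts across replicates.
* Recovery truth for an amplicon is computed from the realized reference:
  `L / (n_GC_in_amplicon * rate)`, removing compositional sampling noise
  from the comparison.
* The test suite runs recovery at 5 Mb / 1,536 plants / 20 replicate
  screens of a 2 kb amplicon, with 3-standard-error acceptance bands; all
  stochastic tests fix their seeds and derive tolerances from binomial or
  Poisson counting error, never from observed spread.
* Degenerate inputs: empty assay lists, zero-mutation assays, amplicons
  without G/C sites, and ambiguity codes in CDS input all raise classed
  errors (`tillingr_input_error`, `tillingr_compute_error`) that the CLI
  maps to exit codes 3 and 4; a permissive mode skips ambiguous codons
  with a warning.

## Limitations

The census treats codon usage as uniform when converting class counts to
fractions; `profile_cds()` exists precisely because real genes deviate.
Density estimates carry no confidence intervals (the estimator's sampling
error is Poisson-dominated and amplicon-specific; the simulator is the
recommended way to quantify it for a given design). GC normalization
assumes the per-G/C-site rate is homogeneous along the genome, which
ignores local context effects on EMS alkylation.
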