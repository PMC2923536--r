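# Mutation-density estimation and screen-design arithmetic for TILLING
# assays on EMS-mutagenized populations.

#' Genome constants used for extrapolation
#'
#' Defaults describe the Brassica rapa genome: ~500 Mbp, 35% GC on average,
#' 11% coding sequence at 41% GC. Because EMS hits only G/C sites, mutation
#' density scales with GC content, and all extrapolations are made relative
#' to these reference values.
#'
#' @param genome_size Genome size in bp.
#' @param genome_gc Genome-average GC content, percent.
#' @param exon_fraction Fraction of the genome that is coding.
#' @param exon_gc Average exon GC content, percent.
#' @return A list of class `population_constants`.
#' @export
population_constants <- function(genome_size = 5e8, genome_gc = 35,
                                 exon_fraction = 0.11, exon_gc = 41) {
  if (genome_size <= 0) stop_input("genome_size must be positive")
  if (genome_gc <= 0 || genome_gc >= 100) stop_input("genome_gc must be in (0,100)")
  if (exon_fraction <= 0 || exon_fraction >= 1) stop_input("exon_fraction must be in (0,1)")
  if (exon_gc <= 0 || exon_gc >= 100) stop_input("exon_gc must be in (0,100)")
  structure(list(genome_size = genome_size, genome_gc = genome_gc,
                 exon_fraction = exon_fraction, exon_gc = exon_gc),
            class = "population_constants")
}

#' Construct a screen-assay table
#'
#' One row per TILLING assay: the raw observables from which every derived
#' quantity (density, per-plant load, expected yield) is computed.
#'
#' @param gene Gene/amplicon identifier.
#' @param ems_pct EMS dose, percent (v/v).
#' @param length_bp Amplicon length, bp.
#' @param gc_pct Amplicon GC content, percent.
#' @param mutations Mutations detected.
#' @param screened M2 plants screened.
#' @param population M2 plants in the population.
#' @return A `data.frame` of class `screen_assay_table`.
#' @export
screen_assays <- function(gene, ems_pct, length_bp, gc_pct, mutations,
                          screened, population) {
  d <- data.frame(gene = gene, ems_pct = ems_pct, length_bp = length_bp,
                  gc_pct = gc_pct, mutations = mutations,
                  screened = screened, population = population,
                  stringsAsFactors = FALSE)
  validate_screen_assays(d)
}

validate_screen_assays <- function(d) {
  req <- c("gene", "ems_pct", "length_bp", "gc_pct", "mutations",
           "screened", "population")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop_input("assay table is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  num <- setdiff(req, "gene")
  for (cl in num) {
    if (!is.numeric(d[[cl]])) {
      stop_input("assay column '", cl, "' must be numeric")
    }
  }
  if (any(d$mutations < 0)) stop_input("mutations must be >= 0")
  if (any(d$screened < 1)) stop_input("screened must be >= 1")
  if (any(d$gc_pct <= 0 | d$gc_pct >= 100)) stop_input("gc_pct must be in (0,100)")
  if (any(d$screened > d$population)) {
    stop_input("screened plants exceed population size")
  }
  if (any(d$mutations == 0)) {
    warning("assay(s) with zero detected mutations: density undefined for ",
            paste(d$gene[d$mutations == 0], collapse = ", "))
  }
  class(d) <- c("screen_assay_table", "data.frame")
  d
}

#' Base pairs screened per detected mutation
#'
#' The raw mutation-density estimator: total base pairs screened
#' (amplicon length x plants) divided by mutations detected. Conventionally
#' rendered `"1/X kb"` via [format_density()].
#'
#' @param length_bp Amplicon length, bp (vectorized).
#' @param screened Plants screened.
#' @param mutations Mutations detected; must be > 0.
#' @return Base pairs per mutation (unrounded).
#' @examples
#' bp_per_mutation(1007, 768, 21)  # 36827.4 -> "1/37"
#' @export
bp_per_mutation <- function(length_bp, screened, mutations) {
  if (any(length_bp <= 0) || any(screened <= 0)) {
    stop_input("length_bp and screened must be positive")
  }
  if (any(mutations <= 0)) {
    stop_compute("mutation density undefined: zero mutations detected")
  }
  length_bp * screened / mutations
}

#' Rescale a mutation density to a different GC content
#'
#' EMS mutates only G/C sites, so base pairs per mutation scales inversely
#' with GC content: a 47% GC amplicon overstates the density achievable in
#' 35% GC genomic background by 47/35.
#'
#' @param bp Base pairs per mutation.
#' @param gc_from GC percent at which `bp` was measured.
#' @param gc_to Target GC percent.
#' @return `bp * gc_from / gc_to`.
#' @examples
#' normalize_bp_per_mutation(36827, 47, 35)  # ~49453 -> "1/49"
#' @export
normalize_bp_per_mutation <- function(bp, gc_from, gc_to) {
  if (any(gc_from <= 0 | gc_from >= 100) || any(gc_to <= 0 | gc_to >= 100)) {
    stop_input("GC percentages must be in (0,100)")
  }
  if (any(bp <= 0)) stop_input("bp must be positive")
  bp * gc_from / gc_to
}

#' Extrapolated mutations per plant
#'
#' Genome size divided by base pairs per mutation, rounded half-up.
#'
#' @param bp_per_mut Base pairs per mutation.
#' @param constants [population_constants()].
#' @return Integer count of mutations per plant.
#' @examples
#' mutations_per_plant(36827.4)  # 13577
#' @export
mutations_per_plant <- function(bp_per_mut, constants = population_constants()) {
  if (any(bp_per_mut <= 0)) stop_input("bp_per_mut must be positive")
  round_half_up(constants$genome_size / bp_per_mut)
}

#' Expected mutation yield of a screen
#'
#' Expected number of mutations recovered when screening `n_plants` over a
#' fragment of `length_bp` at a given density.
#'
#' @param n_plants Plants screened.
#' @param length_bp Fragment length, bp.
#' @param bp_per_mut Base pairs per mutation.
#' @return Expected mutation count (real).
#' @export
expected_mutations <- function(n_plants, length_bp, bp_per_mut) {
  if (any(n_plants < 0) || any(length_bp <= 0) || any(bp_per_mut <= 0)) {
    stop_input("arguments must be positive (n_plants may be 0)")
  }
  n_plants * length_bp / bp_per_mut
}

#' Probability of recovering at least one nonsense mutation
#'
#' With `E` mutations expected in the screened fragment and each being a
#' premature stop with probability `f` (5/96 under the uniform-codon census,
#' see [expected_class_fractions()]), the chance of at least one nonsense
#' allele is `1 - (1 - f)^E`.
#'
#' @param expected_mut Expected mutation count in the fragment.
#' @param nonsense_fraction Per-mutation nonsense probability; substitute a
#'   CDS-specific fraction from [profile_cds()] for a sharper estimate.
#' @return Probability in `[0,1]`; monotone in both arguments.
#' @examples
#' p_at_least_one_nonsense(68.2)  # 0.974: the "97%" design point
#' @export
p_at_least_one_nonsense <- function(expected_mut, nonsense_fraction = 5 / 96) {
  if (any(expected_mut < 0)) stop_input("expected_mut must be >= 0")
  if (any(nonsense_fraction < 0 | nonsense_fraction > 1)) {
    stop_input("nonsense_fraction must be in [0,1]")
  }
  1 - (1 - nonsense_fraction)^expected_mut
}

#' Fraction of genomic G/C sites mutated somewhere in the population
#'
#' Population-wide saturation: the total mutation count (per-plant load
#' times number of plants, summed over sub-populations) divided by the
#' number of mutable (G/C) sites in the genome. The collision-corrected
#' mode treats hits as Poisson over sites and returns `1 - exp(-lambda)`,
#' the expected fraction of sites hit at least once.
#'
#' @param loads Per-plant mutation loads, one per sub-population.
#' @param n_plants Plants in each sub-population (same length as `loads`).
#' @param constants [population_constants()].
#' @param collision_corrected Apply the Poisson occupancy correction.
#' @return Fraction in `[0, Inf)` (naive mode can exceed 1; corrected mode
#'   is always < 1). Empty input gives 0.
#' @examples
#' saturation_fraction(c(9693, 7717), c(6912, 2304))  # 0.484
#' @export
saturation_fraction <- function(loads, n_plants,
                                constants = population_constants(),
                                collision_corrected = FALSE) {
  if (length(loads) != length(n_plants)) {
    stop_input("loads and n_plants must have equal length")
  }
  if (length(loads) == 0) return(0)
  if (any(loads <= 0) || any(n_plants <= 0)) {
    stop_input("loads and n_plants must be positive")
  }
  gc_sites <- constants$genome_size * constants$genome_gc / 100
  lambda <- sum(loads * n_plants) / gc_sites
  if (collision_corrected) 1 - exp(-lambda) else lambda
}

#' Expected exonic, amino-acid-changing and nonsense mutations per plant
#'
#' Splits a per-plant genome-wide mutation load into the expected exonic
#' share and, via the genetic-code census, the amino-acid-changing and
#' stop-introducing parts.
#'
#' @param per_plant_load Genome-wide mutations per plant.
#' @param constants [population_constants()].
#' @param spectrum [code_spectrum()] census.
#' @return Named vector `c(exonic=, aa_changing=, nonsense=)`, rounded
#'   half-up to whole mutations.
#' @examples
#' exon_budget(10000)  # 1100 exonic, 722 aa-changing, 57 nonsense
#' @export
exon_budget <- function(per_plant_load, constants = population_constants(),
                        spectrum = code_spectrum()) {
  if (per_plant_load < 0) stop_input("per_plant_load must be >= 0")
  exonic <- per_plant_load * constants$exon_fraction
  m <- spectrum$mutable_positions
  c(exonic = round_half_up(exonic),
    aa_changing = round_half_up(exonic * (spectrum$missense + spectrum$nonsense) / m),
    nonsense = round_half_up(exonic * spectrum$nonsense / m))
}

#' Residual mutation load after backcrossing
#'
#' Each backcross generation halves the background mutation load.
#'
#' @param initial_load Starting mutation count.
#' @param generations Backcross generations (>= 0).
#' @return `initial_load * 0.5^generations`.
#' @examples
#' backcross_load(10000, 10)  # ~10
#' @export
backcross_load <- function(initial_load, generations) {
  if (any(generations < 0)) stop_input("generations must be >= 0")
  if (any(initial_load < 0)) stop_input("initial_load must be >= 0")
  initial_load * 0.5^generations
}
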