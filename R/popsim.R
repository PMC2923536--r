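# Forward simulator for an EMS-mutagenized diploid M2 population with
# one-dimensional pooled screening and edge-attenuated detection. Exists so
# that every density estimator and design formula in the package can be
# validated by parameter recovery on data with known truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a high-density Brassica-type
#' TILLING population at desk scale: a 5 Mb reference (1/100 of a 500 Mb
#' genome) at 35% GC, a per-G/C-site mutation rate chosen so each plant
#' carries the equivalent of 10,000 genome-wide mutations
#' (10000 / (5e8 * 0.35) per site), a 12.1:1 heterozygous:homozygous ratio,
#' and 8-fold one-dimensional pooling. Detection is perfect by default;
#' `edge_sensitivity < 1` attenuates detection within `edge_window` bp of
#' amplicon ends (mutations near the primers are hard to call on capillary
#' traces).
#'
#' @param reference_length Reference length, bp.
#' @param reference_gc GC content of the reference, fraction in (0,1).
#' @param per_gc_site_rate Mutation probability per G/C site per plant.
#' @param n_plants Number of M2 plants.
#' @param het_hom_ratio Target heterozygous:homozygous ratio; each mutation
#'   is heterozygous with probability `r / (r + 1)`.
#' @param pool_size Plants per pool.
#' @param edge_window Width of the low-sensitivity zone at each amplicon
#'   end, bp.
#' @param edge_sensitivity Detection probability within the edge zone.
#' @param interior_sensitivity Detection probability elsewhere.
#' @param edge_model `"step"` (constant `edge_sensitivity` in the zone) or
#'   `"ramp"` (linear rise to `interior_sensitivity` across the zone).
#' @param allele_dilution If `TRUE`, heterozygous mutations are detected at
#'   half the nominal sensitivity (1 of 16 alleles in an 8-pool vs 2 of 16);
#'   off by default since pooled heteroduplex detection shows no such loss
#'   away from the fragment ends.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reference_length = 5e6,
                       reference_gc = 0.35,
                       per_gc_site_rate = 10000 / (5e8 * 0.35),
                       n_plants = 768,
                       het_hom_ratio = 12.1,
                       pool_size = 8,
                       edge_window = 100,
                       edge_sensitivity = 1,
                       interior_sensitivity = 1,
                       edge_model = c("step", "ramp"),
                       allele_dilution = FALSE,
                       seed = NULL) {
  edge_model <- match.arg(edge_model)
  if (reference_length < 1) stop_input("reference_length must be >= 1")
  if (reference_gc < 0 || reference_gc > 1) stop_input("reference_gc must be in [0,1]")
  if (per_gc_site_rate < 0 || per_gc_site_rate > 1) {
    stop_input("per_gc_site_rate must be in [0,1]")
  }
  if (n_plants < 1) stop_input("n_plants must be >= 1")
  if (het_hom_ratio < 0) stop_input("het_hom_ratio must be >= 0")
  if (pool_size < 2) stop_input("pool_size must be >= 2")
  for (s in c(edge_sensitivity, interior_sensitivity)) {
    if (s < 0 || s > 1) stop_input("sensitivities must be in [0,1]")
  }
  structure(list(
    reference_length = reference_length, reference_gc = reference_gc,
    per_gc_site_rate = per_gc_site_rate, n_plants = n_plants,
    het_hom_ratio = het_hom_ratio, pool_size = pool_size,
    edge_window = edge_window, edge_sensitivity = edge_sensitivity,
    interior_sensitivity = interior_sensitivity, edge_model = edge_model,
    allele_dilution = allele_dilution, seed = seed
  ), class = "sim_config")
}

#' Generate a random reference sequence
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Sequence length, bp.
#' @param gc GC fraction in `[0,1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return A character scalar over `{A,C,G,T}`.
#' @export
make_reference <- function(length, gc = 0.35, seed = NULL) {
  if (length < 1) stop_input("length must be >= 1")
  if (gc < 0 || gc > 1) stop_input("gc must be in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  paste(bases, collapse = "")
}

#' Mutagenize a population of M2 plants
#'
#' Each G/C site of the reference mutates independently in each plant with
#' probability `per_gc_site_rate` (G->A on the sense strand for G sites,
#' C->T for C sites; the complementary-strand lesion is the same event).
#' A/T sites never mutate. Zygosity is assigned per mutation: heterozygous
#' with probability `r/(r+1)` for `r = het_hom_ratio`.
#'
#' @param reference Reference sequence (character scalar).
#' @param config A [sim_config()]; its `seed`, if set, seeds the RNG.
#' @return A list of class `sim_population`: `mutations` (data frame
#'   `plant_id`, `pos`, `ref`, `alt`, `zygosity`), `loads` (per-plant
#'   mutation counts), `n_plants`, `gc_sites` (count of G/C positions),
#'   `reference` and `config`.
#' @export
mutagenize_population <- function(reference, config = sim_config()) {
  reference <- toupper(as.character(reference))
  if (!is.null(config$seed)) set.seed(config$seed)
  bases <- strsplit(reference, "")[[1]]
  gc_pos <- which(bases == "G" | bases == "C")
  n_gc <- length(gc_pos)
  n <- config$n_plants
  n_mut <- stats::rbinom(n, n_gc, config$per_gc_site_rate)
  pos <- unlist(lapply(n_mut, function(k) {
    if (k == 0) integer(0) else gc_pos[sample.int(n_gc, k)]
  }), use.names = FALSE)
  plant_id <- rep.int(seq_len(n), n_mut)
  ref <- bases[pos]
  alt <- ifelse(ref == "G", "A", "T")
  p_het <- config$het_hom_ratio / (config$het_hom_ratio + 1)
  zyg <- ifelse(stats::runif(length(pos)) < p_het, "het", "hom")
  structure(list(
    mutations = data.frame(plant_id = plant_id, pos = pos, ref = ref,
                           alt = alt, zygosity = zyg,
                           stringsAsFactors = FALSE),
    loads = as.integer(n_mut),
    n_plants = n,
    gc_sites = n_gc,
    reference = reference,
    config = config
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Simulated M2 population: %d plants, %d bp reference (%d G/C sites)\n",
              x$n_plants, nchar(x$reference), x$gc_sites))
  cat(sprintf("  %d mutations (mean load %.1f/plant), het fraction %.3f\n",
              nrow(x$mutations), mean(x$loads),
              mean(x$mutations$zygosity == "het")))
  invisible(x)
}

#' One-dimensional pooling of plants
#'
#' Partitions plants into consecutive pools of `pool_size`; each plant
#' appears in exactly one pool, and a remainder (if any) forms one short
#' final pool.
#'
#' @param n_plants Number of plants.
#' @param pool_size Plants per pool.
#' @return Integer vector of pool ids, one per plant.
#' @examples
#' table(pool_plants(20, 8))  # pools of 8, 8, 4
#' @export
pool_plants <- function(n_plants, pool_size = 8) {
  if (n_plants < 1) stop_input("n_plants must be >= 1")
  if (pool_size < 1) stop_input("pool_size must be >= 1")
  n_pools <- ceiling(n_plants / pool_size)
  rep(seq_len(n_pools), each = pool_size)[seq_len(n_plants)]
}

# Per-mutation detection probability given offsets within an amplicon.
.detect_prob <- function(offset, amp_len, config, zygosity = NULL) {
  w <- config$edge_window
  d <- pmin(offset - 1, amp_len - offset)  # distance to nearest end
  if (config$edge_model == "step" || w == 0) {
    p <- ifelse(d < w, config$edge_sensitivity, config$interior_sensitivity)
  } else {
    frac <- pmin(d / w, 1)
    p <- config$edge_sensitivity +
      (config$interior_sensitivity - config$edge_sensitivity) * frac
  }
  if (isTRUE(config$allele_dilution) && !is.null(zygosity)) {
    p <- p * ifelse(zygosity == "het", 0.5, 1)
  }
  p
}

#' Screen an amplicon across a simulated population
#'
#' Every true mutation inside the amplicon is detected independently with a
#' position-dependent probability: `edge_sensitivity` within `edge_window`
#' bp of either end, `interior_sensitivity` elsewhere (or a linear ramp,
#' see [sim_config()]). Both heterozygous and homozygous mutations are
#' detectable — a homozygous mutant pooled with 7 wild-type lines still
#' forms mismatched heteroduplex.
#'
#' @param population A [mutagenize_population()] result.
#' @param amplicon Integer vector `c(start, end)`, 1-based inclusive on the
#'   reference.
#' @param config Simulation config; defaults to the population's.
#' @return A list of class `sim_screen`: `amplicon`, `amplicon_length`,
#'   `true_mutations`, `detected_mutations`, `detected_by_position`
#'   (offsets within the amplicon, 1-based) and `detected` (the detected
#'   subset of the mutation table with an `offset` column).
#' @export
detect_screen <- function(population, amplicon, config = population$config) {
  if (length(amplicon) != 2 || amplicon[1] > amplicon[2]) {
    stop_input("amplicon must be c(start, end) with start <= end")
  }
  if (amplicon[1] < 1 || amplicon[2] > nchar(population$reference)) {
    stop_input("amplicon outside the reference")
  }
  L <- amplicon[2] - amplicon[1] + 1
  m <- population$mutations
  inside <- m$pos >= amplicon[1] & m$pos <= amplicon[2]
  m <- m[inside, , drop = FALSE]
  offset <- m$pos - amplicon[1] + 1L
  p <- .detect_prob(offset, L, config, m$zygosity)
  hit <- stats::runif(nrow(m)) < p
  det <- cbind(m[hit, , drop = FALSE], offset = offset[hit])
  rownames(det) <- NULL
  structure(list(
    amplicon = amplicon,
    amplicon_length = L,
    true_mutations = nrow(m),
    detected_mutations = sum(hit),
    detected_by_position = offset[hit],
    detected = det
  ), class = "sim_screen")
}

#' Edge sensitivity reproducing a target edge share of detections
#'
#' For a step edge model with perfect interior detection and uniformly
#' distributed mutations, solves for the edge-zone sensitivity `s` such
#' that a fraction `target_share` of all detections falls inside edge zones
#' covering a fraction `edge_fraction` of the amplicon:
#' `s = p (1 - w) / (w (1 - p))` for `w = edge_fraction`,
#' `p = target_share`.
#'
#' @param edge_fraction Fraction of the amplicon inside edge zones (e.g.
#'   2 x 100 bp of 1000 bp = 0.2).
#' @param target_share Desired fraction of detections in the edge zones
#'   (e.g. 5/617).
#' @return Sensitivity in `[0,1]`.
#' @examples
#' calibrate_edge_sensitivity(0.2, 5 / 617)  # ~0.033
#' @export
calibrate_edge_sensitivity <- function(edge_fraction, target_share) {
  if (edge_fraction <= 0 || edge_fraction >= 1) {
    stop_input("edge_fraction must be in (0,1)")
  }
  if (target_share < 0 || target_share >= 1) {
    stop_input("target_share must be in [0,1)")
  }
  target_share * (1 - edge_fraction) /
    (edge_fraction * (1 - target_share))
}

#' Run a simulated TILLING assay and emit a screen-assay row
#'
#' Screens an amplicon over the whole simulated population and packages the
#' result as a [screen_assays()] row (with the amplicon's realized GC
#' percent), so the simulator output feeds directly into
#' [summarize_assays()] and the density estimators.
#'
#' @inheritParams detect_screen
#' @param gene Identifier for the emitted row.
#' @param ems_pct Nominal dose label for the emitted row.
#' @return A `screen_assay_table` with one row. Zero detected mutations
#'   produce a valid row (density estimation on it will then signal its
#'   usual "density undefined" error).
#' @export
run_assay <- function(population, amplicon, config = population$config,
                      gene = "sim", ems_pct = NA_real_) {
  scr <- detect_screen(population, amplicon, config)
  amp_seq <- substr(population$reference, amplicon[1], amplicon[2])
  gc_n <- nchar(gsub("[^GC]", "", amp_seq))
  d <- data.frame(gene = gene, ems_pct = ems_pct,
                  length_bp = scr$amplicon_length,
                  gc_pct = 100 * gc_n / scr$amplicon_length,
                  mutations = scr$detected_mutations,
                  screened = population$n_plants,
                  population = population$n_plants,
                  stringsAsFactors = FALSE)
  class(d) <- c("screen_assay_table", "data.frame")
  d
}

#' Parameter-recovery experiment for the density estimator
#'
#' Simulates `n_replicates` independent M2 populations on one reference,
#' screens a fixed amplicon in each with perfect detection unless the
#' config says otherwise, estimates base pairs per mutation from each
#' simulated assay, and compares the estimates with the exact expectation
#' `L / (n_GC_in_amplicon * per_gc_site_rate)`. Per-plant loads are
#' recovered by normalizing each estimate to the reference's realized GC
#' and dividing into the reference length.
#'
#' @param config A [sim_config()]; `config$seed` is ignored in favour of
#'   `seed`.
#' @param n_replicates Number of replicate populations (>= 2).
#' @param amplicon Amplicon interval; default: a central 1 kb window.
#' @param seed Integer seed for the whole experiment.
#' @param out_tsv Optional path; per-replicate results are written as TSV.
#' @return A list of class `recovery_report`: `replicates` (data frame with
#'   per-replicate detected counts, bp-per-mutation and load estimates),
#'   `truth` (`bp_per_mutation`, `load`), `estimate` (means), `se`
#'   (standard errors of the means), `bias` and `config`.
#' @export
recovery_experiment <- function(config = sim_config(), n_replicates = 20,
                                amplicon = NULL, seed = 1, out_tsv = NULL) {
  if (n_replicates < 2) stop_input("n_replicates must be >= 2")
  set.seed(seed)
  reference <- make_reference(config$reference_length, config$reference_gc)
  if (is.null(amplicon)) {
    mid <- config$reference_length %/% 2
    amplicon <- c(mid - 499, mid + 500)
  }
  amp_seq <- substr(reference, amplicon[1], amplicon[2])
  L <- amplicon[2] - amplicon[1] + 1
  gc_amp <- nchar(gsub("[^GC]", "", amp_seq))
  if (gc_amp == 0) stop_input("amplicon contains no G/C sites")
  gc_ref_pct <- 100 * nchar(gsub("[^GC]", "", reference)) / nchar(reference)

  cfg <- config
  cfg$seed <- NULL  # replicate-level RNG flows from the experiment seed
  reps <- lapply(seq_len(n_replicates), function(i) {
    pop <- mutagenize_population(reference, cfg)
    assay <- run_assay(pop, amplicon, cfg)
    if (assay$mutations == 0) {
      return(data.frame(replicate = i, true_mutations = NA_integer_,
                        detected = 0, bp_per_mutation = NA_real_,
                        load = NA_real_))
    }
    bp <- bp_per_mutation(assay$length_bp, assay$screened, assay$mutations)
    bp_ref <- normalize_bp_per_mutation(bp, assay$gc_pct, gc_ref_pct)
    data.frame(replicate = i,
               true_mutations = NA_integer_,
               detected = assay$mutations,
               bp_per_mutation = bp,
               load = nchar(reference) / bp_ref)
  })
  reps <- do.call(rbind, reps)

  truth_bp <- L / (gc_amp * config$per_gc_site_rate)
  truth_load <- round(nchar(reference) * (gc_ref_pct / 100) *
                        config$per_gc_site_rate, 6)
  ok <- !is.na(reps$bp_per_mutation)
  est_bp <- mean(reps$bp_per_mutation[ok])
  est_load <- mean(reps$load[ok])
  se_bp <- stats::sd(reps$bp_per_mutation[ok]) / sqrt(sum(ok))
  se_load <- stats::sd(reps$load[ok]) / sqrt(sum(ok))

  if (!is.null(out_tsv)) {
    utils::write.table(reps, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(list(
    replicates = reps,
    truth = c(bp_per_mutation = truth_bp, load = truth_load),
    estimate = c(bp_per_mutation = est_bp, load = est_load),
    se = c(bp_per_mutation = se_bp, load = se_load),
    bias = c(bp_per_mutation = est_bp - truth_bp,
             load = est_load - truth_load),
    seed = seed,
    amplicon = amplicon,
    config = config
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (seed %d)\n",
              nrow(x$replicates), x$seed))
  cat(sprintf("  bp/mutation: truth %.0f, estimate %.0f +/- %.0f (bias %+.1f%%)\n",
              x$truth[["bp_per_mutation"]], x$estimate[["bp_per_mutation"]],
              x$se[["bp_per_mutation"]],
              100 * x$bias[["bp_per_mutation"]] / x$truth[["bp_per_mutation"]]))
  cat(sprintf("  load/plant:  truth %.1f, estimate %.1f +/- %.2f\n",
              x$truth[["load"]], x$estimate[["load"]], x$se[["load"]]))
  invisible(x)
}
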