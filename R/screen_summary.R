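# Assay-table summaries: per-assay derived columns and per-dose averages,
# following the display conventions of published TILLING screen tables.

#' Summarize a table of TILLING assays
#'
#' Computes, for each assay row, the raw and GC-normalized mutation density,
#' the extrapolated per-plant mutation load (raw and normalized to the
#' genome-average GC), and the expected mutation yield per kb when screening
#' the whole population (at the amplicon's own GC and normalized to exon
#' GC), then averages each derived column within EMS-dose groups.
#'
#' Display conventions (chosen to reproduce published screen tables
#' cell-for-cell): all rounding is half-up; the normalized per-plant load is
#' derived from the *rounded* raw load (`round(round(load) * genome_gc /
#' gc)`); dose-group averages are unweighted means of the rounded per-assay
#' display values. Unrounded densities are kept alongside.
#'
#' @param assays A `screen_assay_table` (see [screen_assays()],
#'   [read_assay_table()]). Rows with zero mutations are dropped with a
#'   warning.
#' @param constants [population_constants()].
#' @return A list of class `tilling_summary`: `assays` (per-assay derived
#'   columns), `averages` (one row per EMS dose) and `constants`.
#' @examples
#' s <- summarize_assays(read_assay_table(
#'   system.file("extdata", "table1_assays.tsv", package = "tillingr")))
#' s$averages
#' @export
summarize_assays <- function(assays, constants = population_constants()) {
  assays <- validate_screen_assays(as.data.frame(assays))
  drop <- assays$mutations == 0
  if (any(drop)) assays <- assays[!drop, , drop = FALSE]
  if (nrow(assays) == 0) stop_input("no assays with detected mutations")

  bp_raw <- bp_per_mutation(assays$length_bp, assays$screened, assays$mutations)
  bp_norm <- normalize_bp_per_mutation(bp_raw, assays$gc_pct, constants$genome_gc)
  load_raw <- mutations_per_plant(bp_raw, constants)
  # Printed-table convention: normalized load from the rounded raw load.
  load_norm <- round_half_up(load_raw * constants$genome_gc / assays$gc_pct)
  yield_raw <- round_half_up(
    expected_mutations(assays$population, 1000, bp_raw))
  yield_norm <- round_half_up(expected_mutations(
    assays$population, 1000,
    normalize_bp_per_mutation(bp_raw, assays$gc_pct, constants$exon_gc)))

  per <- data.frame(
    gene = assays$gene,
    ems_pct = assays$ems_pct,
    length_bp = assays$length_bp,
    gc_pct = assays$gc_pct,
    mutations = assays$mutations,
    screened = assays$screened,
    population = assays$population,
    bp_per_mutation = bp_raw,
    bp_per_mutation_norm = bp_norm,
    density = format_density(bp_raw),
    density_norm = format_density(bp_norm),
    load = load_raw,
    load_norm = load_norm,
    expected_per_kb = yield_raw,
    expected_per_kb_norm = yield_norm,
    stringsAsFactors = FALSE
  )

  avg_one <- function(g) {
    data.frame(
      ems_pct = g$ems_pct[1],
      n_assays = nrow(g),
      load = round_half_up(mean(g$load)),
      load_norm = round_half_up(mean(g$load_norm)),
      density = paste0("1/", round_half_up(
        mean(round_half_up(g$bp_per_mutation / 1000)))),
      density_norm = paste0("1/", round_half_up(
        mean(round_half_up(g$bp_per_mutation_norm / 1000)))),
      expected_per_kb = round_half_up(mean(g$expected_per_kb)),
      expected_per_kb_norm = round_half_up(mean(g$expected_per_kb_norm)),
      stringsAsFactors = FALSE
    )
  }
  averages <- do.call(rbind, lapply(split(per, per$ems_pct), avg_one))
  rownames(averages) <- NULL

  structure(list(assays = per, averages = averages, constants = constants),
            class = "tilling_summary")
}

#' @export
print.tilling_summary <- function(x, ...) {
  cols <- c("gene", "ems_pct", "length_bp", "gc_pct", "mutations",
            "screened", "load", "load_norm", "density", "density_norm",
            "expected_per_kb", "expected_per_kb_norm")
  cat("TILLING assay summary (normalized values at ",
      x$constants$genome_gc, "% genome GC / ",
      x$constants$exon_gc, "% exon GC)\n", sep = "")
  print(x$assays[, cols], row.names = FALSE)
  cat("\nDose-group averages:\n")
  print(x$averages, row.names = FALSE)
  invisible(x)
}

#' Observed vs expected mutation-class composition
#'
#' Compares observed counts of silent / mis-sense / nonsense mutations with
#' the counts expected from the genetic-code census fractions (observed
#' total times expected fraction). Descriptive only — no hypothesis test is
#' performed.
#'
#' @param observed Named counts with entries `silent`, `missense`,
#'   `nonsense`.
#' @param fractions Expected class fractions summing to 1; defaults to
#'   [expected_class_fractions()].
#' @return A data frame of class `class_composition`: per class the
#'   observed and expected counts and fractions.
#' @examples
#' class_composition_report(c(silent = 90, missense = 167, nonsense = 5))
#' @export
class_composition_report <- function(observed,
                                     fractions = expected_class_fractions()) {
  cls <- c("silent", "missense", "nonsense")
  if (!all(cls %in% names(observed))) {
    stop_input("observed must name counts for: ", paste(cls, collapse = ", "))
  }
  observed <- observed[cls]
  fractions <- fractions[cls]
  if (any(observed < 0)) stop_input("counts must be >= 0")
  total <- sum(observed)
  if (total == 0) stop_input("observed counts are all zero")
  if (abs(sum(fractions) - 1) > 1e-8) stop_input("fractions must sum to 1")
  out <- data.frame(
    class = cls,
    observed = as.numeric(observed),
    observed_fraction = as.numeric(observed) / total,
    expected = total * as.numeric(fractions),
    expected_fraction = as.numeric(fractions),
    stringsAsFactors = FALSE
  )
  class(out) <- c("class_composition", "data.frame")
  out
}
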