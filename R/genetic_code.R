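# Enumeration of EMS-accessible changes in the standard genetic code.
#
# EMS (ethyl methane sulfonate) alkylates guanine at the O6 position, so in
# practice it induces almost exclusively G:C -> A:T transitions. On the sense
# strand every lesion therefore reads as G->A or C->T; antisense lesions are
# the complementary event at the same site and are not counted twice.

.EMS_TO <- c(G = "A", C = "T")

.codon_table <- function() {
  # Standard genetic code (translation table 1); "*" denotes stop.
  Biostrings::GENETIC_CODE
}

.check_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L) {
    stop_input(arg, " must be a single string")
  }
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop_input(arg, " must be a triplet over {A,C,G,T}, got '", codon, "'")
  }
  codon
}

.classify <- function(aa_from, aa_to) {
  # Stop-to-stop counts as silent: the encoded product is unchanged.
  as.character(ifelse(aa_from == aa_to, "silent",
                      ifelse(aa_to == "*" & aa_from != "*",
                             "nonsense", "missense")))
}

#' All EMS-induced changes possible in one codon
#'
#' Enumerates every G->A and C->T substitution available in a codon and
#' classifies the coding consequence of each. A codon with neither G nor C
#' cannot be hit by EMS and yields zero rows.
#'
#' @param codon A single codon, e.g. `"TGG"`.
#' @return A data frame with one row per G/C position, in position order:
#'   `codon`, `position` (1-3), `from_base`, `to_base`, `new_codon`,
#'   `aa_from`, `aa_to` (one-letter code, `"*"` = stop), `change_class`
#'   (`"silent"`, `"missense"` or `"nonsense"`).
#' @examples
#' ems_changes_for_codon("TGG")  # both G's create stop codons
#' ems_changes_for_codon("AAA")  # empty: no G or C
#' @seealso [code_spectrum()] for the census over all 64 codons.
#' @export
ems_changes_for_codon <- function(codon) {
  codon <- .check_codon(codon)
  tab <- .codon_table()
  bases <- strsplit(codon, "")[[1]]
  pos <- which(bases %in% c("G", "C"))
  new_codon <- vapply(pos, function(i) {
    b <- bases
    b[i] <- .EMS_TO[[b[i]]]
    paste(b, collapse = "")
  }, character(1))
  aa_from <- rep(unname(tab[codon]), length(pos))
  aa_to <- unname(tab[new_codon])
  data.frame(
    codon = rep(codon, length(pos)),
    position = pos,
    from_base = bases[pos],
    to_base = unname(.EMS_TO[bases[pos]]),
    new_codon = new_codon,
    aa_from = aa_from,
    aa_to = aa_to,
    change_class = .classify(aa_from, aa_to),
    stringsAsFactors = FALSE
  )
}

#' Classify a single EMS codon substitution
#'
#' @param from_codon,to_codon Codons differing at exactly one position by a
#'   G->A or C->T substitution.
#' @return `"silent"` (product unchanged, including stop-to-stop),
#'   `"nonsense"` (sense codon becomes a stop) or `"missense"`.
#' @examples
#' classify_change("CGA", "TGA")  # nonsense: Arg -> stop
#' classify_change("GCG", "GCA")  # silent: Ala -> Ala
#' @export
classify_change <- function(from_codon, to_codon) {
  from_codon <- .check_codon(from_codon, "from_codon")
  to_codon <- .check_codon(to_codon, "to_codon")
  fb <- strsplit(from_codon, "")[[1]]
  tb <- strsplit(to_codon, "")[[1]]
  diff <- which(fb != tb)
  if (length(diff) != 1L) {
    stop_input("codons must differ at exactly one position")
  }
  ok <- (fb[diff] == "G" && tb[diff] == "A") ||
    (fb[diff] == "C" && tb[diff] == "T")
  if (!ok) {
    stop_input("not an EMS transition (G->A or C->T): ",
               fb[diff], "->", tb[diff])
  }
  tab <- .codon_table()
  unname(.classify(tab[from_codon], tab[to_codon]))
}

#' Default chemical-similarity grouping of amino acids
#'
#' Grouping used to flag "conservative" mis-sense changes:
#' \{I,L,V,M\}, \{F,Y,W\}, \{K,R,H\}, \{D,E\}, \{S,T\}, \{N,Q\}, \{A,G\},
#' \{C\}, \{P\}. Any partition of the 20 amino acids (a list of character
#' vectors) can be supplied to [code_spectrum()] in its place; "conservative"
#' is not a property of the code but of the chosen scheme.
#'
#' @return A list of character vectors partitioning the amino acids.
#' @export
ems_similarity_default <- function() {
  list(
    c("I", "L", "V", "M"),
    c("F", "Y", "W"),
    c("K", "R", "H"),
    c("D", "E"),
    c("S", "T"),
    c("N", "Q"),
    c("A", "G"),
    "C",
    "P"
  )
}

.similarity_lookup <- function(groups) {
  aa <- unlist(groups)
  if (anyDuplicated(aa)) stop_input("similarity groups must be disjoint")
  stats::setNames(rep(seq_along(groups), lengths(groups)), aa)
}

#' Census of EMS-accessible changes over the whole genetic code
#'
#' Brute-force enumeration of every G->A and C->T substitution at every
#' position of all 64 codons of the standard genetic code, with each change
#' classified as silent, mis-sense or nonsense. The census is the basis for
#' screen-design arithmetic: the nonsense fraction of mutable positions sets
#' the chance that a recovered mutation is a premature stop.
#'
#' @param similarity Amino-acid grouping used to count conservative
#'   mis-sense sites; see [ems_similarity_default()].
#' @return An object of class `ems_spectrum`: a list with counts
#'   `unaffected_codons`, `mutable_positions`, `silent`, `missense`,
#'   `nonsense`, `distinct_substitutions` (distinct mis-sense amino-acid
#'   pairs), `conservative_sites`, and `changes`, the full 96-row
#'   enumeration as returned by [ems_changes_for_codon()].
#' @examples
#' sp <- code_spectrum()
#' sp$nonsense / sp$mutable_positions  # chance a random EMS hit is a stop
#' @export
code_spectrum <- function(similarity = ems_similarity_default()) {
  codons <- names(.codon_table())
  changes <- do.call(rbind, lapply(codons, ems_changes_for_codon))
  rownames(changes) <- NULL
  mis <- changes[changes$change_class == "missense", ]
  lut <- .similarity_lookup(similarity)
  conservative <- sum(lut[mis$aa_from] == lut[mis$aa_to], na.rm = TRUE)
  out <- list(
    unaffected_codons = sum(!grepl("[GC]", codons)),
    mutable_positions = nrow(changes),
    silent = sum(changes$change_class == "silent"),
    missense = nrow(mis),
    nonsense = sum(changes$change_class == "nonsense"),
    distinct_substitutions = nrow(unique(mis[, c("aa_from", "aa_to")])),
    conservative_sites = conservative,
    changes = changes
  )
  class(out) <- "ems_spectrum"
  out
}

#' @export
print.ems_spectrum <- function(x, ...) {
  cat("EMS mutation spectrum of the standard genetic code\n")
  cat(sprintf("  codons unaffected (no G/C): %d of 64 (%.1f%%)\n",
              x$unaffected_codons, 100 * x$unaffected_codons / 64))
  cat(sprintf("  mutable G/C positions:      %d\n", x$mutable_positions))
  cat(sprintf("    silent:    %2d\n", x$silent))
  cat(sprintf("    mis-sense: %2d (%d distinct substitutions, %d at conservative sites)\n",
              x$missense, x$distinct_substitutions, x$conservative_sites))
  cat(sprintf("    nonsense:  %2d\n", x$nonsense))
  invisible(x)
}

#' Expected class fractions of a random EMS hit in coding sequence
#'
#' Fractions of the 96 mutable genetic-code positions falling in each
#' change class, under the uniform-codon assumption.
#'
#' @param spectrum An [code_spectrum()] result; computed if missing.
#' @return Named numeric vector `c(silent=, missense=, nonsense=)` summing
#'   to 1.
#' @export
expected_class_fractions <- function(spectrum = code_spectrum()) {
  c(silent = spectrum$silent,
    missense = spectrum$missense,
    nonsense = spectrum$nonsense) / spectrum$mutable_positions
}
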