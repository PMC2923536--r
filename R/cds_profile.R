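# Per-site EMS effect profiling of coding sequences: used to pick the
# amplicon window with the highest stop-codon potential before designing a
# screen.

#' Profile a coding sequence for EMS effect potential
#'
#' Classifies every possible EMS change (G->A, C->T on the sense strand) in
#' the frame-covered part of a coding sequence, and counts nonsense-capable
#' sites in tiling windows so the region with most stop-codon potential can
#' be chosen as the screening amplicon.
#'
#' Only complete codons from `frame_offset + 1` onward are covered; trailing
#' bases short of a codon are ignored. Windows of `window_bp` tile the
#' covered region (the last window may be short), so window nonsense counts
#' always sum to the profile's total nonsense count.
#'
#' @param sequence Sense-strand DNA string (a plain character scalar or
#'   anything coercible via `as.character`, e.g. a `DNAString`).
#' @param seq_id Identifier carried into the output.
#' @param frame_offset Bases to skip before the first codon (0, 1 or more).
#' @param window_bp Window width for the nonsense-density track.
#' @param ambiguity `"error"` rejects non-ACGT characters; `"skip"` drops
#'   codons containing them with a warning.
#' @return An object of class `cds_profile`: list with `sequence_id`,
#'   `length_bp`, `mutable_sites`, `per_site_changes` (data frame: `pos`
#'   1-based on the input sequence, `codon`, `codon_pos`, `from_base`,
#'   `to_base`, `new_codon`, `aa_from`, `aa_to`, `change_class`),
#'   `class_counts` and `window_nonsense` (data frame: `start`, `end`,
#'   `nonsense_sites`).
#' @examples
#' p <- profile_cds("ATGTGGTAA")
#' p$class_counts
#' @export
profile_cds <- function(sequence, seq_id = "cds", frame_offset = 0,
                        window_bp = 300,
                        ambiguity = c("error", "skip")) {
  ambiguity <- match.arg(ambiguity)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence)) {
    stop_input("sequence must be a single DNA string")
  }
  n <- nchar(sequence)
  if (frame_offset < 0) stop_input("frame_offset must be >= 0")
  if (frame_offset >= n) stop_input("frame_offset >= sequence length")
  if (window_bp < 1) stop_input("window_bp must be >= 1")
  n_codons <- (n - frame_offset) %/% 3
  if (n_codons < 1) stop_input("fewer than one complete codon after frame offset")

  starts <- frame_offset + 3 * (seq_len(n_codons) - 1) + 1
  codons <- substring(sequence, starts, starts + 2)
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    if (ambiguity == "error") {
      stop_input("sequence contains non-ACGT characters (codon ",
                 which(bad)[1], ": '", codons[which(bad)[1]], "')")
    }
    warning(sum(bad), " codon(s) with ambiguity codes skipped in ", seq_id)
  }

  # One lookup table of all 96 genetic-code changes, indexed by codon.
  tab <- code_spectrum()$changes
  idx_by_codon <- split(seq_len(nrow(tab)), tab$codon)
  keep <- which(!bad)
  hit_lists <- idx_by_codon[codons[keep]]
  hit_lists[is.na(names(hit_lists))] <- list(integer(0))  # codons w/o G or C
  rows <- unlist(hit_lists, use.names = FALSE)
  reps <- lengths(hit_lists)
  chg <- tab[rows, , drop = FALSE]
  per_site <- data.frame(
    pos = rep(starts[keep], reps) + chg$position - 1L,
    codon = chg$codon,
    codon_pos = chg$position,
    from_base = chg$from_base,
    to_base = chg$to_base,
    new_codon = chg$new_codon,
    aa_from = chg$aa_from,
    aa_to = chg$aa_to,
    change_class = chg$change_class,
    stringsAsFactors = FALSE
  )
  per_site <- per_site[order(per_site$pos), , drop = FALSE]
  rownames(per_site) <- NULL

  class_counts <- c(
    silent = sum(per_site$change_class == "silent"),
    missense = sum(per_site$change_class == "missense"),
    nonsense = sum(per_site$change_class == "nonsense")
  )

  cover_start <- frame_offset + 1L
  cover_end <- frame_offset + 3L * n_codons
  win_start <- seq.int(cover_start, cover_end, by = window_bp)
  win_end <- pmin(win_start + window_bp - 1L, cover_end)
  npos <- per_site$pos[per_site$change_class == "nonsense"]
  window_nonsense <- data.frame(
    start = win_start,
    end = win_end,
    nonsense_sites = vapply(seq_along(win_start), function(i) {
      sum(npos >= win_start[i] & npos <= win_end[i])
    }, integer(1))
  )

  out <- list(
    sequence_id = seq_id,
    length_bp = n,
    mutable_sites = nrow(per_site),
    per_site_changes = per_site,
    class_counts = class_counts,
    window_nonsense = window_nonsense
  )
  class(out) <- "cds_profile"
  out
}

#' @export
print.cds_profile <- function(x, ...) {
  cat(sprintf("CDS profile '%s': %d bp, %d EMS-mutable sites\n",
              x$sequence_id, x$length_bp, x$mutable_sites))
  cat(sprintf("  silent %d | mis-sense %d | nonsense %d\n",
              x$class_counts[["silent"]], x$class_counts[["missense"]],
              x$class_counts[["nonsense"]]))
  best <- x$window_nonsense[which.max(x$window_nonsense$nonsense_sites), ]
  if (nrow(best) == 1 && x$class_counts[["nonsense"]] > 0) {
    cat(sprintf("  best stop-codon window: %d-%d (%d sites)\n",
                best$start, best$end, best$nonsense_sites))
  }
  invisible(x)
}

#' Write a CDS profile as TSV
#'
#' One row per possible EMS change, 1-based sense-strand coordinates.
#'
#' @param profile A [profile_cds()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  d <- profile$per_site_changes
  d <- cbind(seq_id = profile$sequence_id, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
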