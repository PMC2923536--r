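# Format plumbing: FASTA sequences, assay tables (TSV), mutation tables
# (TSV / minimal VCF-style) and packaged fixtures.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file. Line-wrapped records are handled; sequences are
#'   uppercased.
#' @return Named character vector of sequences, in file order. An empty
#'   file yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    warning("no FASTA records in ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop_input("malformed FASTA in ", path,
                                                 ": ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  # keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}

#' Read a screen-assay table from TSV
#'
#' Expected columns: `gene`, `ems_pct`, `length_bp`, `gc_pct`, `mutations`,
#' `screened`, `population`. Lines starting with `#` are comments. Rows with
#' zero detected mutations load but are flagged with a warning.
#'
#' @param path TSV file.
#' @return A validated `screen_assay_table` data frame.
#' @examples
#' read_assay_table(
#'   system.file("extdata", "table1_assays.tsv", package = "tillingr"))
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  d <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_input("cannot parse TSV ", path, ": ",
                                   conditionMessage(e)))
  validate_screen_assays(d)
}

#' Packaged fixture: the eight-assay screen table
#'
#' Raw columns of the eight TILLING assays (six genes at 0.3% EMS, two at
#' 0.4%) shipped with the package; 617 mutations in total.
#'
#' @return A `screen_assay_table` with 8 rows.
#' @export
example_assays <- function() {
  read_assay_table(system.file("extdata", "table1_assays.tsv",
                               package = "tillingr"))
}

#' Packaged fixture: observed mutation-class counts
#'
#' Per-assay counts of silent / mis-sense / nonsense mutations and the
#' heterozygous:homozygous ratio among detected mutations, by EMS dose.
#'
#' @return A data frame with one row per gene x dose.
#' @export
example_class_counts <- function() {
  utils::read.delim(system.file("extdata", "table2_classes.tsv",
                                package = "tillingr"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a simulated mutation table as TSV
#'
#' Columns: `plant_id`, `pos` (1-based), `ref`, `alt`, `zygosity`.
#'
#' @param population A [mutagenize_population()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(population, path) {
  utils::write.table(population$mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated mutations in minimal VCF-style format
#'
#' One record per (plant, mutation) with the plant id in the INFO field and
#' zygosity as a genotype in a single sample column (`0/1` heterozygous,
#' `1/1` homozygous). Not a full VCF — coordinates, REF and ALT follow the
#' convention but there is no reference FASTA linkage or header contig line
#' beyond the one for the simulated reference.
#'
#' @param population A [mutagenize_population()] result.
#' @param path Output file.
#' @param chrom Name used in the CHROM column.
#' @return `path`, invisibly.
#' @export
write_mutation_vcf <- function(population, path, chrom = "simref") {
  m <- population$mutations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(population$reference)),
    "##INFO=<ID=PLANT,Number=1,Type=Integer,Description=\"M2 plant id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE", sep = "\t")
  ), con)
  if (nrow(m)) {
    gt <- ifelse(m$zygosity == "het", "0/1", "1/1")
    writeLines(paste(chrom, m$pos, ".", m$ref, m$alt, ".", "PASS",
                     paste0("PLANT=", m$plant_id), "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}
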