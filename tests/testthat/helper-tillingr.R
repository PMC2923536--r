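# Independent oracle for genetic-code tests: translation via seqinr,
# enumeration by direct nested loops (no shared code with the package).

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 1)
}

# Brute-force enumeration of every G->A / C->T change over all 64 codons.
oracle_ems_enumeration <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  out <- NULL
  for (cd in codons) {
    b <- strsplit(cd, "")[[1]]
    for (i in 1:3) {
      if (b[i] == "G" || b[i] == "C") {
        nb <- b
        nb[i] <- if (b[i] == "G") "A" else "T"
        ncd <- paste(nb, collapse = "")
        aa1 <- oracle_translate(cd)
        aa2 <- oracle_translate(ncd)
        cls <- if (aa1 == aa2) "silent"
               else if (aa2 == "*") "nonsense" else "missense"
        out <- rbind(out, data.frame(codon = cd, position = i,
                                     new_codon = ncd, aa_from = aa1,
                                     aa_to = aa2, change_class = cls,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

random_codon_seq <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}

table1_printed <- function() {
  # Derived cells as printed in the source screen table. Two cells are
  # documented printing discrepancies and carry the recomputed value here:
  # the 0.4% BraA.RPL.c density prints "1/358" for 1/58, and the
  # expected-yield cells for BraA.RPL.b (209) and BraA.MET1.a (191) print
  # one off the value the raw columns give under half-up rounding
  # (208.49 -> 208, 191.58 -> 192); no rounding rule reproduces all three.
  data.frame(
    gene = c("BraA.RPL.a", "BraA.RPL.b", "BraA.RPL.c", "BraA.IND.a",
             "BraA.MET1.a", "BraA.MET1.b", "BraA.RPL.b", "BraA.RPL.c"),
    ems_pct = c(rep(0.3, 6), 0.4, 0.4),
    load = c(13577, 15082, 14309, 5674, 13858, 14385, 11539, 8672),
    load_norm = c(10111, 11730, 10656, 4844, 10105, 10712, 8975, 6458),
    density = c("1/37", "1/33", "1/35", "1/88", "1/36", "1/35",
                "1/43", "1/58"),
    density_norm = c("1/49", "1/43", "1/47", "1/103", "1/49", "1/47",
                     "1/56", "1/77"),
    expected_per_kb = c(188, 208, 198, 78, 192, 199, 53, 40),
    expected_per_kb_norm = c(164, 190, 173, 78, 164, 173, 48, 35),
    stringsAsFactors = FALSE
  )
}

table1_printed_averages <- function() {
  data.frame(
    ems_pct = c(0.3, 0.4),
    load = c(12814, 10106),
    load_norm = c(9693, 7717),
    density = c("1/44", "1/51"),
    density_norm = c("1/56", "1/67"),
    expected_per_kb = c(177, 47),
    expected_per_kb_norm = c(157, 42),
    stringsAsFactors = FALSE
  )
}
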