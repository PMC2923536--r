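# Population simulator: mutation model, pooling, detection and parameter
# recovery at reduced scale (module-level; the full-scale recovery runs in
# the acceptance suite).

small_config <- function(...) {
  sim_config(reference_length = 2e5, reference_gc = 0.35,
             per_gc_site_rate = 1e-3, n_plants = 100, seed = 11, ...)
}

test_that("reference generation is reproducible with controlled GC", {
  r1 <- make_reference(5000, 0.35, seed = 5)
  r2 <- make_reference(5000, 0.35, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1, make_reference(5000, 0.35, seed = 6)))
  at_only <- make_reference(300, 0, seed = 1)
  expect_false(grepl("[GC]", at_only))
  big <- make_reference(1e5, 0.35, seed = 2)
  gc_n <- nchar(gsub("[^GC]", "", big))
  se <- sqrt(1e5 * 0.35 * 0.65)
  expect_lt(abs(gc_n - 35000), 3 * se)
})

test_that("mutations occur only at G/C sites as G->A or C->T", {
  cfg <- small_config()
  ref <- make_reference(cfg$reference_length, cfg$reference_gc, seed = 21)
  pop <- mutagenize_population(ref, cfg)
  m <- pop$mutations
  expect_gt(nrow(m), 0)
  ref_bases <- substring(ref, m$pos, m$pos)
  expect_equal(m$ref, ref_bases)
  expect_true(all(m$ref %in% c("G", "C")))
  expect_identical(m$alt, ifelse(m$ref == "G", "A", "T"))
  # positions unique within each plant
  expect_false(any(duplicated(m[, c("plant_id", "pos")])))
})

test_that("mean load and zygosity match the configured parameters", {
  cfg <- small_config()
  ref <- make_reference(cfg$reference_length, cfg$reference_gc, seed = 22)
  pop <- mutagenize_population(ref, cfg)
  expected_load <- pop$gc_sites * cfg$per_gc_site_rate
  se_load <- sqrt(pop$gc_sites * cfg$per_gc_site_rate) / sqrt(pop$n_plants)
  expect_lt(abs(mean(pop$loads) - expected_load), 3 * se_load)
  p_het <- cfg$het_hom_ratio / (cfg$het_hom_ratio + 1)
  n <- nrow(pop$mutations)
  obs_het <- mean(pop$mutations$zygosity == "het")
  expect_lt(abs(obs_het - p_het), 3 * sqrt(p_het * (1 - p_het) / n))
  # zero rate: sterile mutagen
  cfg0 <- small_config()
  cfg0$per_gc_site_rate <- 0
  expect_equal(nrow(mutagenize_population(ref, cfg0)$mutations), 0)
  # reproducibility from the config seed
  pop2 <- mutagenize_population(ref, cfg)
  expect_identical(pop$mutations, pop2$mutations)
})

test_that("pooling partitions plants into the documented plate layout", {
  for (n in c(8, 100, 2304, 6912)) {
    pools <- pool_plants(n, 8)
    expect_length(pools, n)
    expect_equal(max(pools), ceiling(n / 8))
    expect_true(all(table(pools) <= 8))
  }
  expect_equal(max(pool_plants(6912, 8)), 864)   # 9 plates of 96 pools
  expect_equal(max(pool_plants(2304, 8)), 288)   # 3 plates
  expect_equal(max(pool_plants(8, 8)), 1)
  # remainder forms one short final pool
  p <- pool_plants(20, 8)
  expect_equal(as.vector(table(p)), c(8, 8, 4))
})

test_that("perfect detection is lossless and offsets stay in range", {
  cfg <- small_config()
  ref <- make_reference(cfg$reference_length, cfg$reference_gc, seed = 31)
  pop <- mutagenize_population(ref, cfg)
  amp <- c(1000, 2999)
  scr <- detect_screen(pop, amp, cfg)
  expect_equal(scr$detected_mutations, scr$true_mutations)
  expect_true(all(scr$detected_by_position >= 1 &
                    scr$detected_by_position <= scr$amplicon_length))
  expect_error(detect_screen(pop, c(3000, 2000)),
               class = "tillingr_input_error")
  expect_error(detect_screen(pop, c(1, 1e7)),
               class = "tillingr_input_error")
})

test_that("detected count is monotone non-increasing in edge window", {
  cfg <- small_config(edge_sensitivity = 0.1)
  ref <- make_reference(cfg$reference_length, cfg$reference_gc, seed = 41)
  pop <- mutagenize_population(ref, cfg)
  amp <- c(50000, 50999)
  detected <- sapply(c(0, 50, 100, 200, 400), function(w) {
    cfg$edge_window <- w
    set.seed(77)  # identical detection draws across windows
    detect_screen(pop, amp, cfg)$detected_mutations
  })
  expect_true(all(diff(detected) <= 0))
})

test_that("edge calibration solves the step-model share equation", {
  s <- calibrate_edge_sensitivity(0.2, 5 / 617)
  expect_equal(0.2 * s / (0.2 * s + 0.8), 5 / 617)
  expect_lt(abs(s - 0.033), 0.001)
  expect_equal(calibrate_edge_sensitivity(0.5, 0), 0)
})

test_that("simulated assays recover the configured density", {
  cfg <- small_config()
  rep <- recovery_experiment(cfg, n_replicates = 8, amplicon = c(90001, 92000),
                             seed = 12)
  # load estimator is linear in counts, hence unbiased: 3 SE band
  expect_lt(abs(rep$estimate[["load"]] - rep$truth[["load"]]),
            3 * rep$se[["load"]])
  expect_equal(nrow(rep$replicates), 8)
  # identical seeds give identical experiments
  rep2 <- recovery_experiment(cfg, n_replicates = 8,
                              amplicon = c(90001, 92000), seed = 12)
  expect_identical(rep$estimate, rep2$estimate)
  expect_error(recovery_experiment(cfg, n_replicates = 1),
               class = "tillingr_input_error")
})

test_that("GC normalization aligns assays from GC-poor and GC-rich regions", {
  # reference with a GC-rich first half and GC-poor second half
  set.seed(55)
  ref <- paste0(make_reference(5e4, 0.60), make_reference(5e4, 0.30))
  cfg <- sim_config(reference_length = 1e5, per_gc_site_rate = 2e-3,
                    n_plants = 400, seed = 56)
  pop <- mutagenize_population(ref, cfg)
  rich <- run_assay(pop, c(10001, 14000), cfg, gene = "rich")
  poor <- run_assay(pop, c(60001, 64000), cfg, gene = "poor")
  bp_rich <- bp_per_mutation(rich$length_bp, rich$screened, rich$mutations)
  bp_poor <- bp_per_mutation(poor$length_bp, poor$screened, poor$mutations)
  # raw densities differ roughly with GC; normalized ones agree
  norm_rich <- normalize_bp_per_mutation(bp_rich, rich$gc_pct, 35)
  norm_poor <- normalize_bp_per_mutation(bp_poor, poor$gc_pct, 35)
  # Poisson relative error bound on each count, 3 sigma, combined
  rel_se <- sqrt(1 / rich$mutations + 1 / poor$mutations)
  expect_lt(abs(log(norm_rich / norm_poor)), 3 * rel_se)
  expect_lt(bp_rich, bp_poor)  # GC-rich region is denser in raw terms
})

test_that("zero detections propagate as an explicit density error", {
  cfg <- small_config()
  cfg$per_gc_site_rate <- 0
  ref <- make_reference(1e4, 0.35, seed = 61)
  pop <- mutagenize_population(ref, cfg)
  assay <- run_assay(pop, c(1, 1000), cfg)
  expect_equal(assay$mutations, 0)
  expect_error(bp_per_mutation(assay$length_bp, assay$screened,
                               assay$mutations),
               class = "tillingr_compute_error")
})

test_that("mutation tables round-trip through TSV and minimal VCF", {
  cfg <- small_config()
  cfg$reference_length <- 1e4
  cfg$n_plants <- 20
  ref <- make_reference(1e4, 0.35, seed = 71)
  pop <- mutagenize_population(ref, cfg)
  tsv <- tempfile(fileext = ".tsv")
  write_mutation_table(pop, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back, pop$mutations)
  vcf <- tempfile(fileext = ".vcf")
  write_mutation_vcf(pop, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nrow(pop$mutations))
  gt <- sapply(strsplit(body, "\t"), `[`, 10)
  expect_equal(gt == "0/1", pop$mutations$zygosity == "het")
})
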