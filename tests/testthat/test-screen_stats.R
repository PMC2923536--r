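# Density estimation, GC normalization and screen-design arithmetic,
# anchored to the eight-assay screen table shipped as a fixture.

test_that("density and per-plant load reproduce known assay rows", {
  bp <- bp_per_mutation(1007, 768, 21)
  expect_equal(bp, 1007 * 768 / 21)
  expect_equal(format_density(bp), "1/37")
  expect_equal(mutations_per_plant(bp), 13577)
  bp2 <- bp_per_mutation(1072, 4608, 149)
  expect_equal(format_density(bp2), "1/33")
  # normalization to genome-average GC
  expect_equal(normalize_bp_per_mutation(bp, 47, 35), bp * 47 / 35)
  expect_equal(format_density(normalize_bp_per_mutation(bp, 47, 35)), "1/49")
  expect_equal(mutations_per_plant(49453), 10111)
  expect_equal(mutations_per_plant(5e8), 1)
  expect_error(bp_per_mutation(1000, 100, 0),
               class = "tillingr_compute_error")
})

test_that("every derived cell of the fixture table reproduces", {
  s <- summarize_assays(example_assays())
  printed <- table1_printed()
  expect_equal(nrow(s$assays), 8)
  for (col in c("load", "load_norm", "density", "density_norm",
                "expected_per_kb", "expected_per_kb_norm")) {
    expect_equal(s$assays[[col]], printed[[col]], info = col)
  }
  avg <- table1_printed_averages()
  for (col in names(avg)) {
    expect_equal(s$averages[[col]], avg[[col]], info = col)
  }
})

test_that("normalization is invertible and scale-consistent", {
  set.seed(99)
  for (i in 1:20) {
    bp <- runif(1, 1e3, 1e6)
    a <- runif(1, 20, 70)
    b <- runif(1, 20, 70)
    expect_equal(normalize_bp_per_mutation(
      normalize_bp_per_mutation(bp, a, b), b, a), bp)
  }
  expect_equal(normalize_bp_per_mutation(12345, 40, 40), 12345)
  # doubling detected mutations and plants leaves density unchanged
  expect_equal(bp_per_mutation(1007, 2 * 768, 2 * 21),
               bp_per_mutation(1007, 768, 21))
})

test_that("expected yield matches the published design points", {
  e <- expected_mutations(6912, 1000, 1007 * 768 / 21)
  expect_equal(round(e, 1), 187.7)
  expect_equal(expected_mutations(0, 1000, 5e4), 0)
  e41 <- expected_mutations(6912, 1000, (1007 * 768 / 21) * 47 / 41)
  expect_equal(round_half_up(e41), 164)
})

test_that("nonsense-recovery probability matches closed form and oracle", {
  expect_equal(round(p_at_least_one_nonsense(68.2), 3), 0.974)
  expect_equal(sprintf("%.0f%%", 100 * p_at_least_one_nonsense(68.2)), "97%")
  expect_equal(p_at_least_one_nonsense(0, 0.3), 0)
  expect_equal(p_at_least_one_nonsense(10, 0.5), 1 - 0.5^10)
  # binomial oracle at integer expected counts
  for (n in c(1, 5, 20, 68)) {
    expect_equal(p_at_least_one_nonsense(n, 5 / 96),
                 1 - dbinom(0, n, 5 / 96))
  }
  # monotone in both arguments
  e <- seq(0, 100, by = 5)
  expect_true(all(diff(p_at_least_one_nonsense(e)) > 0))
  f <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(p_at_least_one_nonsense(30, f)) > 0))
})

test_that("population saturation matches the half-the-genome estimate", {
  sat <- saturation_fraction(c(9693, 7717), c(6912, 2304))
  expect_equal(round(sat, 3), 0.484)
  expect_equal(sat, (9693 * 6912 + 7717 * 2304) / (5e8 * 0.35))
  corrected <- saturation_fraction(c(9693, 7717), c(6912, 2304),
                                   collision_corrected = TRUE)
  expect_equal(corrected, 1 - exp(-sat))
  expect_equal(round(corrected, 3), 0.384)
  expect_equal(saturation_fraction(numeric(0), numeric(0)), 0)
  # naive >= collision-corrected for any positive intensity
  set.seed(3)
  for (i in 1:10) {
    loads <- runif(3, 100, 20000)
    n <- sample(100:10000, 3)
    expect_gte(saturation_fraction(loads, n),
               saturation_fraction(loads, n, collision_corrected = TRUE))
  }
})

test_that("exon budget splits a genome-wide load via the census", {
  b <- exon_budget(10000)
  expect_equal(unname(b["exonic"]), 1100)
  expect_equal(unname(b["aa_changing"]), round_half_up(1100 * 63 / 96))
  expect_equal(unname(b["nonsense"]), round_half_up(1100 * 5 / 96))
  expect_equal(unname(exon_budget(0)), c(0, 0, 0))
})

test_that("backcrossing halves the load each generation", {
  expect_equal(backcross_load(10000, 10), 10000 * 0.5^10)
  expect_equal(round_half_up(backcross_load(10000, 10)), 10)
  expect_equal(backcross_load(617, 0), 617)
  expect_equal(backcross_load(617, 1), 308.5)
})

test_that("class composition report compares observed with census", {
  r <- class_composition_report(c(silent = 90, missense = 167, nonsense = 5))
  expect_equal(r$observed, c(90, 167, 5))
  expect_equal(round(r$expected, 1), c(90.1, 158.3, 13.6))
  expect_equal(sum(r$expected), sum(r$observed))
  expect_equal(round(r$observed_fraction[1], 3),
               round(r$expected_fraction[1], 3))  # silent: 0.344 vs 0.344
  # the census composition is its own expectation
  r2 <- class_composition_report(c(silent = 33, missense = 58, nonsense = 5))
  expect_equal(r2$observed, r2$expected)
  expect_error(class_composition_report(c(silent = 0, missense = 0,
                                          nonsense = 0)),
               class = "tillingr_input_error")
})

test_that("assay validation catches schema and range errors", {
  expect_error(screen_assays("g", 0.3, 1000, 0, 5, 100, 100),
               class = "tillingr_input_error")
  expect_error(screen_assays("g", 0.3, 1000, 45, 5, 200, 100),
               class = "tillingr_input_error")
  expect_warning(screen_assays("g", 0.3, 1000, 45, 0, 100, 100),
                 "density undefined")
  expect_error(summarize_assays(data.frame(gene = "g")),
               class = "tillingr_input_error")
})
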