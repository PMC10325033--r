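test_that("count simulation is reproducible and honours degenerate settings", {
  spec <- isoform_sim_spec(seed = 31)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a$counts$counts, b$counts$counts)

  zero_long <- simulate_counts(isoform_sim_spec(long_utr_fraction = 0,
                                                seed = 32))
  expect_true(all(zero_long$counts$counts["utr_long", ] == 0))
  expect_error(isoform_sim_spec(exon_proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(isoform_sim_spec(long_utr_fraction = 1.5), "long_utr_fraction")
})

test_that("in the Poisson limit at huge depth the composition converges to truth", {
  spec <- isoform_sim_spec(dispersion = 0, depth_sdlog = 0, depth_mean = 5e7,
                           n_samples = 4L, seed = 33)
  sim <- simulate_counts(spec)
  ln <- length_normalize(compute_cpm(sim$counts), sim$annotation)
  co <- composition(exon_usage(ln, sim$annotation), sim$grouping)
  expect_equal(co$composition_pct,
               unname(sim$truth$expected_composition_pct[co$exon]),
               tolerance = 0.1 / 25)  # within 0.1 percentage point
})

test_that("junction simulation's truth record matches the filter on extremes", {
  all_mito <- simulate_junctions(30, 10, prevalence_profile = 1,
                                 mito_fraction = 1, seed = 41)
  expect_equal(nrow(filter_junctions(all_mito$tables)), 0L)
  expect_false(any(all_mito$truth$survives_filter))

  clean <- simulate_junctions(30, 10, prevalence_profile = 1,
                              mito_fraction = 0, noncanonical_fraction = 0,
                              seed = 42)
  out <- filter_junctions(clean$tables)
  expect_equal(nrow(out), 30L)
  expect_true(all(clean$truth$survives_filter))
  tr <- clean$truth
  expect_setequal(junction_keys(out),
                  paste(tr$chrom, tr$intron_start, tr$intron_end,
                        tr$strand_code))
})

test_that("random junction specs are scored exactly by their truth record", {
  for (seed in 51:60) {
    sim <- simulate_junctions(40, 15, mito_fraction = 0.15,
                              noncanonical_fraction = 0.15, seed = seed)
    out <- filter_junctions(sim$tables)
    tr <- sim$truth[sim$truth$survives_filter, ]
    expect_setequal(junction_keys(out),
                    paste(tr$chrom, tr$intron_start, tr$intron_end,
                          tr$strand_code))
  }
})

test_that("phage-display simulation is seeded and validates its epitope", {
  spec <- mva_sim_spec(n_unique_peptides = 300, seed = 61)
  a <- simulate_mva(spec)
  b <- simulate_mva(spec)
  expect_identical(a$selected, b$selected)
  expect_equal(anyDuplicated(a$selected$sequence), 0L)
  expect_identical(a$selected$sequence, a$input$sequence)
  expect_error(mva_sim_spec(epitope_interval = c(147, 150)),
               "shorter than min_matches")
})

test_that("without epitope carriers no epitope is called downstream", {
  sim <- simulate_mva(mva_sim_spec(epitope_peptide_fraction = 0,
                                   n_unique_peptides = 500, seed = 63))
  tgt <- neurotrophin_targets()[["BDNF_precursor_synthetic"]]
  prof <- fold_enrichment(
    alignment_load(normalize_library(sim$selected), tgt),
    alignment_load(normalize_library(sim$input), tgt))
  expect_null(call_epitope(prof, tgt))
})

test_that("epitope carriers match the target across the whole planted interval", {
  sim <- simulate_mva(mva_sim_spec(seed = 64))
  tgt <- neurotrophin_targets()[["BDNF_precursor_synthetic"]]
  hit <- Reduce(`|`, lapply(sim$truth$epitope_peptides[1:50], function(p) {
    v <- logical(nchar(tgt)); v[align_peptide(p, tgt)] <- TRUE; v
  }))
  expect_true(all(hit[147:155]))          # every epitope residue is exercised
  expect_false(any(hit[-(147:155)]))      # and nothing outside it
})
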