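test_that("library normalization merges duplicates and sums to one", {
  lib <- normalize_library(data.frame(
    sequence = c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "AAAAAAAAAAAA"),
    raw_count = c(2, 1, 1)))
  expect_equal(nrow(lib), 2L)
  expect_equal(lib$normalized_count[lib$sequence == "AAAAAAAAAAAA"], 0.75)
  expect_equal(sum(lib$normalized_count), 1)

  single <- normalize_library(data.frame(sequence = "ACDEFGHIKLMN",
                                         raw_count = 5))
  expect_equal(single$normalized_count, 1)

  set.seed(11)
  seqs <- apply(matrix(sample(AA20, 50 * 12, TRUE), 50), 1, paste, collapse = "")
  lib <- normalize_library(data.frame(sequence = seqs,
                                      raw_count = sample(1:100, 50, TRUE)))
  expect_equal(sum(lib$normalized_count), 1, tolerance = 1e-12)

  expect_warning(normalize_library(data.frame(
    sequence = c("ACDEFGHIKLMN", "TOOSHORT", "ACDEFGHIKLMX"),
    raw_count = c(1, 1, 1))), "dropped")
  expect_error(normalize_library(data.frame(sequence = "ACDEFGHIKLMN",
                                            raw_count = 0)), "zero")
})

test_that("peptide alignment needs at least min_matches identities", {
  prot <- "MMMMMACDEFGHIKLMNPQRST"
  # identical to the window starting at 6
  expect_equal(align_peptide("ACDEFGHIKLMN", prot), 6:17)
  # five identities only: no qualifying offset
  pep5 <- "ACDEFWWWWWWW"
  expect_equal(align_peptide(pep5, prot), integer())
  # exactly six qualifies, and only matched positions are returned
  pep6 <- "ACDEFGWWWWWW"
  expect_equal(align_peptide(pep6, prot), 6:11)
  # short protein: empty with a warning
  expect_warning(res <- align_peptide("ACDEFGHIKLMN", "ACDEF"), "shorter")
  expect_equal(res, integer())
})

test_that("alignment load removes the top peptide at each position", {
  prot <- paste(rep("A", 20), collapse = "")
  lib <- normalize_library(data.frame(
    sequence = c("AAAAAAAAAAAA", "AAAAAAAAAAAC"),
    raw_count = c(3, 1)))
  prof <- alignment_load(lib, prot)
  # both peptides hit every interior position; top (0.75) removed leaves 0.25
  expect_equal(prof$load[12], 0.25)
  # a position supported by a single peptide scores 0
  single <- normalize_library(data.frame(sequence = "AAAAAAAAAAAA",
                                         raw_count = 10))
  expect_equal(alignment_load(single, prot)$load, rep(0, 20))
  # without the guard the full sum is kept, and never below the guarded load
  cfg <- mva_config(drop_top_peptide = FALSE)
  prof2 <- alignment_load(lib, prot, cfg)
  expect_equal(prof2$load[12], 1)
  expect_true(all(prof2$load >= prof$load))
})

test_that("raising min_matches never increases any position's load", {
  set.seed(12)
  for (i in 1:10) {
    inst <- random_mva_instance()
    prev <- NULL
    for (mm in c(4L, 6L, 8L, 10L)) {
      load <- alignment_load(inst$library, inst$protein,
                             mva_config(min_matches = mm))$load
      if (!is.null(prev)) expect_true(all(load <= prev + 1e-12))
      prev <- load
    }
  }
})

test_that("profiles are invariant to peptide order and duplicate splitting", {
  set.seed(13)
  inst <- random_mva_instance()
  raw <- data.frame(sequence = inst$library$sequence,
                    raw_count = inst$library$raw_count)
  shuffled <- raw[sample(nrow(raw)), ]
  split_dup <- rbind(raw, raw)  # every row twice at half the weight each
  split_dup$raw_count <- split_dup$raw_count / 2
  base <- alignment_load(normalize_library(raw), inst$protein)
  expect_equal(alignment_load(normalize_library(shuffled), inst$protein)$load,
               base$load)
  expect_equal(alignment_load(normalize_library(split_dup), inst$protein)$load,
               base$load)
})

test_that("fold enrichment applies the pseudocount contract", {
  prof <- function(load) structure(
    data.frame(position = seq_along(load), residue = "A", load = load),
    class = c("alignment_load_profile", "data.frame"))
  fe <- fold_enrichment(prof(c(0.2, 0, 0.3)), prof(c(0.2, 0.1, 0)))
  expect_equal(fe$fold_enrichment[1], 1)
  expect_lt(fe$fold_enrichment[2], 1e-7)      # selected 0: ~pseudocount ratio
  expect_gt(fe$fold_enrichment[3], 1e7)       # input 0: large but finite
  expect_true(is.finite(fe$fold_enrichment[3]))
  expect_error(fold_enrichment(prof(1:3 / 10), prof(1:4 / 10)), "different length")
})

test_that("epitope calling picks the longest qualifying run with tie-breaks", {
  prot <- paste(rep("A", 30), collapse = "")
  prof <- function(fold) structure(
    data.frame(position = seq_along(fold), residue = "A", load = 0,
               input_load = 0, fold_enrichment = fold),
    class = c("alignment_load_profile", "data.frame"))
  expect_null(call_epitope(prof(rep(1, 30)), prot))
  f <- rep(1, 30); f[10:16] <- 8
  cl <- call_epitope(prof(f), prot)
  expect_equal(c(cl$start, cl$end), c(10, 16))
  # run below the minimum length is ignored
  f <- rep(1, 30); f[10:12] <- 50
  expect_null(call_epitope(prof(f), prot))
  # equal-length runs: the one with the higher peak wins
  f <- rep(1, 30); f[3:7] <- 6; f[20:24] <- c(6, 6, 9, 6, 6)
  cl <- call_epitope(prof(f), prot)
  expect_equal(c(cl$start, cl$end), c(20, 24))
})

test_that("identical selected and input libraries show no binding anywhere", {
  set.seed(14)
  sim <- simulate_mva(mva_sim_spec(enrichment_factor = 1,
                                   n_unique_peptides = 400, seed = 21))
  expect_identical(sim$selected, sim$input)
  lib <- normalize_library(sim$selected)
  screen <- cross_reactivity_screen(lib, as.list(neurotrophin_targets()),
                                    lib)
  for (res in screen) {
    expect_equal(max(res$profile$fold_enrichment), 1)
    expect_false(res$specific_binding)
  }
})

test_that("a library selected against one target calls no epitope on another", {
  sim <- simulate_mva(mva_sim_spec(seed = 33, n_unique_peptides = 800))
  tg <- neurotrophin_targets()
  screen <- cross_reactivity_screen(
    normalize_library(sim$selected),
    list(BDNF = tg[["BDNF_precursor_synthetic"]],
         NGF = tg[["NGF_precursor_synthetic"]]),
    normalize_library(sim$input))
  expect_true(screen$BDNF$specific_binding)
  expect_equal(c(screen$BDNF$call$start, screen$BDNF$call$end), c(147, 155))
  expect_false(screen$NGF$specific_binding)
})
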