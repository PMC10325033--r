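toy_annotation <- function() {
  feature_annotation(
    feature_id = c("exonI", "exonIV", "cds", "utr_short", "utr_long"),
    chrom = "chr2", start = c(1L, 2001L, 4001L, 6001L, 8001L),
    end = c(1000L, 3000L, 5000L, 6500L, 10000L), strand = "+",
    role = c("five_prime_exon", "five_prime_exon", "cds", "utr_short",
             "utr_long_extension"),
    gene_id = "Bdnf")
}

toy_counts <- function(values, samples = c("s1", "s2")) {
  m <- matrix(values, nrow = 5, dimnames = list(
    c("exonI", "exonIV", "cds", "utr_short", "utr_long"), samples))
  count_matrix(m)
}

test_that("cpm follows its definition and columns sum to 1e6 over a full annotation", {
  cm <- count_matrix(matrix(c(10, 90), 2, 1,
                            dimnames = list(c("a", "b"), "s1")),
                     assigned_totals = 100)
  expect_equal(compute_cpm(cm)["a", "s1"], 100000)
  expect_equal(compute_cpm(cm)["b", "s1"], 900000)

  set.seed(5)
  m <- matrix(rpois(50, 40), 10, 5,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  cpm <- compute_cpm(count_matrix(m))
  expect_equal(unname(colSums(cpm)), rep(1e6, 5))
  # invariant under uniform scaling of counts and totals
  cpm2 <- compute_cpm(count_matrix(m * 7, assigned_totals = colSums(m) * 7))
  expect_equal(cpm2, cpm)
  expect_error(compute_cpm(count_matrix(m, assigned_totals = c(0, colSums(m)[-1]))),
               "assigned total is zero.*s1")
})

test_that("length normalization divides by feature length in kb and is invertible", {
  ann <- toy_annotation()
  cpm <- matrix(500, 5, 1, dimnames = list(ann$feature_id, "s1"))
  ln <- length_normalize(cpm, ann)
  expect_equal(ln["exonIV", "s1"], 500)         # 1000 bp feature: identity
  expect_equal(ln["utr_short", "s1"], 1000)     # 500 bp
  expect_equal(ln["utr_long", "s1"], 250)       # 2000 bp
  set.seed(6)
  cpm <- matrix(runif(10, 0, 1e4), 5, 2,
                dimnames = list(ann$feature_id, c("s1", "s2")))
  ln <- length_normalize(cpm, ann)
  expect_equal(ln * (ann$length_bp / 1000), cpm)
  expect_error(length_normalize(rbind(cpm, zz = 1), ann), "missing from annotation")
})

test_that("exon usage divides exon lnCPM by CDS lnCPM and flags weak samples", {
  ann <- toy_annotation()
  ln <- matrix(c(30, 10, 60, 5, 5,      # s1: CDS 60
                 1, 2, 0.05, 1, 1),     # s2: CDS below the 0.1 default
               5, 2, dimnames = list(ann$feature_id, c("s1", "s2")))
  u <- exon_usage(ln, ann)
  expect_equal(u["exonI", "s1"], 0.5)
  expect_equal(u["exonIV", "s1"], 10 / 60)
  expect_true(all(is.na(u[, "s2"])))
  ln0 <- ln; ln0["exonI", "s1"] <- 0
  expect_equal(exon_usage(ln0, ann)["exonI", "s1"], 0)
  noCds <- ann[ann$role != "cds", ]
  expect_error(exon_usage(ln, noCds), "cds")
})

test_that("composition turns group sums into percentages that sum to 100", {
  u <- matrix(c(1, 3), 2, 1, dimnames = list(c("I", "IV"), "s1"))
  co <- composition(u, c(s1 = "g"))
  expect_equal(co$composition_pct, c(25, 75))

  u <- matrix(1, 4, 3, dimnames = list(paste0("e", 1:4), paste0("s", 1:3)))
  co <- composition(u, c(s1 = "a", s2 = "a", s3 = "b"))
  expect_equal(co$composition_pct, rep(25, 8))

  # a group whose only sample is undefined is flagged, not dropped
  u <- matrix(c(1, 3, NA, NA), 2, 2, dimnames = list(c("I", "IV"), c("s1", "s2")))
  co <- composition(u, c(s1 = "a", s2 = "b"))
  expect_true(all(co$defined[co$group == "a"]))
  expect_false(any(co$defined[co$group == "b"]))
  expect_true(all(is.na(co$composition_pct[co$group == "b"])))
})

test_that("group-level outputs are invariant to sample order", {
  set.seed(8)
  u <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("e", 1:4), paste0("s", 1:10)))
  grouping <- setNames(rep(c("a", "b"), each = 5), colnames(u))
  co1 <- composition(u, grouping)
  perm <- sample(10)
  co2 <- composition(u[, perm], grouping)
  co2 <- co2[match(paste(co1$exon, co1$group), paste(co2$exon, co2$group)), ]
  expect_equal(co1$composition_pct, co2$composition_pct)
})

test_that("long-3'UTR proportion is extension lnCPM over CDS lnCPM", {
  ann <- toy_annotation()
  ln <- matrix(c(1, 1, 40, 1, 40,
                 1, 1, 40, 1, 0), 5, 2,
               dimnames = list(ann$feature_id, c("s1", "s2")))
  p <- long_utr_proportion(ln, ann)
  expect_equal(unname(p["s1"]), 1.0)  # all transcripts carry the long UTR
  expect_equal(unname(p["s2"]), 0.0)
  noExt <- ann[ann$role != "utr_long_extension", ]
  expect_error(long_utr_proportion(ln, noExt), "utr_long_extension")
})

test_that("pre-analyzed exon ratios are per-sample percentages", {
  lv <- matrix(c(2, 2, 0, 5, 0, 0), 2, 3,
               dimnames = list(c("I", "IV"), c("s1", "s2", "s3")))
  r <- exon_ratio_preanalyzed(lv)
  expect_equal(unname(r[, "s1"]), c(50, 50))
  expect_equal(unname(r[, "s2"]), c(0, 100))
  expect_true(all(is.na(r[, "s3"])))
  set.seed(9)
  lv <- matrix(runif(60, 0.01, 10), 6, 10)
  expect_equal(unname(colSums(exon_ratio_preanalyzed(lv))), rep(100, 10),
               tolerance = 1e-12)
})
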