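#' Specification for simulated isoform count data
#'
#' Describes the generating model of [simulate_counts()]: a gene transcribed
#' from alternative promoters (one 5' exon per transcript class), a CDS
#' shared by all transcripts, a short 3'UTR segment shared by all transcripts
#' and a long-3'UTR extension carried by a fraction of them. Expected read
#' counts follow a coverage model — transcript-class abundance times feature
#' length — with negative-binomial sampling noise and log-normally varying
#' per-sample depth. Defaults mirror a typical bulk RNA-seq design: four 5'
#' exons at proportions 0.10/0.15/0.50/0.25, a 30% long-3'UTR fraction,
#' 20 samples at one million assigned reads, dispersion 0.1.
#'
#' @param exon_proportions named non-negative weights per 5' exon, summing
#'   to 1.
#' @param long_utr_fraction fraction of transcripts carrying the long 3'UTR,
#'   in `[0, 1]`.
#' @param feature_lengths named bp lengths for the CDS (`cds`), short UTR
#'   (`utr_short`), long-UTR extension (`utr_long`) and each 5' exon.
#' @param depth_mean expected assigned reads per sample.
#' @param depth_sdlog log-normal sdlog of per-sample depth around
#'   `depth_mean` (0 = constant depth). Default 0.25.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`, the edgeR convention); 0 gives Poisson counts.
#' @param n_samples number of samples.
#' @param groups group label per sample (recycled); default one group.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return an `isoform_sim_spec` list.
#' @export
isoform_sim_spec <- function(exon_proportions = c(exonI = 0.10, exonII = 0.15,
                                                  exonIV = 0.50, exonVI = 0.25),
                             long_utr_fraction = 0.30,
                             feature_lengths = c(cds = 750, utr_short = 350,
                                                 utr_long = 2700,
                                                 exonI = 300, exonII = 250,
                                                 exonIV = 400, exonVI = 350),
                             depth_mean = 1e6, depth_sdlog = 0.25,
                             dispersion = 0.1, n_samples = 20L,
                             groups = "all", seed = 1L) {
  if (abs(sum(exon_proportions) - 1) > 1e-8)
    stop("exon_proportions must sum to 1")
  if (any(exon_proportions < 0)) stop("exon_proportions must be non-negative")
  if (long_utr_fraction < 0 || long_utr_fraction > 1)
    stop("long_utr_fraction must be in [0, 1]")
  miss <- setdiff(c("cds", "utr_short", "utr_long", names(exon_proportions)),
                  names(feature_lengths))
  if (length(miss))
    stop("feature_lengths missing entries: ", paste(miss, collapse = ", "))
  stopifnot(depth_mean > 0, depth_sdlog >= 0, dispersion >= 0, n_samples >= 1L)
  structure(list(exon_proportions = exon_proportions,
                 long_utr_fraction = long_utr_fraction,
                 feature_lengths = feature_lengths,
                 depth_mean = depth_mean, depth_sdlog = depth_sdlog,
                 dispersion = dispersion, n_samples = as.integer(n_samples),
                 groups = groups, seed = as.integer(seed)),
            class = "isoform_sim_spec")
}

.sim_annotation <- function(spec) {
  exon_ids <- names(spec$exon_proportions)
  ids <- c(exon_ids, "cds", "utr_short", "utr_long")
  lens <- as.integer(spec$feature_lengths[ids])
  starts <- cumsum(c(1L, utils::head(lens, -1L) + 1000L))  # spaced along one contig
  feature_annotation(
    feature_id = ids, chrom = "chr2",
    start = starts, end = starts + lens - 1L, strand = "+",
    role = c(rep("five_prime_exon", length(exon_ids)), "cds", "utr_short",
             "utr_long_extension"),
    gene_id = "Bdnf_sim")
}

#' Simulate an isoform-structured count matrix
#'
#' Draws a features-x-samples count matrix under the coverage model of
#' [isoform_sim_spec()]: the expected count of a 5' exon is proportional to
#' its transcript-class proportion times its length, the CDS and short UTR to
#' total transcript abundance times their lengths, and the long-UTR extension
#' to the long fraction times its length. The truth record carries the
#' generating proportions, so downstream estimates can be scored without
#' re-deriving expectations.
#'
#' @param spec an [isoform_sim_spec()].
#' @return list with `counts` (a [count_matrix()] whose assigned totals are
#'   the column sums over this full annotation), `annotation`, `grouping`
#'   (named vector sample -> group) and `truth` (`exon_proportions`,
#'   `expected_composition_pct`, `long_utr_fraction`).
#' @export
simulate_counts <- function(spec = isoform_sim_spec()) {
  stopifnot(inherits(spec, "isoform_sim_spec"))
  set.seed(spec$seed)
  ann <- .sim_annotation(spec)
  exon_ids <- names(spec$exon_proportions)
  weights <- c(spec$exon_proportions * spec$feature_lengths[exon_ids],
               cds = unname(spec$feature_lengths["cds"]),
               utr_short = unname(spec$feature_lengths["utr_short"]),
               utr_long = unname(spec$long_utr_fraction *
                                   spec$feature_lengths["utr_long"]))
  weights <- weights[ann$feature_id]
  depth <- if (spec$depth_sdlog > 0) {
    stats::rlnorm(spec$n_samples,
                  meanlog = log(spec$depth_mean) - spec$depth_sdlog^2 / 2,
                  sdlog = spec$depth_sdlog)
  } else rep(spec$depth_mean, spec$n_samples)
  mu <- outer(weights / sum(weights), depth)
  counts <- if (spec$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           nrow = nrow(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
  }
  dimnames(counts) <- list(ann$feature_id,
                           sprintf("sample_%02d", seq_len(spec$n_samples)))
  grouping <- stats::setNames(rep_len(as.character(spec$groups),
                                      spec$n_samples), colnames(counts))
  truth <- list(
    exon_proportions = spec$exon_proportions,
    expected_composition_pct = 100 * spec$exon_proportions /
      sum(spec$exon_proportions),
    long_utr_fraction = spec$long_utr_fraction)
  list(counts = count_matrix(counts), annotation = ann, grouping = grouping,
       truth = truth)
}

#' Simulate per-sample splice-junction tables
#'
#' Plants `n_junctions` junctions with controlled per-junction detection
#' prevalence, mitochondrial placement and non-canonical-motif fraction, and
#' emits one STAR-style table per sample containing the junctions detected in
#' that sample. The truth record states, for each planted junction, how many
#' samples detected it and whether it survives the default prevalence filter,
#' so the filter can be scored exactly.
#'
#' @param n_junctions number of planted junctions.
#' @param n_samples number of samples.
#' @param prevalence_profile per-junction detection probability (recycled);
#'   default drawn uniformly on (0, 1).
#' @param mito_fraction fraction of junctions placed on `chrM`.
#' @param noncanonical_fraction fraction of junctions given motif code 0.
#' @param config [junction_filter_config()] used for the truth record's
#'   `survives_filter` flag.
#' @param seed RNG seed.
#' @return list with `tables` (list of [junction_table()], one per sample)
#'   and `truth` (data frame: junction fields, `n_samples_detected`,
#'   `survives_filter`).
#' @export
simulate_junctions <- function(n_junctions = 50L, n_samples = 20L,
                               prevalence_profile = NULL,
                               mito_fraction = 0.1,
                               noncanonical_fraction = 0.1,
                               config = junction_filter_config(),
                               seed = 1L) {
  stopifnot(n_junctions >= 1L, n_samples >= 1L,
            mito_fraction >= 0, mito_fraction <= 1,
            noncanonical_fraction >= 0, noncanonical_fraction <= 1)
  set.seed(seed)
  prev <- if (is.null(prevalence_profile)) stats::runif(n_junctions)
          else rep_len(prevalence_profile, n_junctions)
  is_mito <- stats::runif(n_junctions) < mito_fraction
  chrom <- ifelse(is_mito, "chrM",
                  sample(paste0("chr", 1:19), n_junctions, replace = TRUE))
  motif <- ifelse(stats::runif(n_junctions) < noncanonical_fraction, 0L,
                  sample(1:6, n_junctions, replace = TRUE))
  start <- sample.int(1e6L, n_junctions, replace = TRUE)
  end <- start + sample.int(5000L, n_junctions, replace = TRUE) + 50L
  strand <- sample(0:2, n_junctions, replace = TRUE)
  detected <- matrix(stats::runif(n_junctions * n_samples) <
                       rep(prev, n_samples), n_junctions, n_samples)
  tables <- lapply(seq_len(n_samples), function(s) {
    idx <- which(detected[, s])
    junction_table(chrom = chrom[idx], intron_start = start[idx],
                   intron_end = end[idx], strand_code = strand[idx],
                   motif_code = motif[idx], annotated_flag = 0L,
                   unique_reads = stats::rpois(length(idx), 5) + 1L,
                   multi_reads = stats::rpois(length(idx), 1),
                   overhang = sample(10:50, length(idx), replace = TRUE))
  })
  n_det <- rowSums(detected)
  thr <- detection_threshold(n_samples, config$prevalence_fraction)
  truth <- data.frame(chrom = chrom, intron_start = start, intron_end = end,
                      strand_code = strand, motif_code = motif,
                      n_samples_detected = n_det,
                      survives_filter = !(chrom %in% config$mito_chrom_names) &
                        motif != 0L & n_det >= thr)
  list(tables = tables, truth = truth)
}

#' Specification for a simulated phage-display selection
#'
#' Describes the generating model of [simulate_mva()]: a library of unique
#' random 12-mers with near-uniform input counts, of which a fraction carry a
#' contiguous subsequence (length at least `min_matches`) of a planted
#' epitope at a uniformly random register; in the antibody-selected library
#' the epitope carriers' counts are multiplied by `enrichment_factor`.
#' Flanking residues of an epitope carrier are sampled to mismatch the target
#' at their aligned positions, so the planted signal — and hence the truth
#' record — is confined exactly to the epitope interval.
#'
#' @param target target protein sequence; default the package's synthetic
#'   BDNF precursor stand-in ([neurotrophin_targets()]).
#' @param epitope_interval 1-based `c(start, end)` of the planted epitope
#'   within the target; default `c(147, 155)`, the mature-region epitope
#'   position.
#' @param n_unique_peptides number of unique peptides. Default 2000.
#' @param epitope_peptide_fraction fraction of peptides carrying an epitope
#'   subsequence. Default 0.05.
#' @param enrichment_factor selected-library count multiplier for epitope
#'   carriers (>= 1). Default 100.
#' @param peptide_length,min_matches as in [mva_config()].
#' @param seed RNG seed.
#' @return an `mva_sim_spec` list.
#' @export
mva_sim_spec <- function(target = NULL, epitope_interval = c(147L, 155L),
                         n_unique_peptides = 2000L,
                         epitope_peptide_fraction = 0.05,
                         enrichment_factor = 100,
                         peptide_length = 12L, min_matches = 6L,
                         seed = 1L) {
  if (is.null(target))
    target <- neurotrophin_targets()[["BDNF_precursor_synthetic"]]
  target <- as.character(target)
  L <- nchar(target)
  ei <- as.integer(epitope_interval)
  stopifnot(length(ei) == 2L, ei[1] >= 1L, ei[2] <= L, ei[2] >= ei[1])
  if (ei[2] - ei[1] + 1L < min_matches)
    stop("epitope shorter than min_matches; carriers could never qualify")
  stopifnot(n_unique_peptides >= 1L,
            epitope_peptide_fraction >= 0, epitope_peptide_fraction <= 1,
            enrichment_factor >= 1)
  structure(list(target = target, epitope_interval = ei,
                 n_unique_peptides = as.integer(n_unique_peptides),
                 epitope_peptide_fraction = epitope_peptide_fraction,
                 enrichment_factor = enrichment_factor,
                 peptide_length = as.integer(peptide_length),
                 min_matches = as.integer(min_matches),
                 seed = as.integer(seed)),
            class = "mva_sim_spec")
}

.random_peptides <- function(n, k) {
  matrix(sample(.aa_alphabet, n * k, replace = TRUE), n, k)
}

#' Simulate selected and input phage-display libraries
#'
#' @param spec an [mva_sim_spec()].
#' @return list with `selected` and `input` (data frames with `sequence`,
#'   `raw_count`) and `truth` (`epitope_interval`, `epitope_peptides`).
#' @export
simulate_mva <- function(spec = mva_sim_spec()) {
  stopifnot(inherits(spec, "mva_sim_spec"))
  set.seed(spec$seed)
  k <- spec$peptide_length
  tgt <- strsplit(spec$target, "")[[1]]
  L <- length(tgt)
  n <- spec$n_unique_peptides
  n_epi <- round(spec$epitope_peptide_fraction * n)
  ei <- spec$epitope_interval
  epi_len <- ei[2] - ei[1] + 1L

  make_carrier <- function() {
    l <- sample(spec$min_matches:epi_len, 1L)
    epi_start <- ei[1] + sample.int(epi_len - l + 1L, 1L) - 1L
    reg <- sample.int(k - l + 1L, 1L)
    pep <- character(k)
    pep[reg:(reg + l - 1L)] <- tgt[epi_start:(epi_start + l - 1L)]
    for (j in seq_len(k)[-(reg:(reg + l - 1L))]) {
      aligned <- epi_start - reg + j
      pool <- if (aligned >= 1L && aligned <= L)
        setdiff(.aa_alphabet, tgt[aligned]) else .aa_alphabet
      pep[j] <- sample(pool, 1L)
    }
    paste(pep, collapse = "")
  }

  seqs <- c(if (n_epi) vapply(seq_len(n_epi), function(i) make_carrier(),
                              character(1)),
            if (n - n_epi > 0L)
              apply(.random_peptides(n - n_epi, k), 1L, paste, collapse = ""))
  # enforce uniqueness (collisions are vanishingly rare but possible)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- apply(.random_peptides(length(dup), k), 1L, paste,
                       collapse = "")
  }
  input_counts <- sample(90:110, n, replace = TRUE)
  sel_counts <- input_counts
  if (n_epi)
    sel_counts[seq_len(n_epi)] <- as.integer(round(sel_counts[seq_len(n_epi)] *
                                                     spec$enrichment_factor))
  list(selected = data.frame(sequence = seqs, raw_count = sel_counts,
                             stringsAsFactors = FALSE),
       input = data.frame(sequence = seqs, raw_count = input_counts,
                          stringsAsFactors = FALSE),
       truth = list(epitope_interval = ei,
                    epitope_peptides = if (n_epi) seqs[seq_len(n_epi)]
                                       else character()))
}
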