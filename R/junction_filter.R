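#' Junction filter configuration
#'
#' Parameters of the two-pass splice-junction filter applied between STAR
#' passes: junctions on mitochondrial contigs and junctions with a
#' non-canonical intron motif are removed, and only junctions detected in at
#' least a given fraction of the dataset's samples (rounded up to the nearest
#' integer number of samples) are kept.
#'
#' @param prevalence_fraction fraction of samples a junction must be detected
#'   in, in (0, 1]. Default 0.10.
#' @param mito_chrom_names chromosome names treated as mitochondrial.
#'   Default `c("chrM", "MT")`.
#' @param detection_min_unique_reads minimum uniquely mapping reads for a
#'   junction to count as detected in a sample. Default 1.
#' @return a `junction_filter_config` list.
#' @export
junction_filter_config <- function(prevalence_fraction = 0.10,
                                   mito_chrom_names = c("chrM", "MT"),
                                   detection_min_unique_reads = 1L) {
  stopifnot(length(prevalence_fraction) == 1L,
            prevalence_fraction > 0, prevalence_fraction <= 1,
            detection_min_unique_reads >= 1L)
  structure(list(prevalence_fraction = prevalence_fraction,
                 mito_chrom_names = as.character(mito_chrom_names),
                 detection_min_unique_reads = as.integer(detection_min_unique_reads)),
            class = "junction_filter_config")
}

#' Sample-detection threshold for junction prevalence
#'
#' The number of samples a junction must be detected in:
#' `ceiling(prevalence_fraction * n_samples)`, never below 1. The product is
#' nudged by 1e-9 before `ceiling()` so that binary floating point cannot push
#' an exact integer (e.g. 0.1 * 30) over the next boundary.
#'
#' @param n_samples number of samples in the dataset (>= 1).
#' @param prevalence_fraction fraction in (0, 1].
#' @return integer threshold.
#' @export
#' @examples
#' detection_threshold(25, 0.10) # 3
#' detection_threshold(10, 0.10) # 1
detection_threshold <- function(n_samples, prevalence_fraction = 0.10) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1)
    stop("n_samples must be a single integer >= 1")
  stopifnot(prevalence_fraction > 0, prevalence_fraction <= 1)
  max(1L, as.integer(ceiling(prevalence_fraction * n_samples - 1e-9)))
}

.sj_cols <- c("chrom", "intron_start", "intron_end", "strand_code",
              "motif_code", "annotated_flag", "unique_reads", "multi_reads",
              "overhang")

#' Construct a splice-junction table
#'
#' One row per junction with the nine STAR `SJ.out.tab` fields. Intron
#' coordinates are 1-based and inclusive (first and last base of the intron);
#' `motif_code` 0 means a non-canonical intron motif, 1-6 the canonical
#' dinucleotide motifs; `unique_reads` is STAR's count of uniquely mapping
#' supporting reads.
#'
#' @param chrom,intron_start,intron_end,strand_code,motif_code,annotated_flag,unique_reads,multi_reads,overhang
#'   vectors of equal length mirroring the SJ.out.tab columns.
#' @return a `junction_table` data frame.
#' @export
junction_table <- function(chrom, intron_start, intron_end,
                           strand_code = 0L, motif_code = 1L,
                           annotated_flag = 0L, unique_reads = 0L,
                           multi_reads = 0L, overhang = 0L) {
  n <- length(chrom)
  jt <- data.frame(chrom = as.character(chrom),
                   intron_start = as.integer(intron_start),
                   intron_end = as.integer(intron_end),
                   strand_code = rep_len(as.integer(strand_code), n),
                   motif_code = rep_len(as.integer(motif_code), n),
                   annotated_flag = rep_len(as.integer(annotated_flag), n),
                   unique_reads = rep_len(as.integer(unique_reads), n),
                   multi_reads = rep_len(as.integer(multi_reads), n),
                   overhang = rep_len(as.integer(overhang), n),
                   stringsAsFactors = FALSE)
  if (any(jt$intron_end < jt$intron_start))
    stop("intron_end < intron_start in junction table")
  if (any(jt$unique_reads < 0L) || any(jt$multi_reads < 0L))
    stop("negative read counts in junction table")
  class(jt) <- c("junction_table", "data.frame")
  jt
}

#' Read a STAR SJ.out.tab file
#'
#' @param path path to a headerless 9-column tab-separated junction table.
#' @return a [junction_table()].
#' @export
read_sj <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", rep("integer", 8L)))
  if (ncol(raw) != 9L) stop("expected 9 columns in SJ.out.tab file: ", path)
  names(raw) <- .sj_cols
  do.call(junction_table, raw)
}

#' Write a junction table in SJ.out.tab format
#'
#' @param jt a [junction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sj <- function(jt, path) {
  utils::write.table(jt[, .sj_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.junction_key <- function(jt) {
  paste(jt$chrom, jt$intron_start, jt$intron_end, jt$strand_code, sep = "\r")
}

#' Filter splice junctions by prevalence, motif and chromosome
#'
#' Pools the first-pass junction tables of a dataset and keeps the junctions
#' that (a) do not lie on a mitochondrial contig, (b) have a canonical intron
#' motif (`motif_code != 0`), and (c) are detected (`unique_reads >=
#' detection_min_unique_reads`) in at least [detection_threshold()] samples.
#' Junction identity is `(chrom, intron_start, intron_end, strand_code)`.
#'
#' The surviving junctions are returned as one deduplicated table sorted by
#' `(chrom, intron_start, intron_end)`, with `unique_reads` and `multi_reads`
#' summed over samples and `overhang` the per-junction maximum — the
#' coordinate fields are what a second STAR pass consumes.
#'
#' @param per_sample_tables a non-empty list of [junction_table()]s, one per
#'   sample.
#' @param config a [junction_filter_config()].
#' @return a [junction_table()] of surviving junctions.
#' @export
filter_junctions <- function(per_sample_tables,
                             config = junction_filter_config()) {
  if (!is.list(per_sample_tables) || inherits(per_sample_tables, "data.frame"))
    per_sample_tables <- list(per_sample_tables)
  n_samples <- length(per_sample_tables)
  if (n_samples < 1L) stop("need at least one sample junction table")
  thr <- detection_threshold(n_samples, config$prevalence_fraction)

  pooled <- do.call(rbind, lapply(seq_along(per_sample_tables), function(i) {
    jt <- per_sample_tables[[i]]
    jt$.sample <- rep(i, nrow(jt))
    jt
  }))
  if (!nrow(pooled)) return(junction_table(character(), integer(), integer()))
  key <- .junction_key(pooled)

  detected <- pooled$unique_reads >= config$detection_min_unique_reads
  # count distinct samples in which each junction is detected
  ks <- paste(key, pooled$.sample, sep = "\r")
  det_by_ks <- tapply(detected, ks, any)
  kk <- sub("\r[0-9]+$", "", names(det_by_ks))
  n_detected <- tapply(as.logical(det_by_ks), kk, sum)

  first <- pooled[!duplicated(key), , drop = FALSE]
  fkey <- key[!duplicated(key)]
  keep <- !(first$chrom %in% config$mito_chrom_names) &
    first$motif_code != 0L &
    as.integer(n_detected[fkey]) >= thr
  kept_keys <- fkey[keep]

  sel <- key %in% kept_keys
  agg_u <- tapply(pooled$unique_reads[sel], key[sel], sum)
  agg_m <- tapply(pooled$multi_reads[sel], key[sel], sum)
  agg_o <- tapply(pooled$overhang[sel], key[sel], max)
  out <- first[keep, .sj_cols, drop = FALSE]
  okey <- fkey[keep]
  out$unique_reads <- as.integer(agg_u[okey])
  out$multi_reads <- as.integer(agg_m[okey])
  out$overhang <- as.integer(agg_o[okey])
  out <- out[order(out$chrom, out$intron_start, out$intron_end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("junction_table", "data.frame")
  out
}
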