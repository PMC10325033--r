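#' Construct a count matrix
#'
#' Raw feature-level read counts (features x samples) together with the
#' per-sample total of reads assigned to all annotated features — the CPM
#' denominator. When the annotation covers every counted feature the assigned
#' total is simply the column sum, the default.
#'
#' @param counts non-negative integer matrix, features in rows (rownames =
#'   feature ids), samples in columns (colnames = sample ids).
#' @param assigned_totals per-sample positive totals of assigned reads;
#'   defaults to `colSums(counts)`.
#' @return a `count_matrix` list with elements `counts`, `assigned_totals`,
#'   `feature_ids`, `sample_ids`.
#' @export
count_matrix <- function(counts, assigned_totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (any(counts < 0)) stop("negative counts")
  assigned_totals <- as.numeric(assigned_totals)
  if (length(assigned_totals) != ncol(counts))
    stop("assigned_totals must have one entry per sample")
  names(assigned_totals) <- colnames(counts)
  structure(list(counts = counts, assigned_totals = assigned_totals,
                 feature_ids = rownames(counts), sample_ids = colnames(counts)),
            class = "count_matrix")
}

#' Read a featureCounts-style counts table
#'
#' Tab-separated, leading comment lines (`#`) tolerated; the first column is
#' the feature id and the remaining numeric columns are samples. Annotation
#' columns featureCounts inserts (`Chr`, `Start`, `End`, `Strand`, `Length`)
#' are dropped if present.
#'
#' @param path path to the counts TSV.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  drop <- intersect(c("Chr", "Start", "End", "Strand", "Length"), names(tab))
  tab <- tab[, setdiff(names(tab), drop), drop = FALSE]
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  count_matrix(m)
}

#' Quantification configuration
#'
#' @param min_cds_lncpm length-normalized CDS CPM below which per-sample
#'   ratios (5' exon usage, long-3'UTR proportion) are flagged undefined
#'   rather than reported: with essentially no gene expression the ratio is
#'   noise. Default 0.1.
#' @param excluded_feature_roles feature roles skipped by the usage
#'   statistics. Default `"other"`.
#' @return a `quant_config` list.
#' @export
quant_config <- function(min_cds_lncpm = 0.1,
                         excluded_feature_roles = "other") {
  stopifnot(min_cds_lncpm >= 0)
  structure(list(min_cds_lncpm = min_cds_lncpm,
                 excluded_feature_roles = as.character(excluded_feature_roles)),
            class = "quant_config")
}

#' Counts per million assigned reads
#'
#' `cpm[f, s] = counts[f, s] / assigned_totals[s] * 1e6`. Over a full
#' annotation (assigned totals equal to the column sums) each column sums to
#' exactly 1e6.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
compute_cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  zero <- which(cm$assigned_totals <= 0)
  if (length(zero))
    stop("assigned total is zero for sample(s): ",
         paste(cm$sample_ids[zero], collapse = ", "))
  sweep(cm$counts, 2L, cm$assigned_totals, "/") * 1e6
}

#' Length-normalize an expression matrix
#'
#' Divides each feature's values by its length in kilobases
#' (`length_bp / 1000`), giving CPM per kb.
#'
#' @param mat numeric matrix with feature rownames (typically CPM).
#' @param ann a [feature_annotation()] covering every row of `mat`.
#' @return matrix of length-normalized values.
#' @export
length_normalize <- function(mat, ann) {
  idx <- match(rownames(mat), ann$feature_id)
  if (anyNA(idx))
    stop("feature(s) missing from annotation: ",
         paste(rownames(mat)[is.na(idx)], collapse = ", "))
  len_kb <- ann$length_bp[idx] / 1000
  mat / len_kb
}

.usage_exons <- function(ann, config) {
  ann$feature_id[ann$role == "five_prime_exon" &
                   !(ann$role %in% config$excluded_feature_roles)]
}

.cds_row <- function(lncpm, ann) {
  cds_id <- ann$feature_id[ann$role == "cds"]
  if (length(cds_id) != 1L)
    stop("annotation must contain exactly one 'cds' feature")
  if (!cds_id %in% rownames(lncpm))
    stop("CDS feature '", cds_id, "' absent from the expression matrix")
  lncpm[cds_id, ]
}

#' 5' exon usage relative to the CDS
#'
#' For every alternative 5' exon and sample, the length-normalized exon CPM
#' divided by the length-normalized CDS CPM of the same sample. Since the CDS
#' is shared by all transcripts, the ratio estimates the fraction of the
#' gene's transcripts initiated at that exon's promoter. Samples whose CDS
#' lnCPM falls below `config$min_cds_lncpm` express the gene too weakly for
#' the calculation and get `NA` (flagged undefined) for every exon.
#'
#' @param lncpm length-normalized CPM matrix ([length_normalize()]).
#' @param ann a [feature_annotation()] with one `cds` feature and the 5'
#'   exons of interest.
#' @param config a [quant_config()].
#' @return matrix of usage ratios, 5' exons x samples, `NA` where undefined.
#' @export
exon_usage <- function(lncpm, ann, config = quant_config()) {
  validate_annotation(ann, require_cds = TRUE)
  exons <- .usage_exons(ann, config)
  if (!length(exons)) stop("annotation contains no 'five_prime_exon' features")
  cds <- .cds_row(lncpm, ann)
  usage <- lncpm[exons, , drop = FALSE] / rep(cds, each = length(exons))
  usage[, cds < config$min_cds_lncpm] <- NA_real_
  usage
}

#' Group composition percentages of 5' exon usage
#'
#' Within each sample group, the usage ratios of each 5' exon are summed over
#' the group's defined samples and divided by the total over all exons, giving
#' the percent contribution of each promoter to the group's transcript pool.
#' Percentages within a defined group sum to 100. A group with no defined
#' sample or an all-zero total is returned with `NA` percentages and
#' `defined = FALSE` rather than dropped.
#'
#' @param usage usage-ratio matrix from [exon_usage()] (`NA` = undefined
#'   sample).
#' @param grouping named character vector mapping sample id to group label
#'   (every sample of `usage` must appear).
#' @return data frame with columns `exon`, `group`, `composition_pct`,
#'   `defined`.
#' @export
composition <- function(usage, grouping) {
  samples <- colnames(usage)
  miss <- setdiff(samples, names(grouping))
  if (length(miss))
    stop("sample(s) missing from grouping: ", paste(miss, collapse = ", "))
  groups <- unique(as.character(grouping[samples]))
  res <- lapply(groups, function(g) {
    in_g <- samples[grouping[samples] == g]
    sub <- usage[, in_g, drop = FALSE]
    defined_samples <- colSums(is.na(sub)) == 0L
    sub <- sub[, defined_samples, drop = FALSE]
    sums <- rowSums(sub)
    total <- sum(sums)
    if (ncol(sub) == 0L || total <= 0) {
      data.frame(exon = rownames(usage), group = g,
                 composition_pct = NA_real_, defined = FALSE)
    } else {
      data.frame(exon = rownames(usage), group = g,
                 composition_pct = 100 * sums / total, defined = TRUE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Long-3'UTR transcript proportion
#'
#' The long-3'UTR extension is present only on distally polyadenylated
#' transcripts while the CDS is present on all, so
#' `lncpm(utr_long_extension) / lncpm(cds)` estimates the fraction of the
#' gene's transcripts carrying the long 3'UTR. Undefined (NA) where the CDS
#' lnCPM is below `config$min_cds_lncpm`.
#'
#' @inheritParams exon_usage
#' @return named numeric vector, one proportion per sample (`NA` =
#'   undefined).
#' @export
long_utr_proportion <- function(lncpm, ann, config = quant_config()) {
  validate_annotation(ann, require_cds = TRUE)
  ext_id <- ann$feature_id[ann$role == "utr_long_extension"]
  if (length(ext_id) != 1L)
    stop("annotation must contain one 'utr_long_extension' feature")
  if (!ext_id %in% rownames(lncpm))
    stop("long-UTR feature '", ext_id, "' absent from the expression matrix")
  cds <- .cds_row(lncpm, ann)
  prop <- lncpm[ext_id, ] / cds
  prop[cds < config$min_cds_lncpm] <- NA_real_
  prop
}

#' Per-sample 5' exon ratios for pre-analyzed expression data
#'
#' For datasets distributed as pre-computed exon or transcript levels (no raw
#' counts), each 5' exon's level is normalized by the sum of all annotated
#' 5' exon (or transcript-class) levels in that sample, expressed in percent.
#' Columns with an all-zero total are flagged undefined (`NA`).
#'
#' @param levels non-negative matrix, exon/transcript classes x samples.
#' @return matrix of percentages summing to 100 per defined sample.
#' @export
exon_ratio_preanalyzed <- function(levels) {
  levels <- as.matrix(levels)
  if (any(levels < 0)) stop("levels must be non-negative")
  totals <- colSums(levels)
  out <- sweep(levels, 2L, totals, "/") * 100
  out[, totals <= 0] <- NA_real_
  out
}
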