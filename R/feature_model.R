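#' Construct a feature annotation
#'
#' A feature annotation partitions a gene into the regions quantified by the
#' downstream expression statistics: alternative non-coding 5' exons (promoter
#' proxies), the common coding sequence (CDS, a proxy for total gene output),
#' the shared short 3'UTR segment and the long-3'UTR extension unique to
#' distally polyadenylated transcripts. Coordinates follow the SAF convention:
#' 1-based, inclusive at both ends, so `length_bp = end - start + 1`.
#'
#' @param feature_id character vector of unique feature labels
#'   (e.g. `"Bdnf_exonI"`, `"Bdnf_CDS"`).
#' @param chrom chromosome name per feature.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param strand `"+"` or `"-"` per feature. Stored for bookkeeping; counts are
#'   feature-assigned upstream, so strand enters no arithmetic here.
#' @param role one of `"five_prime_exon"`, `"cds"`, `"utr_short"`,
#'   `"utr_long_extension"`, `"other"`. Features whose role is listed in
#'   [quant_config()]`$excluded_feature_roles` are skipped by the usage
#'   statistics (the annotation equivalent of "not included" exons).
#' @param gene_id single gene label the features belong to.
#'
#' @return A `feature_annotation`: a data frame with columns `feature_id`,
#'   `chrom`, `start`, `end`, `strand`, `role`, `length_bp` and a `gene_id`
#'   attribute.
#' @export
#' @examples
#' feature_annotation(
#'   feature_id = c("Bdnf_exonI", "Bdnf_CDS"),
#'   chrom = "chr2", start = c(1000L, 5000L), end = c(1300L, 5750L),
#'   strand = "+", role = c("five_prime_exon", "cds"), gene_id = "Bdnf")
feature_annotation <- function(feature_id, chrom, start, end,
                               strand = "+",
                               role = "other",
                               gene_id = "gene") {
  ann <- data.frame(
    feature_id = as.character(feature_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(feature_id)),
    role = rep_len(as.character(role), length(feature_id)),
    stringsAsFactors = FALSE
  )
  ann$length_bp <- ann$end - ann$start + 1L
  attr(ann, "gene_id") <- as.character(gene_id)
  class(ann) <- c("feature_annotation", "data.frame")
  validate_annotation(ann)
  ann
}

.feature_roles <- c("five_prime_exon", "cds", "utr_short",
                    "utr_long_extension", "other")

#' Validate a feature annotation
#'
#' Checks the structural invariants: unique feature ids, positive 1-based
#' coordinates with `end >= start` (every feature has strictly positive
#' length), known roles, at most one CDS and at most one long-3'UTR extension.
#'
#' @param ann a `feature_annotation`.
#' @param require_cds if `TRUE`, additionally require exactly one `cds`
#'   feature (needed by the usage statistics; a bare annotation used only for
#'   counting may lack one).
#' @return `ann`, invisibly. Errors describe the offending feature.
#' @export
validate_annotation <- function(ann, require_cds = FALSE) {
  stopifnot(is.data.frame(ann))
  needed <- c("feature_id", "chrom", "start", "end", "strand", "role")
  miss <- setdiff(needed, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  dup <- ann$feature_id[duplicated(ann$feature_id)]
  if (length(dup))
    stop("duplicate feature_id in annotation: ", paste(unique(dup), collapse = ", "))
  bad <- which(ann$start < 1L | ann$end < ann$start)
  if (length(bad))
    stop("invalid coordinates (need 1 <= start <= end) for feature(s): ",
         paste(ann$feature_id[bad], collapse = ", "))
  unknown <- setdiff(unique(ann$role), .feature_roles)
  if (length(unknown))
    stop("unknown feature role(s): ", paste(unknown, collapse = ", "))
  if (sum(ann$role == "cds") > 1L)
    stop("annotation has more than one 'cds' feature")
  if (sum(ann$role == "utr_long_extension") > 1L)
    stop("annotation has more than one 'utr_long_extension' feature")
  if (require_cds && sum(ann$role == "cds") != 1L)
    stop("annotation must contain exactly one 'cds' feature")
  invisible(ann)
}

#' Read a SAF feature annotation
#'
#' Reads a tab-separated SAF file (the featureCounts annotation dialect:
#' header `GeneID Chr Start End Strand`). A non-standard sixth column `Role`
#' is honoured when present; rows without it get role `"other"`. Coordinates
#' are 1-based inclusive.
#'
#' @param path path to a SAF file.
#' @param gene_id gene label to attach; defaults to the file's base name.
#' @return a [feature_annotation()].
#' @export
read_saf <- function(path, gene_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("SAF file is empty: ", path)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 5L ||
      !identical(toupper(hdr[1:5]), c("GENEID", "CHR", "START", "END", "STRAND")))
    stop("not a SAF header (need GeneID\tChr\tStart\tEnd\tStrand): ", path)
  has_role <- length(hdr) >= 6L && toupper(hdr[[6]]) == "ROLE"
  body <- lines[-1]
  n <- length(body)
  if (!n) {
    ann <- feature_annotation(character(), character(), integer(), integer(),
                              character(), character(),
                              gene_id = gene_id %||% basename(path))
    return(ann)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  want <- if (has_role) 6L else 5L
  lens <- lengths(parts)
  bad <- which(lens < 5L)
  if (length(bad))
    stop("malformed SAF row at line ", bad[[1]] + 1L, " of ", path,
         " (expected at least 5 tab-separated fields)")
  get <- function(i) vapply(parts, function(p) p[[i]], character(1))
  start <- suppressWarnings(as.integer(get(3L)))
  end <- suppressWarnings(as.integer(get(4L)))
  nonnum <- which(is.na(start) | is.na(end))
  if (length(nonnum))
    stop("malformed SAF row at line ", nonnum[[1]] + 1L, " of ", path,
         " (non-numeric Start/End)")
  role <- if (has_role) {
    vapply(parts, function(p) if (length(p) >= 6L && nzchar(p[[6]])) p[[6]] else "other",
           character(1))
  } else rep("other", n)
  feature_annotation(
    feature_id = get(1L), chrom = get(2L), start = start, end = end,
    strand = get(5L), role = role,
    gene_id = gene_id %||% basename(path))
}

#' Write a SAF feature annotation
#'
#' Emits a tab-separated SAF file with the stable column order
#' `GeneID Chr Start End Strand Role`; [read_saf()] of the result reproduces
#' the annotation field by field.
#'
#' @param ann a valid [feature_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saf <- function(ann, path) {
  validate_annotation(ann)
  out <- data.frame(GeneID = ann$feature_id, Chr = ann$chrom,
                    Start = ann$start, End = ann$end,
                    Strand = ann$strand, Role = ann$role)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("Feature annotation for gene '", attr(x, "gene_id") %||% "?",
      "' (", nrow(x), " features)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
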