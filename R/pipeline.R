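#' Read a sample-grouping YAML file
#'
#' A flat mapping `sample_id: group_label`.
#'
#' @param path YAML file path.
#' @return named character vector sample -> group.
#' @export
read_grouping <- function(path) {
  g <- yaml::read_yaml(path)
  if (!length(g)) stop("grouping file is empty: ", path)
  stats::setNames(vapply(g, as.character, character(1)), names(g))
}

.write_tidy <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_manifest <- function(out_dir, files, params) {
  manifest <- list(
    package = "bdnfkit",
    version = as.character(utils::packageVersion("bdnfkit")),
    parameters = params,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the expression-quantification pipeline
#'
#' End-to-end: CPM, length-normalized CPM, 5' exon usage relative to the CDS,
#' group composition percentages and the long-3'UTR proportion, written as
#' tidy tab-separated tables plus a JSON manifest with parameters and file
#' checksums. Deterministic: identical inputs give byte-identical tables.
#'
#' @param counts a [count_matrix()] or path to a featureCounts-style TSV.
#' @param annotation a [feature_annotation()] or path to a SAF file.
#' @param grouping named vector sample -> group, or path to a grouping YAML.
#' @param out_dir output directory (created if absent).
#' @param config a [quant_config()].
#' @return invisibly, a list with the computed `cpm`, `lncpm`, `usage`,
#'   `composition`, `long_utr` and the output file paths.
#' @export
run_expression <- function(counts, annotation, grouping, out_dir,
                           config = quant_config()) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(annotation)) annotation <- read_saf(annotation)
  if (is.character(grouping) && length(grouping) == 1L &&
      file.exists(grouping)) grouping <- read_grouping(grouping)
  if (!length(grouping)) stop("empty sample grouping")
  validate_annotation(annotation, require_cds = TRUE)

  cpm <- compute_cpm(counts)
  lncpm <- length_normalize(cpm, annotation)
  usage <- exon_usage(lncpm, annotation, config)
  comp <- composition(usage, grouping)
  lutr <- long_utr_proportion(lncpm, annotation, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat2tidy <- function(m) {
    data.frame(feature = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), defined = !is.na(as.vector(m)))
  }
  expr <- data.frame(feature = rep(rownames(cpm), ncol(cpm)),
                     sample = rep(colnames(cpm), each = nrow(cpm)),
                     cpm = as.vector(cpm), lncpm = as.vector(lncpm))
  files <- c(
    .write_tidy(expr, file.path(out_dir, "expression.tsv")),
    .write_tidy(mat2tidy(usage), file.path(out_dir, "exon_usage.tsv")),
    .write_tidy(comp, file.path(out_dir, "composition.tsv")),
    .write_tidy(data.frame(sample = names(lutr),
                           long_utr_proportion = as.numeric(lutr),
                           defined = !is.na(lutr)),
                file.path(out_dir, "long_utr.tsv")))
  n_undef <- sum(is.na(usage)) + sum(!comp$defined) + sum(is.na(lutr))
  message("run_expression: ", ncol(cpm), " samples, ",
          length(unique(grouping)), " group(s), ", n_undef,
          " flagged/undefined record(s)")
  manifest <- .write_manifest(out_dir, files, list(
    min_cds_lncpm = config$min_cds_lncpm,
    excluded_feature_roles = config$excluded_feature_roles,
    gene_id = attr(annotation, "gene_id")))
  invisible(list(cpm = cpm, lncpm = lncpm, usage = usage, composition = comp,
                 long_utr = lutr, files = c(files, manifest)))
}

#' Run the MVA epitope-mapping pipeline
#'
#' Normalizes the selected and input peptide libraries, screens every target
#' protein (alignment-load profile, fold enrichment, epitope call) and writes
#' per-protein profile tables, a call summary and a JSON manifest. Proteins
#' shorter than the peptides are reported as "no specific binding" with a
#' warning rather than failing the run.
#'
#' @param selected,input peptide tables (data frames with `sequence`,
#'   `raw_count`) or paths to TSV files ([read_peptides()]).
#' @param targets named character vector of protein sequences, an
#'   `AAStringSet`, or a FASTA path.
#' @param out_dir output directory.
#' @param config an [mva_config()].
#' @return invisibly, the [cross_reactivity_screen()] result plus output
#'   paths.
#' @export
run_mva <- function(selected, input, targets, out_dir,
                    config = mva_config()) {
  if (is.character(selected)) selected <- read_peptides(selected)
  if (is.character(input)) input <- read_peptides(input)
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    aa <- Biostrings::readAAStringSet(targets)
    targets <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  sel_lib <- normalize_library(selected, config$peptide_length)
  inp_lib <- normalize_library(input, config$peptide_length)
  screen <- cross_reactivity_screen(sel_lib, as.list(targets), inp_lib, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(screen)) {
    prof <- screen[[nm]]$profile
    prof <- data.frame(position = prof$position, residue = prof$residue,
                       load_selected = prof$load,
                       load_input = prof$input_load,
                       fold_enrichment = prof$fold_enrichment)
    files <- c(files, .write_tidy(prof, file.path(out_dir,
                                                  paste0("profile_", nm, ".tsv"))))
  }
  calls <- do.call(rbind, lapply(names(screen), function(nm) {
    cl <- screen[[nm]]$call
    data.frame(target = nm,
               specific_binding = screen[[nm]]$specific_binding,
               start = if (is.null(cl)) NA_integer_ else cl$start,
               end = if (is.null(cl)) NA_integer_ else cl$end,
               epitope = if (is.null(cl)) "" else cl$peptide,
               peak_fold = if (is.null(cl)) NA_real_ else cl$peak_fold)
  }))
  files <- c(files, .write_tidy(calls, file.path(out_dir, "epitope_calls.tsv")))
  message("run_mva: ", length(screen), " target(s), ",
          sum(calls$specific_binding), " with specific binding")
  manifest <- .write_manifest(out_dir, files, list(
    min_matches = config$min_matches, accrual = config$accrual,
    drop_top_peptide = config$drop_top_peptide,
    epitope_min_fold = config$epitope_min_fold,
    epitope_min_run = config$epitope_min_run))
  invisible(list(screen = screen, calls = calls, files = c(files, manifest)))
}
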