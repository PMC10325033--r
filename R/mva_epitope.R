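#' MVA configuration
#'
#' Tunables of the mimotope-variation-analysis scoring. Phage-display 12-mer
#' peptides are aligned ungapped against a target protein; an alignment
#' qualifies when at least `min_matches` of the 12 positions match (i.e. at
#' most `peptide_length - min_matches` mismatches). Alignment load at a
#' residue is the sum of normalized counts of the unique peptides whose
#' qualifying alignments match that residue, minus the single highest-count
#' peptide at that residue (a guard against a spuriously aligning high-count
#' peptide dominating a position).
#'
#' @param peptide_length displayed peptide length, default 12.
#' @param min_matches minimum matching positions for a qualifying alignment,
#'   default 6.
#' @param drop_top_peptide remove the highest-count peptide at every residue
#'   (default `TRUE`); a residue supported by a single peptide then scores 0.
#' @param accrual `"matched"` (default) accrues load only at the matched
#'   residues of a qualifying alignment, localizing signal to the residues
#'   that explain binding; `"window"` accrues at all `peptide_length` aligned
#'   residues.
#' @param enrichment_pseudocount added to numerator and denominator loads in
#'   [fold_enrichment()] so zero-load input positions stay finite. Default
#'   1e-9.
#' @param epitope_min_fold minimum fold enrichment for a residue to count as
#'   bound, default 5.
#' @param epitope_min_run minimum number of contiguous bound residues for an
#'   epitope call, default 5.
#' @return an `mva_config` list.
#' @export
mva_config <- function(peptide_length = 12L, min_matches = 6L,
                       drop_top_peptide = TRUE,
                       accrual = c("matched", "window"),
                       enrichment_pseudocount = 1e-9,
                       epitope_min_fold = 5, epitope_min_run = 5L) {
  accrual <- match.arg(accrual)
  stopifnot(min_matches >= 1L, min_matches <= peptide_length,
            enrichment_pseudocount > 0, epitope_min_fold > 0,
            epitope_min_run >= 1L)
  structure(list(peptide_length = as.integer(peptide_length),
                 min_matches = as.integer(min_matches),
                 drop_top_peptide = isTRUE(drop_top_peptide),
                 accrual = accrual,
                 enrichment_pseudocount = enrichment_pseudocount,
                 epitope_min_fold = epitope_min_fold,
                 epitope_min_run = as.integer(epitope_min_run)),
            class = "mva_config")
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Normalize a peptide library
#'
#' Merges duplicate sequences by summing raw counts, then divides by the
#' total so normalized counts sum to 1. Sequences of the wrong length or with
#' characters outside the 20 canonical amino acids are dropped with a warning
#' rather than aborting the run.
#'
#' @param peptides data frame with columns `sequence` and `raw_count` (or a
#'   named numeric vector of counts).
#' @param peptide_length expected sequence length, default 12.
#' @return data frame with columns `sequence`, `raw_count`,
#'   `normalized_count`.
#' @export
normalize_library <- function(peptides, peptide_length = 12L) {
  if (is.numeric(peptides) && !is.null(names(peptides)))
    peptides <- data.frame(sequence = names(peptides), raw_count = as.numeric(peptides))
  stopifnot(all(c("sequence", "raw_count") %in% names(peptides)))
  seqs <- toupper(as.character(peptides$sequence))
  counts <- as.numeric(peptides$raw_count)
  if (any(counts < 0)) stop("negative raw peptide counts")
  ok_len <- nchar(seqs) == peptide_length
  ok_alpha <- !grepl(paste0("[^", paste(.aa_alphabet, collapse = ""), "]"), seqs)
  bad <- !(ok_len & ok_alpha)
  if (any(bad)) {
    warning(sum(bad), " peptide(s) dropped (wrong length or non-canonical ",
            "amino acid)")
    seqs <- seqs[!bad]; counts <- counts[!bad]
  }
  if (!length(seqs)) stop("no valid peptides in library")
  agg <- tapply(counts, seqs, sum)
  total <- sum(agg)
  if (total <= 0) stop("total peptide count is zero")
  out <- data.frame(sequence = names(agg), raw_count = as.numeric(agg),
                    normalized_count = as.numeric(agg) / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.protein_chars <- function(protein) {
  if (inherits(protein, "AAString") || inherits(protein, "AAStringSet"))
    protein <- as.character(protein)[[1]]
  if (length(protein) > 1L) return(toupper(protein))  # already split
  strsplit(toupper(protein), "")[[1]]
}

#' Per-peptide matched-position matrix
#'
#' For every peptide, slides it ungapped along the protein with full overlap
#' (offsets 1 .. L - k + 1) and records, over all offsets with at least
#' `min_matches` identities, the union of protein positions the peptide
#' matches (accrual `"matched"`) or covers (accrual `"window"`). Each
#' position is recorded once per peptide however many offsets hit it.
#'
#' @param sequences character vector of equal-length peptide sequences.
#' @param protein target protein sequence (character or `AAString`).
#' @param min_matches minimum identities for a qualifying offset.
#' @param accrual `"matched"` or `"window"`.
#' @return logical matrix, peptides x protein positions. A protein shorter
#'   than the peptides yields an all-`FALSE` matrix with a warning.
#' @export
peptide_match_matrix <- function(sequences, protein, min_matches = 6L,
                                 accrual = c("matched", "window")) {
  accrual <- match.arg(accrual)
  prot <- .protein_chars(protein)
  L <- length(prot)
  n <- length(sequences)
  k <- if (n) nchar(sequences[[1]]) else 0L
  if (n && any(nchar(sequences) != k))
    stop("all peptide sequences must have equal length")
  M <- matrix(FALSE, n, L)
  if (!n) return(M)
  if (L < k) {
    warning("protein shorter than the peptides; no alignment possible")
    return(M)
  }
  P <- matrix(match(unlist(strsplit(sequences, "")), LETTERS),
              nrow = n, ncol = k, byrow = TRUE)
  prot_i <- match(prot, LETTERS)
  for (o in seq_len(L - k + 1L)) {
    w <- prot_i[o:(o + k - 1L)]
    cmp <- P == rep(w, each = n)
    q <- which(.rowSums(cmp, n, k) >= min_matches)
    if (length(q)) {
      cols <- o:(o + k - 1L)
      if (accrual == "matched") {
        M[q, cols] <- M[q, cols, drop = FALSE] | cmp[q, , drop = FALSE]
      } else {
        M[q, cols] <- TRUE
      }
    }
  }
  M
}

#' Align one peptide to a target protein
#'
#' @param peptide a single peptide sequence.
#' @param protein target protein sequence.
#' @param min_matches minimum identities for a qualifying ungapped,
#'   full-overlap alignment, default 6.
#' @param accrual see [mva_config()].
#' @return sorted integer vector of matched protein positions (union over all
#'   qualifying offsets); empty when no offset qualifies.
#' @export
align_peptide <- function(peptide, protein, min_matches = 6L,
                          accrual = "matched") {
  M <- peptide_match_matrix(peptide, protein, min_matches, accrual)
  which(M[1L, ])
}

#' Per-residue alignment-load profile
#'
#' For each protein residue, sums the normalized counts of the unique
#' peptides whose qualifying alignments hit it, then (by default) subtracts
#' the largest contributing count at that residue — the top-peptide removal
#' that damps spurious alignment of high-count peptides. A residue hit by a
#' single peptide consequently has load 0.
#'
#' @param library normalized peptide library ([normalize_library()]).
#' @param protein target protein sequence.
#' @param config an [mva_config()].
#' @return an `alignment_load_profile` data frame with columns `position`,
#'   `residue`, `load`.
#' @export
alignment_load <- function(library, protein, config = mva_config()) {
  prot <- .protein_chars(protein)
  M <- peptide_match_matrix(library$sequence, prot, config$min_matches,
                            config$accrual)
  w <- library$normalized_count
  contrib <- M * w                     # n x L, per-peptide contribution
  tot <- colSums(contrib)
  load <- if (config$drop_top_peptide && nrow(M)) {
    top <- apply(contrib, 2L, max)
    tot - top
  } else tot
  structure(data.frame(position = seq_along(prot), residue = prot,
                       load = as.numeric(load), stringsAsFactors = FALSE),
            class = c("alignment_load_profile", "data.frame"))
}

#' Fold enrichment of a selected library over the input library
#'
#' `fold(p) = (load_selected(p) + eps) / (load_input(p) + eps)` with the
#' configured pseudocount `eps`, so positions with zero input load stay
#' finite and positions with zero load in both libraries score 1.
#'
#' @param selected,input_profile alignment-load profiles over the same
#'   protein ([alignment_load()]).
#' @param config an [mva_config()].
#' @return `selected` with columns `input_load` and `fold_enrichment` added.
#' @export
fold_enrichment <- function(selected, input_profile, config = mva_config()) {
  if (nrow(selected) != nrow(input_profile))
    stop("selected and input profiles cover proteins of different lengths")
  eps <- config$enrichment_pseudocount
  selected$input_load <- input_profile$load
  selected$fold_enrichment <- (selected$load + eps) / (input_profile$load + eps)
  selected
}

#' Call an epitope from a fold-enrichment profile
#'
#' Finds contiguous runs of residues with `fold_enrichment >=
#' epitope_min_fold` and returns the longest run of at least
#' `epitope_min_run` residues; ties are broken by higher peak fold inside the
#' run, then by smaller start. `NULL` when no run qualifies.
#'
#' @param profile profile with `fold_enrichment` filled
#'   ([fold_enrichment()]).
#' @param protein target protein sequence (for the epitope peptide string).
#' @param config an [mva_config()].
#' @return `NULL`, or an `epitope_call` list with `start`, `end`, `peptide`,
#'   `peak_fold`.
#' @export
call_epitope <- function(profile, protein, config = mva_config()) {
  above <- profile$fold_enrichment >= config$epitope_min_fold
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
  runs <- runs[runs$end - runs$start + 1L >= config$epitope_min_run, , drop = FALSE]
  if (!nrow(runs)) return(NULL)
  runs$len <- runs$end - runs$start + 1L
  runs$peak <- vapply(seq_len(nrow(runs)), function(i)
    max(profile$fold_enrichment[runs$start[i]:runs$end[i]]), numeric(1))
  ord <- order(-runs$len, -runs$peak, runs$start)
  best <- runs[ord[1L], ]
  prot <- .protein_chars(protein)
  structure(list(start = best$start, end = best$end,
                 peptide = paste(prot[best$start:best$end], collapse = ""),
                 peak_fold = best$peak),
            class = "epitope_call")
}

#' @export
print.epitope_call <- function(x, ...) {
  cat(sprintf("Epitope call: residues %d-%d (%s), peak fold %.1f\n",
              x$start, x$end, x$peptide, x$peak_fold))
  invisible(x)
}

#' Screen a selected library against several candidate target proteins
#'
#' Runs the full MVA scoring (alignment load, fold enrichment over the input
#' library, epitope calling) against each candidate protein. A protein with
#' no qualifying run is reported as showing no specific binding — the
#' cross-reactivity readout.
#'
#' @param selected,input_library normalized peptide libraries
#'   ([normalize_library()]).
#' @param proteins named list (or `AAStringSet`) of target protein sequences.
#' @param config an [mva_config()].
#' @return named list per protein with elements `profile` (fold-enrichment
#'   profile), `call` (an `epitope_call` or `NULL`) and `specific_binding`
#'   (logical).
#' @export
cross_reactivity_screen <- function(selected, proteins, input_library,
                                    config = mva_config()) {
  if (inherits(proteins, "AAStringSet"))
    proteins <- as.list(as.character(proteins))
  if (!length(proteins)) stop("need at least one target protein")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("target_", seq_along(proteins))
  res <- lapply(names(proteins), function(nm) {
    prot <- proteins[[nm]]
    sel_prof <- alignment_load(selected, prot, config)
    inp_prof <- alignment_load(input_library, prot, config)
    prof <- fold_enrichment(sel_prof, inp_prof, config)
    call <- call_epitope(prof, prot, config)
    list(profile = prof, call = call, specific_binding = !is.null(call))
  })
  names(res) <- names(proteins)
  res
}

#' Read a peptide count table
#'
#' @param path tab-separated file with columns `sequence` and `raw_count`
#'   (header required).
#' @return data frame with those columns.
#' @export
read_peptides <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "raw_count") %in% names(tab)))
    stop("peptide table needs columns 'sequence' and 'raw_count': ", path)
  tab[, c("sequence", "raw_count")]
}

#' Bundled synthetic neurotrophin target sequences
#'
#' Loads the package's stand-in FASTA of four neurotrophin precursors (BDNF,
#' NGF, NT-3, NT-4). These are synthetic sequences: the BDNF entry preserves
#' the true precursor length (249 aa) and the fully conserved mature-region
#' sequence (residues 131-249), so mature-region residue numbering — in
#' particular the 147-SEWVTAADK-155 epitope — matches the real protein; the
#' signal/pro segments and the other three entries are plausible stand-ins of
#' realistic length, suitable for simulation and cross-reactivity tests but
#' not for analysing real binding data against those proteins.
#'
#' @return a named character vector of protein sequences.
#' @export
neurotrophin_targets <- function() {
  path <- system.file("extdata", "neurotrophin_targets_synthetic.fasta",
                      package = "bdnfkit", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}
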