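# Independent brute-force oracles, written against the definitions rather
# than the package's vectorized implementations. Deliberately slow and plain.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# nearest-integer-safe ceiling of fraction * n (exact rule, own arithmetic)
oracle_threshold <- function(n, fraction) {
  x <- fraction * n
  up <- as.integer(ceiling(x))
  if (up - x > 1 - 1e-9) up <- up - 1L   # undo a pure floating-point carry
  max(1L, up)
}

# scans every junction identity across every sample table one at a time
oracle_filter <- function(tables, prevalence = 0.10,
                          mito = c("chrM", "MT"), min_unique = 1L) {
  ids <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("chrom", "intron_start", "intron_end", "strand_code",
          "motif_code")])))
  thr <- oracle_threshold(length(tables), prevalence)
  keep <- logical(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    if (ids$chrom[i] %in% mito || ids$motif_code[i] == 0L) next
    n_det <- 0L
    for (t in tables) {
      hit <- t$chrom == ids$chrom[i] &
        t$intron_start == ids$intron_start[i] &
        t$intron_end == ids$intron_end[i] &
        t$strand_code == ids$strand_code[i] &
        t$unique_reads >= min_unique
      if (any(hit)) n_det <- n_det + 1L
    }
    keep[i] <- n_det >= thr
  }
  out <- ids[keep, c("chrom", "intron_start", "intron_end", "strand_code")]
  out <- out[order(out$chrom, out$intron_start, out$intron_end,
                   out$strand_code), ]
  rownames(out) <- NULL
  out
}

# enumerates every offset, counts identities, unions matched positions
oracle_align <- function(peptide, protein, min_matches = 6L) {
  p <- strsplit(peptide, "")[[1]]
  q <- strsplit(protein, "")[[1]]
  k <- length(p); L <- length(q)
  if (L < k) return(integer())
  hit <- rep(FALSE, L)
  for (o in 1:(L - k + 1)) {
    matched <- integer()
    for (j in 1:k) if (p[j] == q[o + j - 1]) matched <- c(matched, o + j - 1)
    if (length(matched) >= min_matches) hit[matched] <- TRUE
  }
  which(hit)
}

# per-position sum of normalized counts of covering peptides, minus the top
oracle_load <- function(lib, protein, min_matches = 6L, drop_top = TRUE) {
  L <- nchar(protein)
  load <- numeric(L)
  covers <- lapply(lib$sequence, oracle_align, protein = protein,
                   min_matches = min_matches)
  for (p in 1:L) {
    w <- lib$normalized_count[vapply(covers, function(v) p %in% v, logical(1))]
    if (length(w))
      load[p] <- if (drop_top) sum(w) - max(w) else sum(w)
  }
  load
}

random_junction_tables <- function(n_junctions, n_samples) {
  chrom <- sample(c("chr1", "chr2", "chrM", "MT"), n_junctions, replace = TRUE,
                  prob = c(0.4, 0.4, 0.1, 0.1))
  start <- sample.int(1e5L, n_junctions, replace = TRUE)
  end <- start + sample.int(2000L, n_junctions, replace = TRUE)
  strand <- sample(0:2, n_junctions, replace = TRUE)
  motif <- sample(0:6, n_junctions, replace = TRUE)
  lapply(seq_len(n_samples), function(s) {
    present <- runif(n_junctions) < runif(1, 0.05, 0.9)
    idx <- which(present)
    junction_table(chrom = chrom[idx], intron_start = start[idx],
                   intron_end = end[idx], strand_code = strand[idx],
                   motif_code = motif[idx],
                   unique_reads = rpois(length(idx), 3),
                   multi_reads = rpois(length(idx), 1),
                   overhang = sample(5:40, length(idx), replace = TRUE))
  })
}

junction_keys <- function(jt) {
  paste(jt$chrom, jt$intron_start, jt$intron_end, jt$strand_code)
}

# peptides enriched for partial protein identity, so alignments happen
random_mva_instance <- function(max_len = 40L, max_pep = 20L) {
  L <- sample(12:max_len, 1)
  prot <- paste(sample(AA20, L, replace = TRUE), collapse = "")
  n <- sample(1:max_pep, 1)
  seqs <- vapply(seq_len(n), function(i) {
    if (runif(1) < 0.5) {
      paste(sample(AA20, 12, replace = TRUE), collapse = "")
    } else {
      o <- sample.int(L - 11L, 1)
      p <- strsplit(substr(prot, o, o + 11L), "")[[1]]
      nmut <- sample(0:8, 1)
      pos <- sample(12, nmut)
      p[pos] <- sample(AA20, nmut, replace = TRUE)
      paste(p, collapse = "")
    }
  }, character(1))
  counts <- sample(1:50, n, replace = TRUE)
  list(protein = prot,
       library = normalize_library(data.frame(sequence = seqs,
                                              raw_count = counts)))
}
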