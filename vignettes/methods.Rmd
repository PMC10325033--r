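---
title: "Methods: region-ratio expression statistics, MVA epitope scoring, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-ratio expression statistics, MVA epitope scoring, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdnfkit)
```

# The quantification model

`bdnfkit` works downstream of read counting. Its unit of analysis is a SAF
feature annotation that partitions a gene into alternative non-coding 5'
exons (one per promoter), the common CDS, the short 3'UTR segment shared by
all transcripts, and the long-3'UTR extension present only on distally
polyadenylated transcripts. Coordinates are 1-based and inclusive at both
ends (the SAF convention), so a feature's length is `end - start + 1`;
strand is stored but never enters the arithmetic, because counts arrive
already assigned to features.

Three assumptions underlie the region-ratio statistics:

1. **The CDS proxies total gene output.** Every transcript isoform contains
   the CDS, so length-normalized CDS coverage is the denominator against
   which promoter-specific and 3'UTR-specific coverage is measured.
2. **Coverage is proportional to abundance × length.** Counts are modeled as
   proportional to the summed length of the region present in each
   transcript class. Length normalization (per kb) converts counts into a
   per-base coverage comparable across features of different size.
3. **Region ratios identify isoform fractions.** A 5' exon is unique to its
   promoter's transcripts, so `lnCPM(exon)/lnCPM(CDS)` estimates that
   promoter's share; the long-UTR extension is unique to long-UTR
   transcripts, so `lnCPM(extension)/lnCPM(CDS)` estimates the long-isoform
   fraction. No expectation-maximization deconvolution is attempted — the
   regions are disjoint by construction, which is exactly what makes the
   simple ratio valid.

CPM uses the per-sample total of reads assigned to annotated features as its
denominator, supplied in the `count_matrix`. When the annotation is complete
(totals = column sums), CPM columns sum to exactly 10⁶ — a property the test
suite asserts.

## Composition: sums of ratios, not means of compositions

Group composition percentages are computed by summing each exon's usage
ratios over the group's samples and normalizing by the grand total across
exons, *not* by averaging per-sample compositions. The two differ when
per-sample totals vary; the sum-then-normalize order weights samples by
their overall usage signal and keeps a single degenerate sample from
dominating. Percentages within a defined group sum to 100 by construction.

## Undefined values are flagged, never dropped silently

Ratios are meaningless where the gene is essentially unexpressed. Samples
whose CDS lnCPM falls below `min_cds_lncpm` (default **0.1 lnCPM**, i.e. one
tenth of a read per million per kb — an essentially-zero expression level)
get `NA` usage and long-UTR values; groups with no defined sample are
returned with `defined = FALSE`. The threshold is a configuration knob, not
a constant, because what counts as "too low" depends on library depth.

# Junction filtering

The two-pass filter pools each dataset's first-pass STAR `SJ.out.tab`
tables and keeps a junction only if it (a) is not on a mitochondrial contig
(names configurable, default `chrM`/`MT` — the usual contig names across
genome builds), (b) has a canonical intron motif (STAR motif code 1–6;
code 0 is STAR's encoding of "non-canonical"), and (c) is detected in at
least `ceiling(0.10 × n)` of the n samples. "Detected in a sample" means at
least one uniquely mapping supporting read; multi-mapping support is
noisier and does not count, though the threshold is configurable. Junction
identity includes the strand code along with the coordinates, so
same-coordinate junctions on opposite strands are counted separately.

One numerical subtlety: `0.10 × 30` is `3.0000000000000004` in binary
floating point, and a naive `ceiling()` would demand 4 samples where the
rule means 3. `detection_threshold()` therefore subtracts 1e-9 before
rounding up — far smaller than any meaningful fraction-of-a-sample, far
larger than double-precision error.

# MVA epitope scoring

Phage-display selection yields 12-mer peptide counts for an
antibody-selected sample and for the unselected input library. Scoring
proceeds in four steps, each a separate exported function:

1. **Normalization**: duplicate sequences are merged and counts divided by
   the library total, so each library is a probability distribution over
   unique peptides.
2. **Alignment**: each peptide is slid ungapped along the target with full
   overlap only; an offset qualifies when ≥ `min_matches` (default **6**)
   of the 12 positions are identical. Full-overlap-only keeps "6 of 12"
   well-defined at the termini; terminal epitopes remain coverable from
   interior offsets. Load accrues at the *matched* positions of qualifying
   offsets (the union over offsets, each position once per peptide); a
   `"window"` mode accruing at all 12 aligned positions is provided, but
   matched-only is the default because it localizes signal to the residues
   that explain binding and produces sharp epitope boundaries.
3. **Load with top-peptide removal**: at every residue, the highest
   normalized count among the peptides hitting it is subtracted
   (per-residue, independently — the literal per-position reading). A
   residue supported by a single peptide thus scores 0, which is the
   point: one high-count peptide aligning spuriously should not create
   signal on its own.
4. **Fold enrichment and calling**: per-residue fold =
   `(load_selected + ε)/(load_input + ε)` with ε = 1e-9 — about seven
   orders of magnitude below any real normalized count, so it only rescues
   zero-denominator positions. An epitope is the longest contiguous run of
   ≥ 5 residues with fold ≥ 5 (ties: higher peak fold, then smaller
   start). The fold-5/run-5 thresholds are package defaults chosen to
   demand roughly an order-of-magnitude enrichment sustained over a
   biologically plausible linear-epitope length; both are configurable.
   With identical selected and input libraries the fold profile is exactly
   1 everywhere and no call is made — the null calibration the test suite
   checks on all four bundled targets.

# Calibration curves

Densitometric quantification fits `signal = slope × amount + intercept` by
ordinary least squares to a recombinant-protein dilution series (≥ 2
distinct amounts). The intercept is free by default, absorbing background
signal; a forced-zero and a log-linear mode are provided since detector
response at saturation is sometimes better described on a log scale.
Inversion clamps negative estimates to zero and flags estimates outside the
standards' range as extrapolated rather than silently reporting them. A
non-positive slope marks the curve unusable. The max-normalized relative
readout (`relative_signal`) is scale-invariant, as a blot-to-blot relative
measure must be.

# What the generators emulate — and what they do not

**Counts** (`simulate_counts`). Expected feature counts follow the
abundance × length coverage model; realized counts are negative-binomial
with the edgeR-style dispersion (variance = μ + φμ², default φ = 0.1, a
typical bulk-RNA-seq biological CV of ~0.32; φ = 0 gives Poisson). Depth
varies log-normally across samples (sdlog 0.25) so CPM normalization is
actually exercised. Defaults are the package's reference study condition:
four promoters at proportions 0.10/0.15/0.50/0.25, long-UTR fraction 0.30,
20 samples at a mean of 10⁶ assigned reads. The generator does *not*
emulate positional coverage bias, intron signal, multi-gene backgrounds, or
annotation errors — so passing recovery tests demonstrates the estimators'
correctness under the stated model, not robustness to misannotation.

A consequence worth knowing: the long-UTR estimator is a ratio of two noisy
quantities, and E[X/Y] ≈ (μx/μy)(1 + CV²(Y)) for independent noise, so
under φ = 0.1 the recovered fraction sits a few percent above the
generating 0.30 (≈ 0.33 at the reference condition). This bias is a
property of the ratio method itself, shrinking with φ, not an
implementation artifact. Composition percentages are much less affected
because the CDS denominator is shared across exons and cancels in the
normalization.

**Junctions** (`simulate_junctions`). Per-junction detection is Bernoulli
with a planted prevalence; chromosome and motif labels are planted at the
requested mitochondrial and non-canonical fractions. The truth record
stores the *realized* detection counts, so the filter can be scored
exactly rather than in expectation.

**Phage display** (`simulate_mva`). The input library is unique random
12-mers with near-uniform counts; a fraction (default 5 %) carry a
contiguous epitope subsequence of length ≥ 6, at a uniformly random
register, and their counts are multiplied by the enrichment factor
(default 100×) in the selected library. Flanking residues of a carrier are
sampled to *mismatch* the target at their aligned positions. This is a
deliberate design choice: carriers are heavily enriched, so a chance flank
match adjacent to the epitope would carry the full enrichment ratio and
smear the planted boundary — the fold profile is a ratio, insensitive to
how small the absolute loads are. Confining matches to the epitope keeps
the truth record exact, at the cost of not modeling the boundary fuzziness
real selections show. Non-epitope peptides still align by chance
(P(≥ 6/12) ≈ 10⁻⁵ per offset), which the top-peptide removal is designed to
absorb, and the replicate study checks it does: the planted 147–155
boundary is recovered exactly in ≥ 95 of 100 seeded replicates.

All generators take an explicit seed and are bit-reproducible given their
spec.

## The bundled target sequences are synthetic stand-ins

`neurotrophin_targets()` loads four precursor sequences. The BDNF entry has
the true precursor length (249 aa) and the true, fully conserved
mature-region sequence (residues 131–249) — so mature-region numbering,
including the 147–155 epitope interval used as the default planting site,
is faithful — but its signal/pro segment is synthetic, as are the NGF,
NT-3 and NT-4 entries entirely (realistic lengths, random composition).
They support simulation and cross-reactivity *testing*; conclusions about
real binding to those proteins require the real UniProt sequences, which
users should supply as FASTA.

# Problem sizes and verification strategy

The test suite verifies each scoring path against an independent
brute-force re-implementation written from the definitions (junction
filtering on 200 random instances of up to 100 junctions × 30 samples; MVA
alignment and load on 500 random instances of proteins ≤ 40 aa and ≤ 20
peptides), checks the normalization identities exactly, and runs parameter
recovery at the reference study condition (200 count replicates; 100
phage-display replicates). These sizes keep the full suite around a minute
of compute while leaving the stochastic checks well-powered; the
brute-force oracles are intentionally slow, plain loops so that agreement
is evidence rather than tautology.

# Known limitations

* The expression statistics assume feature-assigned counts; ambiguous
  assignment (overlapping features, multi-mapping) must be resolved
  upstream by the counting tool.
* Composition is a ratio-of-sums over groups; it has no per-sample
  uncertainty attached, and no differential test is provided.
* MVA scoring is strictly linear-epitope: conformational epitopes spread
  over discontinuous residues will not produce a contiguous qualifying run.
* The calibration module quantifies given densitometric signals; band
  detection and image analysis are out of scope.
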