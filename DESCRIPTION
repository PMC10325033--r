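Package: bdnfkit
Title: Alternative Promoter Usage, 3'UTR Isoform Ratios, and Antibody
    Epitope Mapping for BDNF Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-quantification toolkit for studies of BDNF transcript
    diversity and antibody validation. Implements SAF-style feature
    annotations partitioning a gene into alternative 5' exons, CDS and
    3'UTR segments; two-pass splice-junction prevalence filtering of
    STAR SJ.out.tab tables; CPM and per-kilobase normalization; 5' exon
    usage relative to the CDS with group composition percentages; the
    long-3'UTR isoform proportion; mimotope variation analysis (MVA)
    scoring of phage-display 12-mer libraries against target proteins
    with per-residue alignment loads, fold enrichment over the input
    library and epitope calling; densitometric calibration-curve protein
    quantification; and seeded synthetic-data generators with truth
    records so every stage is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
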