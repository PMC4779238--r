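Package: msreprimer
Title: High-Throughput Design of MSRE-PCR and Genomic PCR Primer Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Batch design of methylation-sensitive restriction enzyme (MSRE)
    PCR and genomic PCR primer pairs from BED-defined target regions. Extracts
    design sequences from a reference genome, enumerates candidate primer
    pairs under Primer3-compatible constraints with nearest-neighbor melting
    temperature calculation, predicts type-II restriction enzyme cut sites
    (IUPAC-degenerate recognition motifs, both strands), annotates every pair
    with SNPs, CpG islands, repeat elements and nearest RefSeq genes, selects
    final assays through a rank-based quality matrix and MSRE-specific
    filters, and writes summary tables (TSV/HTML), per-target UCSC custom
    tracks (GTF) and genome-browser / In-Silico-PCR links. Also implements
    qPCR calibration-curve evaluation (slope, efficiency, R-squared,
    theoretical 1 ng detection) used to qualify assays, plus a seeded
    synthetic-fixture generator so the whole pipeline runs without any
    download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
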