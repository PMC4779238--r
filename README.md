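# msreprimer

High-throughput design of **MSRE-PCR** (methylation-sensitive restriction
enzyme PCR) and genomic PCR primer pairs, from a BED file of target regions
to an annotated, filtered, browser-linkable assay table.

## Who this is for

Epigenetics groups validating candidate differentially-methylated regions
(e.g. from array- or sequencing-based discovery) with MSRE-qPCR need many
assays at once, and every assay must satisfy constraints that ordinary
primer design tools do not check: the amplicon must contain at least one
recognition site of a methylation-sensitive enzyme (so digestion can report
methylation), the primers must avoid common SNPs, the assay must avoid
repeat elements, and the amplicon must actually cover the CpG position of
interest. `msreprimer` runs that whole design-and-triage workflow in batch,
and its genomic-PCR mode runs the identical pipeline (same output schema)
when no enzyme logic is wanted.

## What it computes

* **Candidate design** — exhaustive (position, length) window enumeration
  on both strands under Primer3-compatible constraints (size, Tm, GC%,
  self-complementarity, poly-X, no N), parsed from Boulder-IO
  `KEY=VALUE` parameter files. Melting temperatures use unified
  nearest-neighbor thermodynamics (Allawi & SantaLucia 1997; SantaLucia
  1998) with entropic salt correction and a monovalent-equivalent
  treatment of divalent cations. Pairs are ranked by the standard penalty
  `w_size |len-opt| + w_Tm |Tm-opt| + w_GC |GC-opt|` summed over both
  primers.
* **Restriction-site prediction** — caret-notation enzyme definitions
  (`C^CGG`), IUPAC-degenerate matching with symbolic reverse complement
  (M = A/C ↔ K = G/T), both strands, palindromic sites counted once,
  overlapping matches all counted; per-region cut-site counts and
  genome-wide CpG coverage / fragments-per-kb statistics.
* **Annotation** — genomic coordinates for every primer, oligo and
  amplicon; SNP counts per primer and amplicon; CpG-island and repeat
  overlap; nearest up-/downstream genes with distances; UCSC genome
  browser and In-Silico PCR links.
* **Selection** — a rank-based (1–10) quality matrix over any numeric
  output column with `>`, `<`, `>=`, `<=` and inclusive-range operators,
  plus the MSRE validation filter (cut site in amplicon, no primer SNP,
  no repeat in assay, target midpoint within ±50 bp of the amplicon).
* **qPCR qualification** — calibration-curve fits (Cq vs log10 ng),
  efficiency `E = (10^(-1/slope) - 1)·100`, R², theoretical 1 ng
  detection (the intercept), and MIQE-style pass/fail criteria.
* **Synthetic fixtures** — a seeded generator producing a small genome
  with CpG islands, literally planted enzyme sites and SNP/repeat/gene
  tracks plus a truth table, so the entire pipeline runs and is testable
  with no downloads.

Outputs: a summary table in TSV and HTML (one row per selected pair, frozen
column order usable as quality-matrix vocabulary), a per-target UCSC custom
track in GTF, and a run log.

## Worked example

```r
library(msreprimer)

# a seeded synthetic genome: 4 CpG islands, planted HpaII (C^CGG) sites
# following the per-island pattern 1, 0, 2, SNP/repeat/gene tracks
spec <- fixture_spec(n_cpg_islands = 4, n_snps = 30, n_repeats = 4,
                     n_genes = 3, chrom_length = 20000, island_length = 500,
                     planted_enzyme_sites = list(HpaII = c(1, 0, 2)),
                     seed = 42)
fix <- generate_fixture(spec)
dir <- tempfile("msre_demo_")
paths <- write_fixture(fix, dir)
writeLines("HpaII", file.path(dir, "enzymes.txt"))

cfg <- run_config(genome = paths[["genome"]], targets = paths[["targets"]],
                  snp = paths[["snp"]], cpg = paths[["cpg"]],
                  repeats = paths[["repeats"]], genes = paths[["genes"]],
                  enzymes = file.path(dir, "enzymes.txt"), mode = "msre",
                  flank_up = 150, flank_down = 150,
                  out_dir = file.path(dir, "out"))
res <- run_pipeline(cfg)
subset(res$summary, msre_pass,
       select = c(target_id, pair_id, fwd_seq, product_size,
                  n_cutsites_amplicon, target_dist))
```

```
   target_id pair_id              fwd_seq product_size n_cutsites_amplicon target_dist
5    tgt_001 pair_05 GGACGATACTCCGTACGCTC          261                   1          -5
20   tgt_004 pair_05 AGCCGTCCTTACTGCTTTGA          292                   1           0
```

Of the 20 designed pairs (5 per target), exactly two qualify as MSRE
assays: their amplicons contain a planted HpaII site, neither primer
overlaps a SNP, no repeat intersects the amplicon, and the island midpoint
(`target_dist`, bp from the amplicon) lies within ±50 bp. Target `tgt_002`
had no planted site, so all of its pairs fail the cut-site criterion —
exactly what the truth table predicts.

Calibration-curve evaluation of a dilution series (10, 2.5, 0.625,
0.156 ng; measured Cq values):

```r
fit_calibration(c(10, 2.5, 0.625, 0.156), c(26.68, 28.68, 30.68, 32.68))
```

```
qPCR calibration (n=4): slope -3.3208, intercept 30.00, R^2 1.0000,
efficiency 100.05%, theoretical 1 ng Cq 30.00
```

A slope near -3.32 means the template doubles each cycle (efficiency
~100 %); the intercept is the expected Cq for 1 ng input.

A command-line front end with `fixtures`, `run`, `qpcr-eval` and
`coverage` subcommands is installed under `inst/scripts/msreprimer`.

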