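---
title: "Designing MSRE-PCR assays with msreprimer: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing MSRE-PCR assays with msreprimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msreprimer)
```

## The problem

Methylation-sensitive restriction enzymes (MSREs) cleave their recognition
site only when the CpG inside it is unmethylated; methylation blocks
digestion. Quantitative PCR on MSRE-digested DNA therefore reads out the
methylation state of the CpGs covered by the assay: an amplicon that
survives digestion was methylated. A usable MSRE-qPCR assay needs an
amplicon that (a) contains at least one recognition site of the chosen
enzyme panel, (b) has primers free of common SNPs (a primer-site SNP
destabilises annealing in some samples), (c) avoids repeat elements (which
defeat specificity), and (d) actually covers the CpG position the study
cares about. Designing hundreds of such assays by hand is impractical;
`msreprimer` automates the whole path from a BED file of target regions to
an annotated, filtered, browser-linkable table of primer pairs. A
genomic-PCR mode runs the identical pipeline without the enzyme step, with
a uniform output schema.

## Pipeline structure

For every target region the pipeline (1) extends the region by optional
up-/downstream flanks and clamps at chromosome bounds, (2) extracts the
design sequence from the reference FASTA, (3) enumerates candidate primers
and pairs under Primer3-compatible constraints, (4) predicts restriction
sites in primers and amplicons (MSRE mode), (5) lifts everything to genomic
coordinates and annotates with SNPs, CpG islands, repeats and nearest
genes, and (6) selects final pairs through an optional rank-based quality
matrix and the MSRE validation filter. Targets are processed independently
and may be distributed over workers; results are reassembled in input
order, so the output bytes are identical for any worker count.

All internal coordinates are 0-based half-open (the BED convention);
conversion to 1-based inclusive coordinates happens only when writing GTF
tracks and UCSC position strings. Keeping a single internal convention was
a deliberate design choice to eliminate off-by-one drift between modules.
Interval overlap everywhere means `max(starts) < min(ends)`, so intervals
that merely touch do not overlap.

## The design engine

The candidate enumerator scans every (position, length) window on both
strands of the design sequence and keeps windows that pass all hard
constraints: primer length, melting temperature, GC percentage,
self-complementarity caps, maximum mononucleotide run, and absence of `N`.
This engine implements a documented subset of the Primer3 parameter
interface (Boulder-IO `KEY=VALUE` files are parsed, unknown keys warn and
are ignored). It aims at compatibility with the parameter *interface*, not
bit-level score parity with any particular Primer3 build; on small targets
the candidate set is verified in the test suite against an independent
brute-force enumeration.

**Melting temperature.** Tm is computed with the unified nearest-neighbor
thermodynamic parameter set (Allawi & SantaLucia 1997; SantaLucia 1998),
duplex-initiation terms per terminal base pair, and the entropic salt
correction `dS + 0.368 (N-1) ln[Na+]`. Divalent cations are folded into an
equivalent monovalent concentration, `Na_eq = Na + 120 sqrt([Mg2+] -
[dNTP])` (all mM), the approximation Primer3 also uses. The effective
annealing concentration is one quarter of the oligo concentration
(non-self-complementary assumption). The constants are frozen in one table
in `R/thermo.R`; the design engine reads window thermodynamics off
cumulative sums and is regression-tested to agree exactly with the direct
per-primer computation.

**Self-complementarity.** `self_any` is the maximum alignment score of the
primer against its own reverse complement over all ungapped offsets, +1 per
match and -1 per mismatch, floored at 0; `self_end` restricts the maximum
to offsets in which the 3'-terminal base participates, so `self_end <=
self_any` by construction. The default caps (8 and 3) match the classical
Primer3 defaults on this score scale.

**Penalty and ranking.** Each primer's penalty is a weighted sum of
absolute deviations from the optima for length, Tm and GC (default weights
1, 1, 0, the Primer3 defaults for the implemented terms). The pair penalty
adds an optional Tm-difference term (default weight 0). Pairs must not
overlap, must fall in a configured product-size range, and are returned
sorted by penalty with deterministic ties broken by (amplicon start,
product size, forward start). Internal oligos, when enabled, reuse the
candidate machinery with oligo-specific bounds and must lie strictly
between the primers.

## Restriction-site prediction

Enzyme definitions use caret notation (`C^CGG`: cleavage after the first
base). Degenerate IUPAC codes are handled as membership sets, and the
reverse complement of a degenerate motif is computed symbolically (the
complement of `M` = A/C is `K` = G/T), which matters for enzymes like XmiI
(`GT^MKAC`). Motifs that equal their own symbolic reverse complement are
palindromic; each physical palindromic site is reported once, as a
plus-strand site. Non-palindromic motifs are scanned on both strands.
Overlapping and self-overlapping matches are all reported — each is a
physical site.

A cut site is counted for a region (forward primer, reverse primer, oligo,
amplicon) when its *recognition match* overlaps the region's interval, not
when the cleavage point falls inside it. This is the biologically
conservative reading: a primer overlapping any part of a recognition site
is disrupted by digestion. The per-kb fragment statistics inside and
outside CpG islands, and the percentage of CpG dinucleotides covered by at
least one site, are computed genome-wide by the same scanner.

## Selection semantics

The quality matrix is a TSV of rules `column, operator, value, rank` over
the numeric columns of the output schema, with operators `>`, `<`, `>=`,
`<=` and the inclusive range `-` (`lo,hi`), and ranks 1–10. Two semantics
are provided because "hierarchical rank" admits more than one reading:

* **cumulative** (default): a pair's quality level is the smallest rank
  `r` such that it satisfies *every* rule with rank `<= r`; pairs failing
  the lowest tier get no level. Because the rule prefixes only grow, this
  behaves as a strictness ladder anchored at rank 1 — in the common case
  of a single-rank matrix it is a plain filter.
* **independent** (flag-selectable): rank tiers are alternatives; the
  level is the smallest rank whose own rules are all satisfied. This is
  the natural encoding of relaxation ladders (rank 1 = strict thresholds,
  rank 2 = looser fallback).

With no matrix at all, pairs are reported in pure penalty order. In both
modes, removing a rule can only improve (or preserve) a pair's level and
adding one can only worsen it; this monotonicity is property-tested.

The MSRE validation filter encodes the wet-lab assay criteria directly:
at least one cut site in the amplicon, no SNP under either primer, no
repeat element in the assay, and the original target midpoint within the
amplicon extended by ±50 bp (configurable). The midpoint criterion was
chosen over whole-target containment because targets may be longer than
any admissible amplicon; a containment mode would then reject every pair.

Gene annotation reports the nearest gene on each genomic side of the
amplicon (distances from the amplicon's outer boundaries, which are the
primers' 5' ends), with distance 0 on both sides for an overlapping gene.
Upstream/downstream are genomic left/right; the gene's own strand is
reported in a separate column rather than folded into the direction.

## qPCR calibration and assay qualification

A calibration curve is an ordinary least-squares fit of Cq against
log10(input ng) over a serial dilution series. The slope maps to
amplification efficiency via `E = (10^(-1/slope) - 1) * 100`; a slope of
-1/log10(2) = -3.3219 is exact doubling (100 %), and the printed two-decimal
slope -3.32 corresponds to 100 % at integer precision. The theoretical
1 ng detection is the fitted intercept (log10(1) = 0). The default
qualification thresholds — efficiency 90–110 % and R² ≥ 0.99 — follow
common MIQE-style practice and are an explicit, overridable configuration;
no claim is made that any particular published assay panel used exactly
these numbers. The dilution-series simulator inverts the same model
(`cq = ct_1ng - log10(amount)/log10(1 + E/100) + noise`), so noiseless
generator/fit round trips are exact to numerical precision and are tested
to that standard.

## The synthetic fixture generator

Real reference genomes and UCSC annotation dumps are too large to ship and
unavailable offline, so the package generates its own study material: a
seeded genome with CpG-rich islands, literally planted enzyme recognition
sites (degenerate codes instantiated concretely), and SNP/repeat/gene
tracks planted at recorded intervals. The generator returns a truth table
of every planted feature and is a pure function of its spec, including the
seed. By default it also scrubs chance occurrences of the planted enzymes'
motifs from the background (mutating one base per spurious match, avoiding
planted intervals), so the truth table is the *complete* site list for
those enzymes — this is what lets the test suite assert that the MSRE
validation filter reproduces the planted truth exactly, with no allowance
for coincidental sites. A feature that cannot be placed raises an error;
nothing is silently dropped.

What the fixture does *not* emulate: real CpG-island length and density
distributions, linkage between SNPs and CpGs, repeat sequence content
(repeats are intervals, not sequence motifs), or chromatin context. Tests
passing on fixtures therefore demonstrate the correctness of the
coordinate arithmetic, scanning, annotation and selection logic — not
wet-lab primer performance.

## Problem sizes and numerical choices

The test suite works at deliberately modest scales chosen to exercise the
code paths thoroughly: oracle-equivalence sweeps over 1,000 random
sequences for the site scanner, brute-force design comparison on targets of
at most 60 bp, and an end-to-end determinism check over 250 targets of
roughly 300 bp design range each across 5 chromosomes. Calibration
recovery uses 500–1,000 simulated replicate series at a Cq noise standard
deviation of 0.15, a typical instrument-level replicate spread. Ties in
pair ranking are broken deterministically as documented above; R² of a
noiseless fit is asserted equal to 1 within 1e-12; Tm window sums must
match the direct computation within 1e-9 °C.

## Known limitations

* No mispriming/repeat libraries, no full secondary-structure ΔG
  alignment, and no cross-target multiplex dimer checking; the
  self-complementarity scores are the classical ungapped ±1 alignments.
* Enzymes with cleavage outside the recognition motif (type IIS offsets)
  or two cleavage positions are out of scope.
* Methylation state itself is not simulated; the package designs and
  annotates assays but does not model digestion efficiency.
* UCSC links are emitted as strings and never fetched; their parameter
  names follow current public conventions and are isolated in two small
  functions should those conventions change.
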