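---
title: "Detecting and characterizing Numts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing Numts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtr)
```

## The problem

Nuclear mitochondrial DNA segments (Numts) are fragments of the
mitochondrial genome that have integrated into nuclear chromosomes, mostly
during double-strand-break repair, and then decayed as pseudogenes. They
matter practically because they co-amplify with authentic mtDNA in
PCR-based barcoding and phylogenetics — particularly for *cox1*, the
standard animal barcode and, in insects, the most frequent Numt source. The
package implements the standard homology-search protocol for cataloguing
Numts in an assembled nuclear genome, given the species' mitogenome and its
37-gene annotation (13 protein-coding genes, 2 rRNAs, 22 tRNAs), and the
downstream characterizations used in comparative Numt surveys.

## The detection procedure

1. **Queries.** The 37 annotated mitochondrial genes are extracted in
   reading direction (minus-strand genes reverse-complemented, genes
   spanning the circular origin concatenated across the junction), and the
   full mitogenome is added as a 38th query. Searching genes *and* the full
   molecule finds both intragenic and intergenic transfers; the merging
   step (below) prevents double counting.

2. **Local alignment.** Each query is aligned against every contig with a
   seed-and-extend local aligner written for this package: exact word
   seeding (word size 11 by default), ungapped X-drop extension, then a
   banded gapped (affine) extension around the seeded diagonals. Scores use
   the BLASTN `blastn`-task convention: match +2, mismatch −3, a gap of
   length $k$ costs $5 + 2k$. Each hit's E-value follows Karlin–Altschul
   statistics,
   $$\mathrm{bit} = \frac{\lambda s - \ln K}{\ln 2}, \qquad
     E = m\,n\,2^{-\mathrm{bit}},$$
   with $m$ the query length and $n$ the total assembly length. $\lambda$
   is the unique positive root of
   $\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$ (solved by bisection to a
   residual below $10^{-10}$); $K$ defaults to 0.41. We deliberately do not
   replicate NCBI's gapped recalibration and effective-search-space length
   adjustment: E-values are comparable to BLASTN's but not bit-identical,
   and the analysis thresholds — not BLAST internals — define the method.
   Users can substitute real BLASTN output through the 12-column tabular
   interchange format (`read_tabular_hits()`/`write_tabular_hits()`).

3. **Filter cascade.** A hit is kept iff
   * E-value ≤ 10⁻⁴ (inclusive),
   * matched alignment length > 50 bp (strict; lengths of exactly 50 are
     removed),
   * identity > 60% (strict; exactly 60% is removed),
   * it does not cover 100% of its own query (optional, on by default).

4. **Locus merging.** On each contig, filtered hits whose subject intervals
   overlap by at least 1 bp (strand-agnostic, transitively closed) are
   merged into one locus spanning their union. Abutting half-open intervals
   do *not* merge. The Numt count is the number of merged loci, which makes
   it independent of the query set: one insertion found by a gene query and
   the full-mitogenome query counts once. Each locus records which *gene*
   queries contributed hits (`source_genes`); full-mitogenome hits carry no
   gene label, so gene attribution counts loci per source gene without
   inflation.

5. **Characterization.** Per-assembly summaries (count, total length,
   percentage of the genome printed to 5 decimals, 100-bp length histogram
   to 1.5 kb plus an open `>1500` bin); 100-bp upstream/downstream flank
   extraction with AT content over unambiguous bases; a paired one-tailed
   t-test of species-level flank AT against genome AT (and upstream vs
   downstream); Spearman correlations of Numt counts against nuclear and
   mitochondrial genome lengths.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open. 1-based inclusive
coordinates appear only at format boundaries: GFF3 annotations and the
BLAST-style tabular hit format (where a subject start greater than the
subject end encodes a minus-strand match). A gene wrapping the circular
origin is encoded with `end` greater than the mitogenome length.

IUPAC ambiguity codes other than ACGT are retained in sequences but (a)
score as mismatches in alignment, (b) never seed words, and (c) are
excluded from both numerator and denominator of AT/GC content. Whether a
published genome-wide AT value includes N-runs is rarely stated; the
unambiguous-base convention is flagged in the JSON report metadata.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| match / mismatch | +2 / −3 | score | BLASTN `blastn` task |
| gap open / extend | 5 / 2 | score | BLASTN `blastn` task |
| word size | 11 | bp | BLASTN `blastn` task |
| X-drop (ungapped) | 20 | score | generous; extension heuristics should never be the binding constraint |
| band half-width | 40 | columns | covers indel drift far beyond the simulated 0.5%/site |
| min raw score | 40 | score | well below anything that passes E ≤ 10⁻⁴ at genome scale |
| max E-value | 10⁻⁴ | — | survey convention |
| min length (exclusive) | 50 | bp | survey convention |
| min identity (exclusive) | 0.60 | fraction | survey convention |
| flank window | 100 | bp | survey convention |

The extension parameters are sized so that the E-value filter, not the
heuristics, decides what is reported at the scales this package targets.

## The synthetic benchmark

Real Numt surveys start from hundreds-of-megabase assemblies; nothing about
the *method* requires that scale, so the package ships a generator that
reproduces the statistical structure the analysis relies on, at desk scale:

* a multi-contig nuclear background of i.i.d. bases at lepidopteran-like GC
  (0.38), optionally with AT-rich hotspot windows;
* an AT-rich (GC 0.19) circular mitogenome of 15.6 kb carrying the full
  37-gene complement in a typical insect gene order, with known start/stop
  codon assignments (including incomplete `T`/`TA` stops and the `CGA`
  *cox1* start) returned as truth for closed-loop codon tests;
* planted fragments: source gene sampled by weight (uniform over the 13
  PCGs by default; a *cox1*-dominated preset mirrors the transfer profile
  reported in insects), fragment start uniform within the gene, length
  uniform in 150–1500 bp, substitutions at rate $d$ (uniform over the three
  alternative bases, i.e. Jukes–Cantor-like with no
  transition/transversion bias — the simplest model consistent with an
  identity-threshold analysis), indels at rate $g$ with geometric lengths,
  insertion sites chosen with probability proportional to (local 100-bp
  AT)$^\beta$.

The default benchmark is three contigs totalling 120 kb with 20 fragments
at $d = 0.05$, $g = 0.005$, $\beta = 0$.

Design choices worth recording:

* **Truth coordinates are final coordinates.** Insertion sites are chosen
  in the pre-insertion system; cumulative offsets convert them to the
  post-insertion system before the truth table is written, so truth/call
  comparison is a pure interval intersection.
* **Minimum site spacing.** Insertion sites on one contig are kept at least
  200 bp apart (and 150 bp from contig ends), so each Numt's 100-bp flank
  windows contain only background sequence, never a neighbouring insertion.
  Non-overlap alone would allow flank contamination that biases the AT
  statistics.
* **Determinism.** Every stage derives a named substream from the single
  top-level seed, so stages re-run in isolation reproduce the pipeline run
  byte for byte.

What the generator does **not** emulate: repeat landscapes and transposable
elements (the main source of spurious homology in real genomes),
chromosome-scale contiguity, assembly artefacts, and post-insertion decay
heterogeneity (every site mutates at the same rate). Passing the benchmark
therefore demonstrates the correctness of the machinery — alignment scores,
statistics, coordinate bookkeeping, threshold logic — not field
performance on repeat-rich genomes.

## Statistical choices

* **Spearman p-values** use the t-approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df (the asymptotic method of
  `cor.test`). Exact and Edgeworth methods can differ in the second
  significant digit; the coefficient, not the p-value, is the quantity
  compared across studies.
* **The flank AT test** is a *paired* one-tailed t-test across species:
  each species contributes one pooled flank AT value and one genome AT
  value. Pairing is the only alignment of the two vectors that uses the
  per-species structure of a multi-species survey. Species-level flank AT
  pools bases (weighted by actual flank lengths, clipped flanks contribute
  what they have) rather than averaging per-flank fractions, which would be
  biased under variable flank lengths. The upstream-vs-downstream
  comparison uses the same machinery, one-tailed "greater" by default.
* **Degenerate inputs.** A paired test on identical vectors returns
  statistic 0 and one-tailed p = 0.5; zero rank variance makes Spearman's
  rho undefined (`NA`); empty or fully ambiguous sequences have undefined
  AT content (`NA`).

## Verification strategy

The seeded aligner is verified against a full Smith–Waterman
(Gotoh affine) implementation — itself cross-checked against
`Biostrings::pairwiseAlignment` — on hundreds of seeded random pairs
containing a planted, 0–10% diverged copy of part of the query. These
equivalence suites run at word size 8: with words of 11 a short planted
copy at 10% divergence occasionally retains no intact 11-mer, which no
word-seeded aligner (BLASTN included) can find; the suite tests extension
exactness, not seeding sensitivity. End-to-end recovery is measured as
recall/precision against the generator's truth table; codon tabulation is
checked in closed loop against the generator's codon assignments; the
AT-bias test is checked both for power (β = 4 with hotspots) and for type-I
error calibration (β = 0, 500 replicates, binomial bounds).

Two idealizations surfaced during verification and are worth knowing about.
First, a maximal-scoring local alignment over an unmutated planted copy can
extend a few columns past the insertion boundary when the adjacent random
sequence happens to score positively, so hit identity over a perfect copy
is very close to, but not always exactly, 1. Second, heavily diverged long
fragments (e.g. 45% substitution divergence) are *mostly* — not always —
invisible to the filter cascade: a 1.5-kb fragment at 55% average identity
occasionally retains a >50-bp local core above 60% identity with E ≤ 10⁻⁴,
and such cores are reported by NCBI BLASTN under the same thresholds too.
Detection decays sharply with divergence, but the wall is not absolute.

## Problem sizes

The shipped tests and the acceptance script use the default 120-kb
benchmark (seconds per end-to-end run), 200-trial alignment equivalence
suites, a 12-species AT-bias study, and 500 null replicates for the
calibration check; these sizes were chosen so the full suite exercises
every code path in a few minutes while keeping every statistical check
well-powered.

## Limitations

* E-values are Karlin–Altschul-comparable but not bit-identical to NCBI
  BLASTN (no gapped recalibration or length adjustment); threshold
  decisions at E = 10⁻⁴ can differ for borderline hits. Import real BLASTN
  output if bit-exact parity matters.
* No low-complexity masking by default (configurable off/on is not yet a
  dust implementation; seeds are simply exact words). AT-rich insect
  genomes searched with AT-rich mitochondrial queries can produce
  borderline hits that masking would suppress; the E-value filter absorbs
  this at the scales tested.
* Numt age estimation, cross-species orthology of insertions
  (synaponumts), and chromosome-level localization are out of scope.
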