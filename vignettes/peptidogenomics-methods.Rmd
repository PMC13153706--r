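---
title: "Methods: six-frame peptidogenomics in sixpep"
author: "sixpep maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-frame peptidogenomics in sixpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixpep)
```

## The model

An endogenous peptide identified by mass spectrometry is a short
amino-acid string with no intrinsic genomic address. `sixpep` gives it
one by searching a *coordinate-tracked six-frame translation database*:
every chromosome is conceptually translated on both strands in all three
frame offsets, each translation is cut at stop codons (TAA/TAG/TGA,
standard genetic code), and every maximal stop-free run of at least
`min_len` residues becomes a database segment carrying its
forward-strand, 0-based half-open genomic interval, strand and frame.
A peptide found as a substring of a segment at residue offset $k$ with
length $m$ maps to $[s + 3k,\; s + 3(k+m))$ on the plus strand, or
$[e - 3(k+m),\; e - 3k)$ on the minus strand, where $[s, e)$ is the
segment's interval. Peptides matching more than one locus are discarded
rather than assigned arbitrarily: all downstream statistics are about
peptides with a single unambiguous genomic origin.

Classification against gene models then separates conventional peptides
(CPs) from non-conventional peptides (NCPs). A locus is a CP if and only
if it lies fully inside annotated CDS of a transcript on the same strand
*and* its reading frame agrees with the annotated CDS phase at every
covered base. On the plus strand that reduces to
$\mathrm{start} \equiv \mathrm{cds\_start} + \mathrm{phase} \pmod 3$; on
the minus strand, reading right-to-left,
$\mathrm{end} \equiv \mathrm{cds\_end} - \mathrm{phase} \pmod 3$.
Everything else is an NCP: `OUT_OF_FRAME_EXON` (exonic, overlapping CDS,
failing the strand or phase test — antisense to a CDS counts as
out-of-frame), `UTR5`/`UTR3` (contained in UTR exonic intervals),
`INTRON`, and `INTERGENIC` (no overlap with any gene span, where a gene
span is the transcript extent including UTRs and introns).

### Design choices that were genuinely open

* **Stop-codon restart.** The segmentation resumes translation at the
  next *codon in the same frame* after a stop. Restarting at the literal
  next nucleotide would shift frame and duplicate content already
  covered by the other frame offsets; same-frame restart keeps the six
  frames disjoint and complete.
* **Precedence.** A locus touching several annotation element types
  takes the most-coding-like one:
  CP > OUT_OF_FRAME_EXON > UTR5 > UTR3 > INTRON > INTERGENIC.
  Because the database is unspliced, a genuine CP can only ever be
  contained in a single CDS piece, so exon/intron boundary-straddlers
  can never be called CP; they fall to out-of-frame when they touch CDS.
* **Full containment, precedence fallback.** Containment in a single
  element is required for the clean categories; partial overlaps resolve
  by the same precedence over the element types touched.
* **Unique-locus rule.** Multi-locus peptides are dropped entirely.
  The alternative (random assignment) would contaminate every
  per-category statistic with placement noise.
* **Ile/Leu.** Mass spectrometry cannot distinguish Ile from Leu. The
  mapper's default treats them as distinct letters (reproducing how
  identified sequences are usually reported); `il_equiv = TRUE` exists
  for sensitivity analysis.
* **TSS.** Distances are measured to the *translation initiation site*
  (first base of annotated CDS), the convention used in the
  peptide-distribution analysis this package supports, not the
  transcription start.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_len` | 5 | residues | minimum database segment length; no published database-side minimum exists, so it is configurable and recorded in the database sidecar |
| `min_pep_len` | 6 | residues | shortest peptide worth mapping; shorter sequences are almost never unique in a genome-scale database |
| `fdr_threshold` | 0.05 | — | strict `<` bound on identification FDR; a row at exactly 0.05 is excluded |
| `window_size`, `step` | 6 Mb, 3 Mb | nt | sliding-window density geometry |
| `hotspot_threshold` | 10 | loci | hotspot = window count strictly greater than this |
| `spacing_cutoff` | 100 kb | nt | adjacent-spacing reporting bound |
| `tss_window` | 700 | nt | TSS-proximity reporting bound |
| `fold` (tissue) | 15 | — | enhancement threshold, boundary inclusive ("at least 15 times") |

The tissue rule compares the top tissue's mean against the **maximum**
of the other detected tissues' means (the strictest reading of "higher
than that in other tissues"); `other = "mean"` switches to the laxer
mean-of-others variant for sensitivity analysis.

## Numerical choices

* **Ambiguity resolution.** Every non-ACGT IUPAC symbol is replaced by a
  uniform draw among the bases it denotes, using an RNG seeded from
  (seed, chromosome name), once, before translation; the resolved genome
  is cached on the database (with an MD5 digest) so mapping and
  start-codon extraction see exactly the sequence the database saw.
  `start_codon()` refuses loci whose recorded digest does not match.
* **Masses.** Average (not monoisotopic) residue masses, the
  conventional scale for population-level molecular-weight summaries;
  MW = residue sum + 18.0153 Da.
* **Isoelectric point.** Net charge is a Henderson–Hasselbalch sum over
  the termini and the D/E/C/Y/H/K/R side chains with a Bjellqvist-style
  pKa table (N-term 7.50, C-term 3.55, C 9.00, D 4.05, E 4.45, H 5.98,
  K 10.00, R 12.00, Y 10.00); the root is found by bisection on
  [0, 14] to 1e-3 pH. The charge function is strictly decreasing in pH,
  so bisection is exact up to tolerance; tests verify agreement with a
  1e-4-step grid scan to 2e-3.
* **Percent identity** slides the shorter sequence along the longer at
  every full-containment offset and divides the best match count by the
  *longer* length — the only convention under which an 8-mer perfectly
  contained in a 13-mer scores 61.54%.
* **Window list.** Window starts advance by `step` until the previous
  window has reached the chromosome end; the final window is truncated,
  never discarded, so short chromosomes still contribute. A locus is
  assigned to windows by its start coordinate (point density), so an
  interior locus is counted in exactly two overlapping windows.
* **circRNA translation.** Circular sequences are doubled head-to-tail
  before three-frame translation so junction-spanning runs are
  representable. When the monomer length is divisible by 3 the reading
  frame repeats each lap and a stop-free doubled run would contain the
  monomer peptide twice, so runs are truncated to one circle (monomer
  codon count); when the length is not divisible by 3 the frame shifts
  per lap, doubled runs are genuinely new sequence, and they are kept
  whole. This is the only reading consistent with requiring the
  junction peptide MEW from circular `ATGGA` while still preventing
  artificial multi-lap repeats.
* **Degenerate inputs.** Chromosomes with a single locus contribute an
  infinite spacing distance (denominator only); chromosomes without any
  annotated CDS yield undefined TSS distances, excluded from the summary
  with a logged count; sub-3-nt transcripts translate to an empty set
  with a warning.

## The synthetic-data generator

`simulate_study()` is the package's test bed: everything downstream of
spectral identification is validated against data with planted truth.

* `generate_genome()`: i.i.d. bases at a set GC fraction (default 0.42,
  a typical mammalian value), with an `N` fraction (default 0.1%)
  exercising ambiguity resolution.
* `plant_gene_models()`: non-overlapping genes (1–4 exons, CDS pieces of
  150–450 nt with correct GFF3 phases, UTRs of 100–250 nt — long enough
  to host the longest plantable peptide — introns of 300–1500 nt,
  ≥ 5 kb intergenic separation), with the CDS bases overwritten by a
  stop-free in-frame coding sequence starting at ATG.
* `plant_peptidome()`: peptides of 6–30 residues read directly off the
  resolved genome at loci satisfying their target category, accepted
  only if they classify to that category and occur exactly once in the
  whole six-frame database (rejection sampling, capped at 1,000 attempts
  per peptide to guarantee termination). The default mix is 8% CP and
  92% NCP split 61/38/0.6/0.2/0.2 across
  intergenic/intron/3'UTR/5'UTR/out-of-frame — the category proportions
  typical of a mammalian endogenous peptidome. An optional hotspot
  places a cluster of intergenic peptides inside one chosen window.
* `plant_tissue_matrix()`: SPECIFIC peptides in one tissue; ENHANCED at
  ≥ 2× the fold threshold above all other detected tissues; MIXED with
  max/min ratio below half the threshold; multiplicative log-normal
  replicate noise at σ = 0.2 (the generator has no published intensity
  model to copy, so noise is a parameter). The planted margins are ≥ 2×
  away from the decision boundary, so recovery is exact at default
  noise by construction.

The default study is 2 chromosomes × 10 Mb, 50 genes, 2,000 peptides —
the scale used in the end-to-end recovery test; unit tests use smaller
genomes (50–200 kb) where the same code paths are exercised in seconds.
One master seed fans out to per-stage seeds (`stage_seed()`), making the
entire study byte-reproducible.

**What passing on synthetic data does and does not show.** The generator
emulates the *structure* the pipeline consumes: gene models with correct
phases, peptides of every genomic category, density clusters, and
fold-change tissue patterns. It does not emulate real spectral noise,
repeat-rich or homologous sequence (which would raise the multi-locus
discard rate), biased codon usage, incomplete or conflicting
annotations, or missing-value patterns of real MS quantification.
Perfect recovery here validates the arithmetic and the bookkeeping —
coordinates, phases, thresholds, partitions — not the biological error
rate on a real peptidome.

## Known limitations

* The database is deliberately unspliced: peptides spanning exon–exon
  junctions are out of reach, exactly as for any genome-level six-frame
  search.
* Only the standard genetic code is supported; selenocysteine and
  pyrrolysine are not modeled.
* Classification takes annotation at face value; it does not reconcile
  conflicting transcript models beyond the stated precedence.
* The FDR, score and abundance columns of identification tables are
  consumed, not computed — spectral search and quantification are
  upstream of this package.
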