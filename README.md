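# sixpep

Peptidogenomics toolkit: mapping mass-spectrometry-identified endogenous
peptides onto a genome through a coordinate-tracked six-frame translation
database, and characterizing the non-conventional peptides (NCPs) that do
not come from annotated in-frame coding sequence.

## The problem

Spectral searches against a standard proteome can only ever re-identify
annotated proteins. Endogenous peptidomes, however, contain large numbers
of peptides translated from supposedly non-coding sequence — intergenic
regions, introns, UTRs, alternative reading frames of known exons, and
ncRNAs. To find them, the search database must be the genome itself:
every chromosome conceptually translated in all six reading frames,
segmented at stop codons, with each segment's genomic coordinates and
orientation carried along so an identified peptide can be placed back on
the genome.

`sixpep` implements that workflow for anyone analyzing an endogenous
peptidome against a genome (peptidomics / proteogenomics of any organism
with an assembly and a GFF3 annotation):

1. **Database** — `build_sixframe_db()` resolves IUPAC ambiguity codes
   with a seeded RNG, translates every chromosome × strand × frame
   (standard genetic code, stops TAA/TAG/TGA), and keeps each maximal
   stop-free run of ≥ `min_len` residues as a segment with forward-strand
   0-based half-open coordinates. Export/import:
   `write_sixframe_fasta()` with the header dialect
   `>{chrom}|{strand}|{frame}|{start}|{end}`.
2. **Mapping** — `locate_peptide()` finds every exact occurrence of a
   peptide inside the segments (coordinates derived as
   `[seg_start + 3k, seg_start + 3(k+m))` on `+`, end-anchored on `-`);
   `unique_locus_filter()` keeps only peptides assignable to a single
   genomic locus.
3. **Classification** — `classify_loci()` labels each locus `CP`
   (fully inside annotated CDS, same strand, codon phase agreeing with
   the annotated phase at every position) or one of the NCP categories
   `OUT_OF_FRAME_EXON`, `UTR5`, `UTR3`, `INTRON`, `INTERGENIC`, with the
   precedence CP > out-of-frame > UTR5 > UTR3 > intron > intergenic.
4. **Genome-scale statistics** — 6-Mb sliding windows with 3-Mb steps
   (`window_density()`), hotspots as windows with count strictly > 10
   (`detect_hotspots()`), adjacent-peptide spacing, distances to
   translation initiation sites, arm-normalized positions, and
   count-vs-chromosome-length Pearson correlation.
5. **Properties** — average-mass molecular weight, bisection isoelectric
   point, hydrophobic/hydrophilic composition (8-residue vs 11-residue
   sets, Ile in neither), genomic start codons (AUG vs non-AUG), and
   ungapped percent identity (`percent_identity()`).
6. **Tissue patterns** — `classify_tissue_pattern()`: SPECIFIC (one
   tissue only), ENHANCED (top tissue ≥ 15× the other detected tissues,
   boundary inclusive), MIXED otherwise; `overlap_analysis()` for
   tissue co-detection counts.
7. **ncRNA / Ribo-seq support** — `transcript_translations()` (three
   sense frames, circRNA sequences doubled head-to-tail so
   junction-spanning peptides are found) and `match_support()`.
8. **Synthetic studies** — `generate_genome()`, `plant_gene_models()`,
   `plant_peptidome()`, `plant_tissue_matrix()` build fully synthetic
   genomes, annotations, peptidomes and abundance matrices with known
   truth labels; `simulate_study()` runs the whole pipeline on them.

## Worked example

```r
library(sixpep)

study <- simulate_study(seed = 41, lengths = rep(2e5, 2), n_genes = 8,
                        n_peptides = 80, config = pipeline_config(seed = 41))
r <- study$report
r$n_mapped_unique; r$n_cp; r$n_ncp; r$ncp_pct
#> 80    6    74    92.5
r$category_tally
#>            category  n   pct
#> 1                CP  6  7.50
#> 2 OUT_OF_FRAME_EXON  0  0.00
#> 3              UTR5  0  0.00
#> 4              UTR3  1  1.25
#> 5            INTRON 28 35.00
#> 6        INTERGENIC 45 56.25
head(study$classified[, c("peptide", "chrom", "start", "category", "mw", "pi")], 2)
#>            peptide chrom start   category       mw       pi
#> 1  FSRLYILNPYMSEEA  chr1 31265 INTERGENIC 1833.089 4.531799
#> 2 SLTMTCVRPFSFSWWS…  chr2 35698     INTRON 3234.719 10.145813
```

All 80 planted peptides are recovered at their planted locus with their
planted category (`category recovery: 1`); the NCP share (92.5%) reflects
the planted 8% CP fraction. `r$aug_fraction` (0.05 here) shows the strong
non-AUG start-codon preference expected when peptides arise outside
annotated initiation contexts, and `r$tissue_class_counts` recovers the
planted SPECIFIC/ENHANCED/MIXED pattern labels exactly.

A thin command-line wrapper is installed at
`inst/scripts/sixpep-pipeline.R` with `simulate`, `build-db` and
`run-all` subcommands over the same functions.

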