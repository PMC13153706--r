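LOCUS_CATEGORIES <- c("CP", "OUT_OF_FRAME_EXON", "UTR5", "UTR3",
                      "INTRON", "INTERGENIC")

#' Codon phase implied by a locus at a genomic position
#'
#' For a peptide locus translated on its strand, returns the codon
#' phase (0, 1 or 2) the translation implies at any covered genomic
#' position: 0 at the first base read, 1 at the second, and so on,
#' reading left-to-right on `+` loci and right-to-left on `-` loci.
#'
#' @param locus one-row data frame (or list) with `start`, `end`,
#'   `strand`.
#' @param position genomic position(s), 0-based.
#' @return integer phase(s) in 0-2.
#' @export
locus_frame_phase <- function(locus, position) {
  if (any(position < locus$start | position >= locus$end)) {
    stop("position outside locus [", locus$start, ",", locus$end, ")")
  }
  if (locus$strand == "+") {
    (position - locus$start) %% 3L
  } else {
    (locus$end - 1L - position) %% 3L
  }
}

# Per-chromosome feature tables, precomputed once per GeneModels object
classifier_index <- function(models) {
  fe <- models$features
  tx <- models$transcripts
  genes <- models$genes
  list(
    fe_by_chrom = split(fe, fe$chrom),
    gene_by_chrom = split(genes, genes$chrom),
    tx = tx
  )
}

# A '+' locus is in-frame with a CDS piece iff locus start and
# (cds start + phase) are congruent mod 3; on '-' iff locus end and
# (cds end - phase) are congruent mod 3 (reading right to left).
cds_in_frame <- function(locus, cds) {
  if (locus$strand != cds$strand) return(FALSE)
  if (cds$strand == "+") {
    (locus$start %% 3L) == ((cds$start + cds$phase) %% 3L)
  } else {
    (locus$end %% 3L) == ((cds$end - cds$phase) %% 3L)
  }
}

classify_one <- function(locus, idx) {
  fe <- idx$fe_by_chrom[[locus$chrom]]
  genes <- idx$gene_by_chrom[[locus$chrom]]
  gene_hit <- "."
  if (!is.null(genes) && nrow(genes)) {
    ov <- genes$start < locus$end & genes$end > locus$start
    if (any(ov)) gene_hit <- genes$gene_id[which(ov)[1]]
  }
  if (gene_hit == ".") {
    return(list(category = "INTERGENIC", gene_id = "."))
  }
  ov <- fe[fe$start < locus$end & fe$end > locus$start, , drop = FALSE]
  contained <- ov[ov$start <= locus$start & ov$end >= locus$end, , drop = FALSE]

  # containment-based calls, most-coding-like first
  cds_cont <- contained[contained$type == "cds", , drop = FALSE]
  if (nrow(cds_cont)) {
    for (i in seq_len(nrow(cds_cont))) {
      if (cds_in_frame(locus, cds_cont[i, ])) {
        return(list(category = "CP", gene_id = gene_hit))
      }
    }
  }
  cds_ov <- ov[ov$type == "cds", , drop = FALSE]
  exon_cont <- contained[contained$type == "exon", , drop = FALSE]
  if (nrow(cds_ov) && nrow(exon_cont)) {
    return(list(category = "OUT_OF_FRAME_EXON", gene_id = gene_hit))
  }
  if (nrow(contained[contained$type == "utr5", , drop = FALSE])) {
    return(list(category = "UTR5", gene_id = gene_hit))
  }
  if (nrow(contained[contained$type == "utr3", , drop = FALSE])) {
    return(list(category = "UTR3", gene_id = gene_hit))
  }
  if (nrow(contained[contained$type == "intron", , drop = FALSE])) {
    return(list(category = "INTRON", gene_id = gene_hit))
  }

  # partial overlaps: precedence over whatever element types are touched
  if (nrow(cds_ov)) {
    return(list(category = "OUT_OF_FRAME_EXON", gene_id = gene_hit))
  }
  for (ty in c("utr5", "utr3", "intron")) {
    if (nrow(ov[ov$type == ty, , drop = FALSE])) {
      return(list(category = toupper(sub("utr5", "UTR5", sub("utr3", "UTR3", ty))),
                  gene_id = gene_hit))
    }
  }
  # overlaps a gene span but none of its features (e.g. a gene whose
  # transcript does not tile the whole span): treat as intronic space
  list(category = "INTRON", gene_id = gene_hit)
}

#' Classify peptide loci against gene models
#'
#' Implements the conventional/non-conventional partition: a locus is
#' `CP` iff it lies fully inside annotated CDS of some transcript on
#' the same strand and its reading frame agrees with the annotated CDS
#' phase at every covered position. Exonic loci overlapping CDS that
#' fail the strand or phase test are `OUT_OF_FRAME_EXON` (antisense to
#' a CDS counts as out-of-frame). Loci fully within 5'/3' UTR exonic
#' intervals are `UTR5`/`UTR3`, fully intronic loci are `INTRON`, and
#' loci overlapping no gene span are `INTERGENIC`. Partial overlaps and
#' multi-transcript conflicts resolve by the precedence
#' CP > OUT_OF_FRAME_EXON > UTR5 > UTR3 > INTRON > INTERGENIC.
#'
#' @param loci data frame with `chrom`, `start`, `end`, `strand` (and
#'   typically `peptide`).
#' @param models a `GeneModels` object.
#' @return `loci` with added columns `category` and `gene_id` (`"."`
#'   for intergenic loci).
#' @export
classify_loci <- function(loci, models) {
  stopifnot(inherits(models, "GeneModels"))
  missing_chrom <- setdiff(unique(loci$chrom), models$seqnames)
  if (length(missing_chrom)) {
    stop("locus chromosome(s) absent from the annotation universe: ",
         paste(missing_chrom, collapse = ", "))
  }
  idx <- classifier_index(models)
  if (nrow(loci) == 0L) {
    loci$category <- character(0)
    loci$gene_id <- character(0)
    return(loci)
  }
  res <- lapply(seq_len(nrow(loci)), function(i) classify_one(loci[i, ], idx))
  loci$category <- vapply(res, `[[`, "", "category")
  loci$gene_id <- vapply(res, `[[`, "", "gene_id")
  loci
}

#' Partition classified loci into CPs and NCPs
#'
#' Conventional peptides (CPs) are in-frame CDS matches; every other
#' category (intergenic, intron, UTRs, out-of-frame exon) is a
#' non-conventional peptide (NCP). Reports category and strand tallies
#' with percentages to two decimal places.
#'
#' @param classified data frame from [classify_loci()].
#' @return a list with `cp`, `ncp` (row subsets), `category_tally`
#'   (count and percentage per category), `strand_tally` (per class and
#'   strand), `cp_pct`, `ncp_pct`.
#' @export
cp_ncp_partition <- function(classified) {
  stopifnot(all(c("category", "strand") %in% names(classified)))
  stopifnot(all(classified$category %in% LOCUS_CATEGORIES))
  cp <- classified[classified$category == "CP", , drop = FALSE]
  ncp <- classified[classified$category != "CP", , drop = FALSE]
  n <- nrow(classified)
  cat_counts <- table(factor(classified$category, levels = LOCUS_CATEGORIES))
  category_tally <- data.frame(
    category = names(cat_counts),
    n = as.integer(cat_counts),
    pct = vapply(as.integer(cat_counts), pct, 0, total = n),
    stringsAsFactors = FALSE
  )
  strand_tally <- data.frame(
    class = rep(c("CP", "NCP"), each = 2),
    strand = rep(c("+", "-"), 2),
    n = c(sum(cp$strand == "+"), sum(cp$strand == "-"),
          sum(ncp$strand == "+"), sum(ncp$strand == "-")),
    stringsAsFactors = FALSE
  )
  list(cp = cp, ncp = ncp,
       category_tally = category_tally, strand_tally = strand_tally,
       cp_pct = pct(nrow(cp), n), ncp_pct = pct(nrow(ncp), n))
}
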