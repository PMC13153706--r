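# Independent oracles and shared fixtures. The oracles deliberately use
# a different route than the package: seqinr's codon translation and
# explicit per-window loops instead of Biostrings vectorized calls.

toy_genome <- c(chr1 = "ATGGCCTAAGGG")

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# seqinr-based translation of a nucleotide string (character in/out)
oracle_translate <- function(nt) {
  paste(seqinr::translate(strsplit(tolower(nt), "")[[1]]), collapse = "")
}

# Brute-force six-frame runs for one chromosome: full-frame translation
# split at stops, filtered by min_len. Returns aa runs per
# (strand, frame), without coordinates (coordinates are checked by the
# round-trip invariant instead).
oracle_sixframe_runs <- function(chrom_seq, min_len = 5L) {
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") chrom_seq else oracle_revcomp(chrom_seq)
    for (frame in 0:2) {
      n_codon <- (nchar(s) - frame) %/% 3L
      if (n_codon < 1L) {
        out[[paste(strand, frame)]] <- character(0)
        next
      }
      aa <- oracle_translate(substr(s, frame + 1L, frame + 3L * n_codon))
      runs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      out[[paste(strand, frame)]] <- runs[nchar(runs) >= min_len]
    }
  }
  out
}

# Naive all-window scan: every genomic window of length 3m, both
# strands, translated and compared with the peptide.
oracle_locate <- function(peptide, genome) {
  m <- nchar(peptide)
  hits <- list()
  for (nm in names(genome)) {
    chrom <- genome[[nm]]
    L <- nchar(chrom)
    if (L < 3 * m) next
    for (start in 0:(L - 3 * m)) {
      win <- substr(chrom, start + 1L, start + 3L * m)
      if (oracle_translate(win) == peptide) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = nm, strand = "+", start = start, end = start + 3L * m,
          stringsAsFactors = FALSE)
      }
      if (oracle_translate(oracle_revcomp(win)) == peptide) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = nm, strand = "-", start = start, end = start + 3L * m,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

random_genome <- function(seed, len = 1000L, n_chrom = 1L) {
  set.seed(seed)
  g <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

random_peptides <- function(seed, n, len_range = c(5L, 15L)) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(sixpep:::AA_LETTERS, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# The spec-style single-transcript gene model used across classifier
# tests: '+' strand, exons [100,200)+[300,400), CDS [130,200)+[300,340)
# with phases 0 and 2, UTR5 [100,130), UTR3 [340,400).
example_models <- function() {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 100, end = 400, stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "g1.t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", start = 100, end = 400,
                   stringsAsFactors = FALSE)
  fe <- data.frame(
    transcript_id = "g1.t1",
    type = c("exon", "exon", "cds", "cds", "utr5", "utr3", "intron"),
    chrom = "chr1", strand = "+",
    start = c(100, 300, 130, 300, 100, 340, 200),
    end = c(200, 400, 200, 340, 130, 400, 300),
    phase = c(NA, NA, 0L, 2L, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  gene_models(genes, tx, fe, seqnames = c("chr1", "chr9"))
}

make_locus <- function(chrom, start, end, strand, peptide = "PEPTIDE") {
  data.frame(peptide = peptide, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

tissues6 <- c("liver", "lung", "spleen", "muscle", "intestine", "testis")
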