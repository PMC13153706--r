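#' Peptide molecular weight (average mass)
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param peptide amino-acid string.
#' @param tables a [residue_tables()] list.
#' @return mass in Daltons.
#' @export
molecular_weight <- function(peptide, tables = residue_tables()) {
  check_peptide(peptide)
  sum(tables$masses[strsplit(peptide, "")[[1]]]) + tables$water
}

# Net charge at a given pH (Henderson-Hasselbalch sum over the
# N-terminus, C-terminus and ionizable side chains)
net_charge <- function(peptide, pH, tables = residue_tables()) {
  pka <- tables$pka
  comp <- table(strsplit(peptide, "")[[1]])
  cnt <- function(a) if (a %in% names(comp)) as.numeric(comp[[a]]) else 0
  pos <- 1 / (1 + 10^(pH - pka["Nterm"])) +
    cnt("K") / (1 + 10^(pH - pka["K"])) +
    cnt("R") / (1 + 10^(pH - pka["R"])) +
    cnt("H") / (1 + 10^(pH - pka["H"]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH)) +
    cnt("D") / (1 + 10^(pka["D"] - pH)) +
    cnt("E") / (1 + 10^(pka["E"] - pH)) +
    cnt("C") / (1 + 10^(pka["C"] - pH)) +
    cnt("Y") / (1 + 10^(pka["Y"] - pH))
  unname(pos - neg)
}

#' Peptide isoelectric point
#'
#' The pH at which the net charge is zero, found by bisection on
#' `[0, 14]` to a tolerance of 1e-3 pH units. The charge model is a
#' Henderson-Hasselbalch sum over the termini and the ionizable side
#' chains of D, E, C, Y, H, K, R with a Bjellqvist-style pKa table
#' (configurable through [residue_tables()]).
#'
#' @inheritParams molecular_weight
#' @param tol bisection tolerance in pH units.
#' @return pH of zero net charge.
#' @export
isoelectric_point <- function(peptide, tables = residue_tables(), tol = 1e-3) {
  check_peptide(peptide)
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(peptide, mid, tables) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Hydrophobic and hydrophilic residue counts
#'
#' Counts against the fixed eight-residue hydrophobic set
#' (G, A, V, L, P, M, F, W) and eleven-residue hydrophilic set
#' (S, T, Y, C, N, Q, D, E, R, K, H). Isoleucine belongs to neither
#' set, so the two counts plus the Ile count equal the peptide length.
#'
#' @inheritParams molecular_weight
#' @return named integer vector `c(n_hydrophobic, n_hydrophilic)`.
#' @export
hydropathy_counts <- function(peptide, tables = residue_tables()) {
  check_peptide(peptide)
  chars <- strsplit(peptide, "")[[1]]
  c(n_hydrophobic = sum(chars %in% tables$hydrophobic),
    n_hydrophilic = sum(chars %in% tables$hydrophilic))
}

#' Genomic start codon of a peptide locus
#'
#' Reads the first codon of the locus on its strand from the
#' ambiguity-resolved genome the database was built from, and reports
#' whether it is the canonical AUG initiator (DNA `ATG`).
#'
#' @param loci data frame of loci (`chrom`, `start`, `end`, `strand`),
#'   optionally carrying a `genome_digest` attribute.
#' @param genome resolved genome (named character vector) as stored on
#'   a `TranslationDB`; if `loci` carries a `genome_digest` attribute
#'   it must match the genome's digest.
#' @return a data frame with columns `codon` and `is_aug`.
#' @export
start_codon <- function(loci, genome) {
  ld <- attr(loci, "genome_digest")
  gd <- attr(genome, "digest")
  if (!is.null(ld) && !is.null(gd) && !identical(ld, gd)) {
    stop("locus/genome digest mismatch: loci were mapped against a ",
         "different resolved genome")
  }
  codon <- vapply(seq_len(nrow(loci)), function(i) {
    chrom <- genome[[loci$chrom[i]]]
    if (loci$strand[i] == "+") {
      substr(chrom, loci$start[i] + 1L, loci$start[i] + 3L)
    } else {
      revcomp(substr(chrom, loci$end[i] - 2L, loci$end[i]))
    }
  }, character(1))
  data.frame(codon = codon, is_aug = codon == "ATG", stringsAsFactors = FALSE)
}

#' Percent identity under best ungapped containment alignment
#'
#' Slides the shorter sequence along the longer at every offset where
#' it is fully contained, takes the best match count, and normalizes by
#' the longer sequence's length (so an 8-mer perfectly contained in a
#' 13-mer scores 8/13).
#'
#' @param peptide,reference amino-acid strings.
#' @return percent identity rounded to two decimals.
#' @export
percent_identity <- function(peptide, reference) {
  check_peptide(peptide)
  check_peptide(reference)
  a <- strsplit(peptide, "")[[1]]
  b <- strsplit(reference, "")[[1]]
  if (length(a) > length(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  ns <- length(a)
  nl <- length(b)
  best <- 0L
  for (off in 0:(nl - ns)) {
    best <- max(best, sum(a == b[(off + 1):(off + ns)]))
  }
  round(100 * best / nl, 2)
}

#' Physicochemical property table for peptide loci
#'
#' One row per locus: length, molecular weight, isoelectric point,
#' hydropathy counts, and the genomic start codon.
#'
#' @param loci data frame of mapped loci with a `peptide` column.
#' @param genome resolved genome (for start codons); `NULL` to skip.
#' @param tables a [residue_tables()] list.
#' @return `loci` with columns `length`, `mw`, `pi`, `n_hydrophobic`,
#'   `n_hydrophilic` (and `codon`, `is_aug` when `genome` is given).
#' @export
peptide_properties <- function(loci, genome = NULL,
                               tables = residue_tables()) {
  loci$length <- nchar(loci$peptide)
  loci$mw <- vapply(loci$peptide, molecular_weight, 0, tables = tables,
                    USE.NAMES = FALSE)
  loci$pi <- vapply(loci$peptide, isoelectric_point, 0, tables = tables,
                    USE.NAMES = FALSE)
  chars <- strsplit(loci$peptide, "")
  loci$n_hydrophobic <- vapply(chars, function(x) {
    sum(x %in% tables$hydrophobic)
  }, integer(1))
  loci$n_hydrophilic <- vapply(chars, function(x) {
    sum(x %in% tables$hydrophilic)
  }, integer(1))
  if (!is.null(genome)) {
    sc <- start_codon(loci, genome)
    loci$codon <- sc$codon
    loci$is_aug <- sc$is_aug
  }
  loci
}
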