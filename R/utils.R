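#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide ambiguity codes -> the bases each denotes
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Derive a stage-specific seed from a master seed
#'
#' A single master seed fans out deterministically to per-stage seeds so
#' every pipeline stage is independently reproducible.
#'
#' @param seed master seed (integer).
#' @param stage character stage label.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 10007) %% 2147483647L)
}

# Percentage rounded to a fixed number of decimals
pct <- function(x, total, digits = 2) {
  if (total == 0) return(NA_real_)
  round(100 * x / total, digits)
}

# Validate an amino-acid sequence over the 20 standard residues
check_peptide <- function(peptide, what = "peptide") {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) ||
      nchar(peptide) == 0L) {
    stop(what, " must be a non-empty character string")
  }
  bad <- setdiff(strsplit(peptide, "")[[1]], AA_LETTERS)
  if (length(bad)) {
    stop(what, " '", peptide, "' contains illegal residue(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(peptide)
}

check_peptides <- function(peptides) {
  ok <- grepl(paste0("^[", paste(AA_LETTERS, collapse = ""), "]+$"), peptides)
  if (!all(ok)) {
    stop("illegal residue(s) in peptide(s): ",
         paste(utils::head(peptides[!ok], 5), collapse = ", "))
  }
  invisible(peptides)
}

# Reverse-complement of an ACGT string (resolved genomes carry no ambiguity)
revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# MD5 digest of a genome's canonical serialization (name=seq records)
genome_digest <- function(genome) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(paste0(names(genome), "=", unlist(genome)), tf)
  unname(tools::md5sum(tf))
}
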