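# Concatenated segment subject for fast substring search, memoized on
# the db's cache environment. Segments are joined with '*' so a match
# can never span two segments.
db_subject <- function(db, il_equiv = FALSE) {
  key <- if (il_equiv) "subject_il" else "subject"
  if (!is.null(db$cache[[key]])) return(db$cache[[key]])
  seqs <- db$segments$aa_seq
  concat <- paste(seqs, collapse = "*")
  if (il_equiv) concat <- chartr("I", "L", concat)
  # 1-based start of each segment within the concatenation
  starts <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]
  obj <- list(aa = Biostrings::AAString(concat), starts = starts)
  db$cache[[key]] <- obj
  obj
}

#' Locate a peptide in a six-frame database
#'
#' Exact substring search of the peptide over every database segment
#' (overlapping occurrences included). Matching is within-segment only:
#' a peptide cannot span a stop codon, mirroring how the database was
#' segmented. Genomic coordinates are derived from the containing
#' segment's coordinates and the residue offset of the match.
#'
#' @param peptide amino-acid string (20 standard residues).
#' @param db a `TranslationDB`.
#' @param il_equiv if `TRUE`, isoleucine and leucine match
#'   interchangeably (mass spectrometry cannot distinguish them);
#'   default `FALSE`.
#' @return a data frame with one row per occurrence: `peptide`,
#'   `chrom`, `strand`, `frame`, `start`, `end`, `segment_offset`.
#' @export
locate_peptide <- function(peptide, db, il_equiv = FALSE) {
  check_peptide(peptide)
  stopifnot(inherits(db, "TranslationDB"))
  empty <- data.frame(peptide = character(0), chrom = character(0),
                      strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      segment_offset = integer(0), stringsAsFactors = FALSE)
  if (nrow(db$segments) == 0L) return(empty)
  subj <- db_subject(db, il_equiv)
  pat <- if (il_equiv) chartr("I", "L", peptide) else peptide
  hits <- Biostrings::matchPattern(Biostrings::AAString(pat), subj$aa)
  if (length(hits) == 0L) return(empty)
  pos <- Biostrings::start(hits)                     # 1-based in concat
  seg_idx <- findInterval(pos, subj$starts)
  k <- pos - subj$starts[seg_idx]                    # 0-based residue offset
  m <- nchar(peptide)
  seg <- db$segments[seg_idx, ]
  start <- ifelse(seg$strand == "+",
                  seg$start + 3L * k,
                  seg$end - 3L * (k + m))
  end <- start + 3L * m
  data.frame(peptide = peptide, chrom = seg$chrom, strand = seg$strand,
             frame = seg$frame, start = as.integer(start),
             end = as.integer(end), segment_offset = as.integer(k),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Locate many peptides
#'
#' @param peptides character vector of peptide sequences.
#' @inheritParams locate_peptide
#' @return a data frame as in [locate_peptide()], rows for all
#'   peptides; peptides without any occurrence contribute no rows.
#' @export
locate_peptides <- function(peptides, db, il_equiv = FALSE) {
  do.call(rbind, lapply(unique(peptides), locate_peptide, db = db,
                        il_equiv = il_equiv))
}

#' Keep only peptides with a single unambiguous genomic locus
#'
#' Peptides matching multiple loci are discarded entirely rather than
#' assigned arbitrarily. Peptides with no locus at all (an identified
#' sequence absent from the database) are recorded in the discard table
#' with multiplicity 0 and flagged with a warning.
#'
#' @param loci data frame from [locate_peptides()].
#' @param peptides optional full peptide universe, so that zero-hit
#'   peptides are accounted for; defaults to the peptides present in
#'   `loci`.
#' @return a list with `kept` (single-locus data frame, one row per
#'   peptide) and `discarded` (data frame `peptide`, `n_loci`).
#' @export
unique_locus_filter <- function(loci, peptides = NULL) {
  if (is.null(loci)) {
    loci <- data.frame(peptide = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(peptides)) peptides <- unique(loci$peptide)
  peptides <- unique(peptides)
  counts <- table(factor(loci$peptide, levels = peptides))
  n_loci <- as.integer(counts)
  names(n_loci) <- names(counts)
  kept_pep <- names(n_loci)[n_loci == 1L]
  disc_pep <- names(n_loci)[n_loci != 1L]
  if (any(n_loci == 0L)) {
    warning(sum(n_loci == 0L),
            " identified peptide(s) absent from the database")
  }
  kept <- loci[loci$peptide %in% kept_pep, , drop = FALSE]
  kept <- kept[match(kept_pep, kept$peptide), , drop = FALSE]
  rownames(kept) <- NULL
  list(
    kept = kept,
    discarded = data.frame(peptide = disc_pep,
                           n_loci = unname(n_loci[disc_pep]),
                           stringsAsFactors = FALSE)
  )
}

#' Map an identification table to unique genomic loci
#'
#' End-to-end mapping stage: applies the FDR flag from
#' [read_id_table()], drops peptides shorter than `min_pep_len`
#' (short sequences are rarely unique in a genome-scale database),
#' locates the remainder and keeps single-locus peptides only.
#'
#' @param id_table data frame from [read_id_table()] (or any data frame
#'   with `peptide` and optionally `pass_fdr` columns).
#' @param db a `TranslationDB`.
#' @param min_pep_len minimum peptide length to attempt mapping
#'   (default 6).
#' @inheritParams locate_peptide
#' @return a list with `kept`, `discarded` (as in
#'   [unique_locus_filter()]) and `stats`, a one-row data frame of
#'   in/out counts per filter.
#' @export
map_peptides <- function(id_table, db, min_pep_len = 6L, il_equiv = FALSE) {
  stopifnot("peptide" %in% names(id_table))
  pep_all <- unique(id_table$peptide)
  if ("pass_fdr" %in% names(id_table)) {
    pep_fdr <- unique(id_table$peptide[id_table$pass_fdr])
  } else {
    pep_fdr <- pep_all
  }
  pep_len <- pep_fdr[nchar(pep_fdr) >= min_pep_len]
  loci <- locate_peptides(pep_len, db, il_equiv = il_equiv)
  res <- unique_locus_filter(loci, peptides = pep_len)
  res$stats <- data.frame(
    n_peptides = length(pep_all),
    n_pass_fdr = length(pep_fdr),
    n_length_ok = length(pep_len),
    n_unique_locus = nrow(res$kept),
    n_multi_or_zero = nrow(res$discarded)
  )
  res
}
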