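#' Three-frame translations of a transcript
#'
#' Sense-strand conceptual translation in all three frames, split at
#' stop codons into stop-free runs. For circular RNA the sequence is
#' doubled head-to-tail before translation so that runs spanning the
#' back-splice junction are representable. When the monomer length is
#' divisible by 3 the reading frame repeats each lap, so doubled-
#' sequence runs are truncated to one full circle (monomer codon
#' count) to avoid emitting the same peptide twice in a row; when the
#' length is not divisible by 3 the frame shifts per lap and runs are
#' kept whole.
#'
#' @param sequence nucleotide string (sense orientation).
#' @param circular treat the sequence as circular (default `FALSE`).
#' @return character vector of stop-free amino-acid runs (may be
#'   empty); sequences shorter than 3 nt yield an empty set with a
#'   warning.
#' @export
transcript_translations <- function(sequence, circular = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3L) {
    warning("sequence shorter than 3 nt; no translation possible")
    return(character(0))
  }
  subject <- if (circular) paste0(sequence, sequence) else sequence
  runs <- character(0)
  for (frame in 0:2) {
    n_codon <- (nchar(subject) - frame) %/% 3L
    if (n_codon < 1L) next
    coding <- Biostrings::subseq(Biostrings::DNAString(subject),
                                 start = frame + 1L, width = 3L * n_codon)
    aa <- as.character(Biostrings::translate(coding, no.init.codon = TRUE))
    fr <- strsplit(aa, "*", fixed = TRUE)[[1]]
    fr <- fr[nchar(fr) > 0]
    if (circular && L %% 3L == 0L) {
      cap <- L %/% 3L
      fr <- vapply(fr, function(r) substr(r, 1L, cap), character(1),
                   USE.NAMES = FALSE)
    }
    runs <- c(runs, fr)
  }
  unique(runs)
}

#' Match NCPs against transcript-derived translation evidence
#'
#' An NCP is supported by a transcript kind (lncRNA, circRNA or a
#' Ribo-seq-derived ORF set) iff its sequence is a contiguous substring
#' of any stop-free translation run of any transcript of that kind.
#' The union total counts a peptide supported by several kinds once;
#' per-kind totals are reported alongside so the disjoint/overlapping
#' accounting is explicit.
#'
#' @param ncps character vector of NCP sequences.
#' @param transcripts data frame with columns `transcript_id`, `kind`
#'   (one of `lncRNA`, `circRNA`, `riboseq_orf`) and `sequence`.
#' @return a list with `flags` (data frame: `peptide`, one logical
#'   column per kind, `any_support`), `totals` (named counts per kind),
#'   `union_total` and `union_pct` (percentage of all NCPs, one
#'   decimal).
#' @export
match_support <- function(ncps, transcripts) {
  stopifnot(all(c("transcript_id", "kind", "sequence") %in% names(transcripts)))
  kinds <- c("lncRNA", "circRNA", "riboseq_orf")
  bad <- setdiff(unique(transcripts$kind), kinds)
  if (length(bad)) stop("unknown transcript kind(s): ", paste(bad, collapse = ", "))
  check_peptides(ncps)
  ncps <- unique(ncps)
  subject_by_kind <- lapply(kinds, function(k) {
    tr <- transcripts[transcripts$kind == k, , drop = FALSE]
    if (nrow(tr) == 0L) return("")
    runs <- unlist(lapply(seq_len(nrow(tr)), function(i) {
      transcript_translations(tr$sequence[i], circular = (k == "circRNA"))
    }))
    paste(runs, collapse = "*")
  })
  names(subject_by_kind) <- kinds
  flags <- data.frame(peptide = ncps, stringsAsFactors = FALSE)
  for (k in kinds) {
    flags[[k]] <- vapply(ncps, function(p) {
      grepl(p, subject_by_kind[[k]], fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE)
  }
  flags$any_support <- flags$lncRNA | flags$circRNA | flags$riboseq_orf
  support_summary(flags, n_ncps = length(ncps))
}

#' Summarize per-kind support flags
#'
#' @param flags data frame with logical columns `lncRNA`, `circRNA`,
#'   `riboseq_orf` (and optionally `any_support`).
#' @param n_ncps denominator for the union percentage; defaults to
#'   `nrow(flags)`.
#' @return a list with `flags`, `totals`, `union_total`, `union_pct`
#'   (one decimal place).
#' @export
support_summary <- function(flags, n_ncps = nrow(flags)) {
  kinds <- c("lncRNA", "circRNA", "riboseq_orf")
  stopifnot(all(kinds %in% names(flags)))
  if (!"any_support" %in% names(flags)) {
    flags$any_support <- flags$lncRNA | flags$circRNA | flags$riboseq_orf
  }
  totals <- vapply(kinds, function(k) sum(flags[[k]]), integer(1))
  list(flags = flags, totals = totals,
       union_total = sum(flags$any_support),
       union_pct = pct(sum(flags$any_support), n_ncps, digits = 1))
}
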