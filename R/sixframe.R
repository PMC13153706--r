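#' Resolve IUPAC ambiguity codes to concrete bases
#'
#' Every non-ACGT symbol is replaced by a uniformly random choice among
#' the bases that symbol denotes (N by any of A/C/G/T, R by A or G, and
#' so on), using a deterministic generator seeded from the supplied
#' seed and the sequence label, so the same inputs always yield the
#' same resolution. ACGT positions are untouched.
#'
#' @param sequence nucleotide string over the IUPAC alphabet.
#' @param seed integer seed.
#' @param label sequence label (e.g. chromosome name) folded into the
#'   seed so different chromosomes resolve independently.
#' @return the resolved ACGT string.
#' @export
resolve_ambiguity <- function(sequence, seed, label = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_MAP))
  if (length(bad)) {
    stop("symbol(s) outside the IUPAC nucleotide alphabet: ",
         paste(bad, collapse = ", "))
  }
  amb <- which(!(chars %in% c("A", "C", "G", "T")))
  if (length(amb) == 0L) return(sequence)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(stage_seed(seed, paste0("ambiguity:", label)))
  u <- stats::runif(length(amb))
  repl <- vapply(seq_along(amb), function(i) {
    opts <- IUPAC_MAP[[chars[amb[i]]]]
    opts[1L + floor(u[i] * length(opts))]
  }, character(1))
  chars[amb] <- repl
  paste(chars, collapse = "")
}

#' Resolve an entire genome's ambiguity codes
#'
#' @param genome named character vector of IUPAC sequences.
#' @param seed integer seed.
#' @return the resolved genome with attributes `seed` and `digest`
#'   (checksum of the resolved sequence).
#' @export
resolve_genome <- function(genome, seed) {
  out <- vapply(names(genome), function(nm) {
    resolve_ambiguity(genome[[nm]], seed, label = nm)
  }, character(1))
  attr(out, "seed") <- seed
  attr(out, "digest") <- genome_digest(out)
  out
}

#' Translate one frame of one strand of a chromosome
#'
#' Codons are read from offset `frame` (0, 1 or 2) on the given strand;
#' for the minus strand the reverse complement is read and segment
#' coordinates are mapped back to forward-strand intervals. Each
#' maximal stop-free codon run of at least `min_len` residues becomes
#' one segment; stop codons themselves are dropped and translation
#' resumes at the next codon in the same frame. Trailing partial
#' codons are discarded.
#'
#' @param chrom_seq ambiguity-resolved ACGT sequence.
#' @param chrom_name chromosome name recorded in the segments.
#' @param strand `"+"` or `"-"`.
#' @param frame integer 0-2.
#' @param min_len minimum segment length in residues.
#' @return a data frame of segments with columns `chrom`, `strand`,
#'   `frame`, `start`, `end` (forward-strand 0-based half-open) and
#'   `aa_seq`.
#' @export
translate_frame <- function(chrom_seq, chrom_name, strand, frame, min_len = 5L) {
  stopifnot(strand %in% c("+", "-"), frame %in% 0:2, min_len >= 1L)
  L <- nchar(chrom_seq)
  empty <- data.frame(chrom = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      aa_seq = character(0), stringsAsFactors = FALSE)
  read_seq <- if (strand == "+") {
    Biostrings::DNAString(chrom_seq)
  } else {
    Biostrings::reverseComplement(Biostrings::DNAString(chrom_seq))
  }
  n_codon <- (L - frame) %/% 3L
  if (n_codon < 1L) return(empty)
  coding <- Biostrings::subseq(read_seq, start = frame + 1L,
                               width = 3L * n_codon)
  aa <- as.character(Biostrings::translate(coding, no.init.codon = TRUE))
  runs <- gregexpr("[^*]+", aa)[[1]]
  if (runs[1] == -1L) return(empty)
  len <- attr(runs, "match.length")
  keep <- len >= min_len
  if (!any(keep)) return(empty)
  k0 <- as.integer(runs[keep]) - 1L   # 0-based residue offset of run start
  m <- as.integer(len[keep])
  if (strand == "+") {
    start <- frame + 3L * k0
    end <- start + 3L * m
  } else {
    # read-strand interval [frame + 3*k0, frame + 3*(k0+m)) maps to the
    # forward strand by end-anchored reversal
    end <- L - (frame + 3L * k0)
    start <- L - (frame + 3L * (k0 + m))
  }
  data.frame(
    chrom = chrom_name, strand = strand, frame = as.integer(frame),
    start = start, end = end,
    aa_seq = substring(aa, runs[keep], runs[keep] + len[keep] - 1L),
    stringsAsFactors = FALSE
  )
}

#' Build a coordinate-tracked six-frame translation database
#'
#' Resolves ambiguity codes once (so mapping and start-codon extraction
#' see the same sequence), then concatenates [translate_frame()] over
#' every chromosome, both strands, all three frames. The database is
#' fully reproducible from (genome, seed, min_len).
#'
#' @param genome named character vector of chromosome sequences (IUPAC
#'   alphabet; resolved internally).
#' @param seed integer seed for ambiguity resolution.
#' @param min_len minimum segment length in residues (default 5).
#' @return a `TranslationDB` object: list with `segments` (data frame
#'   as in [translate_frame()]), `genome` (the resolved genome),
#'   `genome_digest`, `seed`, `min_len`.
#' @export
build_sixframe_db <- function(genome, seed, min_len = 5L) {
  stopifnot(length(genome) > 0L, !is.null(names(genome)))
  resolved <- resolve_genome(genome, seed)
  segs <- list()
  for (nm in names(resolved)) {
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        segs[[length(segs) + 1L]] <-
          translate_frame(resolved[[nm]], nm, strand, frame, min_len)
      }
    }
  }
  db <- structure(
    list(segments = do.call(rbind, segs), genome = resolved,
         genome_digest = attr(resolved, "digest"), seed = seed,
         min_len = as.integer(min_len), cache = new.env(parent = emptyenv())),
    class = "TranslationDB"
  )
  db
}

#' @export
print.TranslationDB <- function(x, ...) {
  cat("TranslationDB:", nrow(x$segments), "segments over",
      length(unique(x$segments$chrom)), "chromosome(s); min_len =",
      x$min_len, "; seed =", x$seed, "\n")
  invisible(x)
}

#' Export a six-frame database as FASTA
#'
#' Headers follow the dialect
#' `>{chrom}|{strand}|{frame}|{start}|{end}` with 0-based half-open
#' forward-strand coordinates. A JSON sidecar (`<path>.json`) records
#' seed, min_len, genome digest and segment count. Identical inputs
#' produce byte-identical output.
#'
#' @param db a `TranslationDB`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_sixframe_fasta <- function(db, path) {
  stopifnot(inherits(db, "TranslationDB"))
  s <- db$segments
  con <- file(path, "wb")
  writeLines(paste0(">", s$chrom, "|", s$strand, "|", s$frame, "|",
                    s$start, "|", s$end, "\n", s$aa_seq),
             con, sep = "\n")
  close(con)
  jsonlite::write_json(
    list(seed = db$seed, min_len = db$min_len,
         genome_digest = db$genome_digest, n_segments = nrow(s)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a six-frame database FASTA back into a TranslationDB
#'
#' The resolved genome itself is not stored in the FASTA; operations
#' that need it (start codons) require the in-memory object from
#' [build_sixframe_db()].
#'
#' @param path FASTA path written by [write_sixframe_fasta()].
#' @return a `TranslationDB` without the `genome` element.
#' @export
read_sixframe_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 5L))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    list(
      segments = data.frame(
        chrom = unname(vapply(parts, `[`, "", 1)),
        strand = unname(vapply(parts, `[`, "", 2)),
        frame = as.integer(vapply(parts, `[`, "", 3)),
        start = as.integer(vapply(parts, `[`, "", 4)),
        end = as.integer(vapply(parts, `[`, "", 5)),
        aa_seq = unname(as.character(ss)), stringsAsFactors = FALSE,
        row.names = NULL
      ),
      genome = NULL,
      genome_digest = meta$genome_digest %||% NA_character_,
      seed = meta$seed %||% NA_integer_,
      min_len = meta$min_len %||% NA_integer_,
      cache = new.env(parent = emptyenv())
    ),
    class = "TranslationDB"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
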