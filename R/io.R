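#' Read a genome from a FASTA file
#'
#' Records are returned in file order with sequence case-folded to
#' uppercase. Sequences may contain IUPAC ambiguity codes; these are
#' resolved deterministically at database-build time (see
#' [resolve_ambiguity()]).
#'
#' @param path path to a FASTA file.
#' @return a named character vector of uppercase chromosome sequences
#'   (a "genome"), names in file order.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicate FASTA record name(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  if (any(nchar(seqs) == 0L)) stop("zero-length FASTA record in '", path, "'")
  bad <- grepl(paste0("[^", paste(names(IUPAC_MAP), collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ", paste(nm[bad], collapse = ", "))
  }
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features,
#' groups them by transcript via `Parent` attributes, converts the
#' 1-based inclusive GFF3 coordinates to the package-internal 0-based
#' half-open forward-strand convention, and derives introns as the gaps
#' between consecutive exons. Unknown feature types are skipped with a
#' warning.
#'
#' @param path path to a GFF3 file.
#' @return a `GeneModels` object: a list with data frames `genes`
#'   (gene_id, chrom, strand, start, end), `transcripts`
#'   (transcript_id, gene_id, chrom, strand, start, end) and `features`
#'   (transcript_id, type in exon/cds/utr5/utr3/intron, chrom, strand,
#'   start, end, phase), plus `seqnames`, the annotation universe.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  known <- c("gene", "mRNA", "transcript", "exon", "CDS",
             "five_prime_UTR", "three_prime_UTR")
  unknown <- setdiff(unique(as.character(gr$type)), known)
  if (length(unknown)) {
    warning("ignoring unknown GFF3 feature type(s): ",
            paste(unknown, collapse = ", "))
  }
  gr <- gr[as.character(gr$type) %in% known]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,     # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
    stringsAsFactors = FALSE
  )
  df$parent <- vapply(
    if (!is.null(gr$Parent)) gr$Parent else replicate(nrow(df), character(0)),
    function(p) if (length(p)) p[1] else NA_character_, character(1)
  )

  genes <- df[df$type == "gene", c("id", "chrom", "strand", "start", "end")]
  names(genes)[1] <- "gene_id"
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  transcripts <- data.frame(
    transcript_id = tx$id, gene_id = tx$parent, chrom = tx$chrom,
    strand = tx$strand, start = tx$start, end = tx$end,
    stringsAsFactors = FALSE
  )

  child <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  if (nrow(child)) {
    if (any(child$type == "CDS" & is.na(child$phase))) {
      stop("CDS feature lacking phase in '", path, "'")
    }
    # containment check against the parent gene span (via the transcript)
    tx_gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    g_start <- stats::setNames(genes$start, genes$gene_id)
    g_end <- stats::setNames(genes$end, genes$gene_id)
    gid <- tx_gene[child$parent]
    viol <- !is.na(gid) &
      (child$start < g_start[gid] | child$end > g_end[gid])
    if (any(viol)) {
      stop("feature(s) not contained in parent gene span: ",
           paste(utils::head(child$parent[viol], 5), collapse = ", "))
    }
  }
  type_map <- c(exon = "exon", CDS = "cds",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  features <- data.frame(
    transcript_id = child$parent, type = unname(type_map[child$type]),
    chrom = child$chrom, strand = child$strand,
    start = child$start, end = child$end,
    phase = ifelse(child$type == "CDS", child$phase, NA_integer_),
    stringsAsFactors = FALSE
  )

  # derive introns as gaps between consecutive exons of each transcript
  introns <- do.call(rbind, lapply(split(
    features[features$type == "exon", ], features$transcript_id[features$type == "exon"]
  ), function(ex) {
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(
      transcript_id = ex$transcript_id[1], type = "intron",
      chrom = ex$chrom[1], strand = ex$strand[1],
      start = ex$end[-nrow(ex)], end = ex$start[-1],
      phase = NA_integer_, stringsAsFactors = FALSE
    )
  }))
  if (!is.null(introns)) features <- rbind(features, introns)
  rownames(features) <- NULL

  universe <- union(GenomeInfoDb_seqlevels(gr), unique(df$chrom))
  gene_models(genes, transcripts, features, universe)
}

# seqlevels() without importing GenomeInfoDb explicitly (re-exported by
# GenomicRanges' dependency chain)
GenomeInfoDb_seqlevels <- function(gr) {
  as.character(methods::slot(methods::slot(gr, "seqinfo"), "seqnames"))
}

#' Construct a GeneModels object
#'
#' @param genes,transcripts,features data frames as documented in
#'   [read_gff3()].
#' @param seqnames chromosome names forming the annotation universe.
#' @return a `GeneModels` object.
#' @export
gene_models <- function(genes, transcripts, features, seqnames) {
  ex <- features[features$type == "exon", ]
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      stop("overlapping exons in transcript ", tid)
    }
  }
  structure(
    list(genes = genes, transcripts = transcripts, features = features,
         seqnames = unique(seqnames)),
    class = "GeneModels"
  )
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(x$seqnames), "sequence(s)\n")
  invisible(x)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()]: converts internal 0-based half-open
#' coordinates back to the 1-based inclusive GFF3 convention. Derived
#' introns are not written (they are re-derived on read).
#'
#' @param models a `GeneModels` object.
#' @param path output path.
#' @param chrom_lengths optional named vector of chromosome lengths,
#'   recorded as `##sequence-region` directives.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path, chrom_lengths = NULL) {
  fmt <- function(chrom, src, type, start, end, strand, phase, attrs) {
    paste(chrom, src, type, start + 1L, end, ".", strand,
          ifelse(is.na(phase), ".", phase), attrs, sep = "\t")
  }
  lines <- "##gff-version 3"
  if (!is.null(chrom_lengths)) {
    lines <- c(lines, paste("##sequence-region", names(chrom_lengths), 1,
                            as.integer(chrom_lengths)))
  }
  g <- models$genes
  tx <- models$transcripts
  fe <- models$features[models$features$type != "intron", ]
  rev_map <- c(exon = "exon", cds = "CDS", utr5 = "five_prime_UTR",
               utr3 = "three_prime_UTR")
  lines <- c(
    lines,
    fmt(g$chrom, "sixpep", "gene", g$start, g$end, g$strand, NA,
        paste0("ID=", g$gene_id)),
    fmt(tx$chrom, "sixpep", "mRNA", tx$start, tx$end, tx$strand, NA,
        paste0("ID=", tx$transcript_id, ";Parent=", tx$gene_id)),
    fmt(fe$chrom, "sixpep", rev_map[fe$type], fe$start, fe$end, fe$strand,
        fe$phase, paste0("Parent=", fe$transcript_id))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write peptide loci as BED6
#'
#' One line per locus: chrom, 0-based start, end, peptide sequence as
#' the name, score column 0, strand; sorted by (chrom, start).
#'
#' @param loci data frame with columns `chrom`, `start`, `end`,
#'   `peptide`, `strand`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(loci, path) {
  if (nrow(loci) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", "peptide", "strand") %in% names(loci)))
  loci <- loci[order(loci$chrom, loci$start), ]
  writeLines(paste(loci$chrom, loci$start, loci$end, loci$peptide, 0L,
                   loci$strand, sep = "\t"), path)
  invisible(path)
}

#' Read a BED6 file of peptide loci
#'
#' @param path path to a BED file written by [write_bed()].
#' @return a data frame with columns `chrom`, `start`, `end`,
#'   `peptide`, `strand`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peptide = as.character(gr$name),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read a peptide identification table
#'
#' Tab-separated export of a spectral search: one row per peptide
#' observation with tissue, sample, abundance, search score and FDR.
#' Rows at or above the FDR threshold are retained in the returned
#' table but flagged `pass_fdr = FALSE` and excluded from downstream
#' analysis by default (the filter is a strict `<`, so a row at exactly
#' the threshold is excluded).
#'
#' @param path path to a TSV with header columns `peptide`, `tissue`,
#'   `sample`, `abundance`, `score`, `fdr`.
#' @param fdr_threshold strict upper FDR bound, default 0.05.
#' @return a data frame with the input columns plus logical `pass_fdr`.
#' @export
read_id_table <- function(path, fdr_threshold = 0.05) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide", "tissue", "sample", "abundance", "score", "fdr")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("identification table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.numeric(tab$abundance)) stop("non-numeric abundance column")
  if (!is.numeric(tab$fdr)) stop("non-numeric fdr column")
  if (any(tab$abundance < 0)) stop("negative abundance value(s)")
  if (any(tab$fdr < 0 | tab$fdr > 1)) stop("fdr value(s) outside [0,1]")
  tab$peptide <- toupper(tab$peptide)
  check_peptides(tab$peptide)
  tab$pass_fdr <- tab$fdr < fdr_threshold
  tab
}
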