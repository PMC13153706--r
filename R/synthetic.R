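# Sense (non-stop) codons of the standard genetic code
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# Strand-aware conceptual translation of a genomic interval
translate_locus <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC fraction, with a fraction
#' `ambiguity_rate` of positions replaced by `N`. Fully determined by
#' the seed.
#'
#' @param seed integer seed.
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths in nt (each at least 10 kb).
#' @param gc GC fraction in (0,1).
#' @param ambiguity_rate fraction of `N` positions, in `[0, 0.05]`.
#' @return named character vector (chr1, chr2, ...).
#' @export
generate_genome <- function(seed, n_chrom = 2L, lengths = rep(1e7, n_chrom),
                            gc = 0.42, ambiguity_rate = 0.001) {
  if (length(lengths) != n_chrom) stop("lengths must have n_chrom entries")
  if (any(lengths < 1e4)) stop("chromosome lengths must be at least 10 kb")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0,1)")
  if (ambiguity_rate < 0 || ambiguity_rate > 0.05) {
    stop("ambiguity_rate must lie in [0, 0.05]")
  }
  set.seed(stage_seed(seed, "generate_genome"))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- vapply(seq_len(n_chrom), function(i) {
    chars <- sample(names(probs), lengths[i], replace = TRUE, prob = probs)
    if (ambiguity_rate > 0) {
      amb <- stats::runif(lengths[i]) < ambiguity_rate
      chars[amb] <- "N"
    }
    paste(chars, collapse = "")
  }, character(1))
  names(genome) <- paste0("chr", seq_len(n_chrom))
  genome
}

# Layout of one gene in transcription order; returns feature intervals
# relative to the gene start plus the coding sequence to write in.
build_gene <- function(gene_len_budget = NULL) {
  n_exons <- sample(1:4, 1)
  utr5_len <- sample(100:250, 1)
  utr3_len <- sample(100:250, 1)
  cds_lens <- sample(150:450, n_exons, replace = TRUE)
  total_cds <- sum(cds_lens)
  rem <- total_cds %% 3L
  if (rem) cds_lens[n_exons] <- cds_lens[n_exons] + (3L - rem)
  intron_lens <- if (n_exons > 1) sample(300:1500, n_exons - 1, replace = TRUE)
                 else integer(0)
  codons <- c("ATG", sample(sense_codons(), sum(cds_lens) %/% 3L - 1L,
                            replace = TRUE))
  list(n_exons = n_exons, utr5_len = utr5_len, utr3_len = utr3_len,
       cds_lens = cds_lens, intron_lens = intron_lens,
       coding_seq = paste(codons, collapse = ""))
}

#' Plant gene models in a genome
#'
#' Writes `n_genes` non-overlapping genes (1-4 exons each, CDS with
#' valid phases, UTRs of 100-250 nt, introns of 300-1500 nt) into the
#' genome, overwriting the CDS bases with a stop-free in-frame coding
#' sequence starting at ATG. Genes are separated by at least 5 kb of
#' intergenic space.
#'
#' @param genome named character vector.
#' @param seed integer seed.
#' @param n_genes number of genes to plant.
#' @return a list with `genome` (edited) and `models` (a `GeneModels`
#'   object, introns included).
#' @export
plant_gene_models <- function(genome, seed, n_genes = 50L) {
  set.seed(stage_seed(seed, "plant_gene_models"))
  chroms <- names(genome)
  lens <- nchar(genome)
  genes_l <- list()
  tx_l <- list()
  fe_l <- list()
  if (n_genes > 0) {
    assign_chrom <- sample(rep(chroms, length.out = n_genes))
    cursor <- stats::setNames(rep(5000, length(chroms)), chroms)
    for (i in seq_len(n_genes)) {
      nm <- assign_chrom[i]
      g <- build_gene()
      strand <- sample(c("+", "-"), 1)
      exon_t <- numeric(g$n_exons)                  # transcription order
      exon_t[1] <- g$utr5_len + g$cds_lens[1]
      if (g$n_exons > 1) {
        exon_t[2:g$n_exons] <- g$cds_lens[2:g$n_exons]
      }
      exon_t[g$n_exons] <- exon_t[g$n_exons] + g$utr3_len
      gene_len <- sum(exon_t) + sum(g$intron_lens)
      g0 <- cursor[nm] + sample(0:20000, 1)
      if (g0 + gene_len > lens[nm] - 5000) {
        stop("insufficient space on ", nm, " to plant gene ", i)
      }
      cursor[nm] <- g0 + gene_len + 5000

      # genomic-order block lengths: reverse transcription order on '-'
      ord <- if (strand == "+") seq_len(g$n_exons) else rev(seq_len(g$n_exons))
      iord <- if (strand == "+") seq_along(g$intron_lens) else
        rev(seq_along(g$intron_lens))
      pos <- g0
      exon_iv <- matrix(0, g$n_exons, 2)   # genomic intervals, tx order
      intron_iv <- if (g$n_exons > 1) matrix(0, g$n_exons - 1, 2) else NULL
      for (j in seq_len(g$n_exons)) {
        tx_j <- ord[j]
        exon_iv[tx_j, ] <- c(pos, pos + exon_t[tx_j])
        pos <- pos + exon_t[tx_j]
        if (j < g$n_exons) {
          tx_i <- iord[j]
          intron_iv[tx_i, ] <- c(pos, pos + g$intron_lens[tx_i])
          pos <- pos + g$intron_lens[tx_i]
        }
      }
      # CDS/UTR sub-intervals of each exon (genomic coordinates)
      cds_iv <- matrix(0, g$n_exons, 2)
      utr5_iv <- utr3_iv <- NULL
      for (tx_j in seq_len(g$n_exons)) {
        a <- exon_iv[tx_j, 1]
        b <- exon_iv[tx_j, 2]
        u5 <- if (tx_j == 1) g$utr5_len else 0
        u3 <- if (tx_j == g$n_exons) g$utr3_len else 0
        if (strand == "+") {
          cds_iv[tx_j, ] <- c(a + u5, b - u3)
          if (u5) utr5_iv <- c(a, a + u5)
          if (u3) utr3_iv <- c(b - u3, b)
        } else {
          # transcription runs right-to-left: UTR5 at the genomic right
          cds_iv[tx_j, ] <- c(a + u3, b - u5)
          if (u5) utr5_iv <- c(b - u5, b)
          if (u3) utr3_iv <- c(a, a + u3)
        }
      }
      # write the coding sequence into the genome, piece by piece
      off <- 0L
      for (tx_j in seq_len(g$n_exons)) {
        piece_len <- g$cds_lens[tx_j]
        piece <- substr(g$coding_seq, off + 1L, off + piece_len)
        off <- off + piece_len
        written <- if (strand == "+") piece else revcomp(piece)
        substr(genome[[nm]], cds_iv[tx_j, 1] + 1L, cds_iv[tx_j, 2]) <- written
      }
      phases <- (3L - (cumsum(c(0L, g$cds_lens[-g$n_exons])) %% 3L)) %% 3L

      gid <- paste0("gene", i)
      tid <- paste0(gid, ".t1")
      genes_l[[i]] <- data.frame(gene_id = gid, chrom = nm, strand = strand,
                                 start = g0, end = g0 + gene_len,
                                 stringsAsFactors = FALSE)
      tx_l[[i]] <- data.frame(transcript_id = tid, gene_id = gid, chrom = nm,
                              strand = strand, start = g0, end = g0 + gene_len,
                              stringsAsFactors = FALSE)
      fe <- data.frame(
        transcript_id = tid,
        type = "exon", chrom = nm, strand = strand,
        start = exon_iv[order(exon_iv[, 1]), 1],
        end = exon_iv[order(exon_iv[, 1]), 2],
        phase = NA_integer_, stringsAsFactors = FALSE
      )
      fe <- rbind(fe, data.frame(
        transcript_id = tid, type = "cds", chrom = nm, strand = strand,
        start = cds_iv[, 1], end = cds_iv[, 2], phase = phases,
        stringsAsFactors = FALSE
      ))
      if (!is.null(utr5_iv)) {
        fe <- rbind(fe, data.frame(
          transcript_id = tid, type = "utr5", chrom = nm, strand = strand,
          start = utr5_iv[1], end = utr5_iv[2], phase = NA_integer_,
          stringsAsFactors = FALSE
        ))
      }
      if (!is.null(utr3_iv)) {
        fe <- rbind(fe, data.frame(
          transcript_id = tid, type = "utr3", chrom = nm, strand = strand,
          start = utr3_iv[1], end = utr3_iv[2], phase = NA_integer_,
          stringsAsFactors = FALSE
        ))
      }
      if (!is.null(intron_iv)) {
        fe <- rbind(fe, data.frame(
          transcript_id = tid, type = "intron", chrom = nm, strand = strand,
          start = intron_iv[, 1], end = intron_iv[, 2], phase = NA_integer_,
          stringsAsFactors = FALSE
        ))
      }
      fe_l[[i]] <- fe
    }
  }
  empty_genes <- data.frame(gene_id = character(0), chrom = character(0),
                            strand = character(0), start = numeric(0),
                            end = numeric(0), stringsAsFactors = FALSE)
  empty_tx <- data.frame(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         start = numeric(0), end = numeric(0),
                         stringsAsFactors = FALSE)
  empty_fe <- data.frame(transcript_id = character(0), type = character(0),
                         chrom = character(0), strand = character(0),
                         start = numeric(0), end = numeric(0),
                         phase = integer(0), stringsAsFactors = FALSE)
  models <- gene_models(
    if (length(genes_l)) do.call(rbind, genes_l) else empty_genes,
    if (length(tx_l)) do.call(rbind, tx_l) else empty_tx,
    if (length(fe_l)) do.call(rbind, fe_l) else empty_fe,
    seqnames = chroms
  )
  list(genome = genome, models = models)
}

# Default planted category mix: an 8% CP fraction, the remainder spread
# over the NCP categories at realistic endogenous-peptidome proportions
default_category_mix <- function() {
  ncp <- c(INTERGENIC = 0.61, INTRON = 0.38, UTR3 = 0.006, UTR5 = 0.002,
           OUT_OF_FRAME_EXON = 0.002)
  c(CP = 0.08, 0.92 * ncp / sum(ncp))
}

# Count occurrences of a peptide across the whole database
db_occurrences <- function(peptide, db) {
  subj <- db_subject(db, il_equiv = FALSE)
  Biostrings::countPattern(Biostrings::AAString(peptide), subj$aa)
}

# One locus candidate for a target category, or NULL if the draw failed
sample_category_locus <- function(category, genome, models, pools, m) {
  span <- 3L * m
  pick_interval <- function(pool) {
    ok <- pool[(pool$end - pool$start) >= span, , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
    ok[sample(nrow(ok), 1), ]
  }
  if (category %in% c("INTERGENIC", "INTRON", "UTR5", "UTR3")) {
    iv <- pick_interval(pools[[category]])
    if (is.null(iv)) return(NULL)
    start <- iv$start + sample(0:(iv$end - iv$start - span), 1)
    strand <- sample(c("+", "-"), 1)
    return(list(chrom = iv$chrom, start = start, end = start + span,
                strand = strand))
  }
  cds <- pick_interval(pools$CDS)
  if (is.null(cds)) return(NULL)
  if (category == "CP") {
    # in-frame start positions within the piece
    if (cds$strand == "+") {
      first <- cds$start + cds$phase
      slots <- (cds$end - span - first) %/% 3L
      if (slots < 0) return(NULL)
      start <- first + 3L * sample(0:slots, 1)
    } else {
      last <- cds$end - cds$phase
      slots <- (last - span - cds$start) %/% 3L
      if (slots < 0) return(NULL)
      start <- last - span - 3L * sample(0:slots, 1)
    }
    return(list(chrom = cds$chrom, start = start, end = start + span,
                strand = cds$strand))
  }
  if (category == "OUT_OF_FRAME_EXON") {
    antisense <- sample(c(TRUE, FALSE), 1)
    if (antisense) {
      start <- cds$start + sample(0:(cds$end - cds$start - span), 1)
      strand <- if (cds$strand == "+") "-" else "+"
    } else {
      shift <- sample(1:2, 1)
      start <- cds$start + cds$phase + shift +
        3L * sample(0:max(0, (cds$end - cds$start - span - 3L) %/% 3L), 1)
      if (start + span > cds$end) return(NULL)
      strand <- cds$strand
    }
    return(list(chrom = cds$chrom, start = start, end = start + span,
                strand = strand))
  }
  stop("unknown category ", category)
}

#' Plant a peptidome with known truth labels
#'
#' Draws peptides directly off the (ambiguity-resolved) genome at loci
#' satisfying their target category -- intergenic peptides from
#' intergenic six-frame runs, CPs as in-frame CDS substrings, and so
#' on -- verifying by rejection sampling that each peptide maps to a
#' single unique locus in the six-frame database and classifies to its
#' target category. Optionally plants a cluster of `hotspot$n`
#' intergenic peptides inside one sliding window to create a density
#' hotspot.
#'
#' @param genome named character vector (as passed to
#'   [build_sixframe_db()]).
#' @param models a `GeneModels` object from [plant_gene_models()].
#' @param seed integer seed.
#' @param n_peptides number of peptides to plant.
#' @param category_mix named probabilities over the six categories,
#'   summing to 1; default: 8% CP, remainder over NCP categories
#'   dominated by intergenic and intronic loci.
#' @param length_range peptide length bounds in residues, within
#'   `[6, 30]`.
#' @param db optional prebuilt `TranslationDB` for this genome (built
#'   internally otherwise, with this seed).
#' @param hotspot optional list `(chrom, window, n)`: plant `n` extra
#'   intergenic peptides whose starts fall in sliding window number
#'   `window` (1-based) of `chrom`.
#' @param config a [dist_config()] (window geometry for `hotspot`).
#' @param tissues tissue labels used when emitting the identification
#'   table.
#' @param max_attempts rejection-sampling cap per peptide.
#' @return a list with `id_table` (peptide, tissue, sample, abundance,
#'   score, fdr), `truth` (peptide, chrom, start, end, strand,
#'   category, in_hotspot), and `db` (the database used).
#' @export
plant_peptidome <- function(genome, models, seed, n_peptides = 2000L,
                            category_mix = default_category_mix(),
                            length_range = c(6L, 30L), db = NULL,
                            hotspot = NULL, config = dist_config(),
                            tissues = TISSUES_DEFAULT,
                            max_attempts = 1000L) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8,
            all(names(category_mix) %in% LOCUS_CATEGORIES),
            length_range[1] >= 6L, length_range[2] <= 30L)
  if (is.null(db)) db <- build_sixframe_db(genome, seed = seed)
  resolved <- db$genome
  fe <- models$features
  pools <- list(
    INTRON = fe[fe$type == "intron", c("chrom", "start", "end", "strand")],
    UTR5 = fe[fe$type == "utr5", c("chrom", "start", "end", "strand")],
    UTR3 = fe[fe$type == "utr3", c("chrom", "start", "end", "strand")],
    CDS = fe[fe$type == "cds",
             c("chrom", "start", "end", "strand", "phase")]
  )
  # intergenic pool: complement of gene spans, 100-nt margin
  pools$INTERGENIC <- do.call(rbind, lapply(names(resolved), function(nm) {
    L <- nchar(resolved[[nm]])
    g <- models$genes[models$genes$chrom == nm, , drop = FALSE]
    if (nrow(g) == 0L) {
      return(data.frame(chrom = nm, start = 0, end = L, strand = "+"))
    }
    g <- g[order(g$start), ]
    starts <- c(0, g$end + 100)
    ends <- c(g$start - 100, L)
    keep <- ends - starts > 200
    data.frame(chrom = nm, start = starts[keep], end = ends[keep],
               strand = "+", stringsAsFactors = FALSE)
  }))

  # deterministic category counts from the mix (largest remainders)
  raw <- category_mix * n_peptides
  counts <- floor(raw)
  short <- n_peptides - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  targets <- rep(names(counts), counts)

  set.seed(stage_seed(seed, "plant_peptidome"))
  targets <- sample(targets)
  idx <- classifier_index(models)
  seen <- new.env(parent = emptyenv())
  n_hot <- if (is.null(hotspot)) 0L else hotspot$n
  hot_window <- NULL
  if (n_hot > 0L) {
    w <- chrom_windows(nchar(resolved[[hotspot$chrom]]), config)
    hot_window <- w[hotspot$window, ]
  }
  total <- length(targets) + n_hot
  out <- vector("list", total)
  plant_one <- function(category, restrict_window = NULL) {
    for (attempt in seq_len(max_attempts)) {
      m <- sample(length_range[1]:length_range[2], 1)
      cand <- if (is.null(restrict_window)) {
        sample_category_locus(category, resolved, models, pools, m)
      } else {
        span <- 3L * m
        start <- restrict_window$window_start +
          sample(0:(restrict_window$window_end - restrict_window$window_start -
                      span), 1)
        list(chrom = hotspot$chrom, start = start, end = start + span,
             strand = sample(c("+", "-"), 1))
      }
      if (is.null(cand)) next
      pep <- translate_locus(resolved, cand$chrom, cand$start, cand$end,
                             cand$strand)
      if (grepl("*", pep, fixed = TRUE)) next
      if (!is.null(seen[[pep]])) next
      cl <- classify_one(data.frame(chrom = cand$chrom, start = cand$start,
                                    end = cand$end, strand = cand$strand,
                                    stringsAsFactors = FALSE), idx)
      if (cl$category != category) next
      if (db_occurrences(pep, db) != 1L) next
      seen[[pep]] <- TRUE
      return(data.frame(peptide = pep, chrom = cand$chrom,
                        start = cand$start, end = cand$end,
                        strand = cand$strand, category = category,
                        stringsAsFactors = FALSE))
    }
    stop("could not plant a peptide of category '", category,
         "' within ", max_attempts, " attempts")
  }
  for (i in seq_along(targets)) {
    out[[i]] <- cbind(plant_one(targets[i]), in_hotspot = FALSE)
  }
  if (n_hot > 0L) {
    for (j in seq_len(n_hot)) {
      out[[length(targets) + j]] <-
        cbind(plant_one("INTERGENIC", restrict_window = hot_window),
              in_hotspot = TRUE)
    }
  }
  truth <- do.call(rbind, out)
  rownames(truth) <- NULL

  # identification table: each peptide observed in 1-3 tissues,
  # 3 replicate samples each, all passing the FDR filter
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ts <- sample(tissues, sample(1:3, 1))
    do.call(rbind, lapply(ts, function(t) {
      data.frame(
        peptide = truth$peptide[i], tissue = t,
        sample = paste0(t, "_", 1:3),
        abundance = stats::rlnorm(3, meanlog = log(1e6), sdlog = 0.5),
        score = round(stats::runif(3, 30, 120), 1),
        fdr = round(stats::runif(3, 0.001, 0.04), 4),
        stringsAsFactors = FALSE
      )
    }))
  })
  id_table <- do.call(rbind, rows)
  rownames(id_table) <- NULL
  id_table$pass_fdr <- id_table$fdr < 0.05
  list(id_table = id_table, truth = truth, db = db)
}

#' Plant a tissue-abundance matrix with known pattern labels
#'
#' SPECIFIC peptides are detected in exactly one tissue; ENHANCED
#' peptides are planted at least `2 * fold` above every other detected
#' tissue; MIXED peptides span several tissues with max/min ratio below
#' `fold / 2`. Replicates get multiplicative log-normal noise at
#' standard deviation `sigma`.
#'
#' @param peptides character vector of peptide sequences.
#' @param seed integer seed.
#' @param class_mix probabilities over SPECIFIC/ENHANCED/MIXED, summing
#'   to 1.
#' @param fold fold threshold the labels are planted against (default
#'   15); values of 2 or below leave no room for MIXED peptides and
#'   raise an error.
#' @param sigma log-normal replicate noise (default 0.2).
#' @param n_replicates replicates per tissue (default 3).
#' @param tissues tissue labels.
#' @return a list with `matrix` (peptide-by-tissue means),
#'   `replicates` (long data frame), `truth` (peptide, class, tissue).
#' @export
plant_tissue_matrix <- function(peptides, seed,
                                class_mix = c(SPECIFIC = 1 / 3,
                                              ENHANCED = 1 / 3,
                                              MIXED = 1 / 3),
                                fold = 15, sigma = 0.2, n_replicates = 3L,
                                tissues = TISSUES_DEFAULT) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("SPECIFIC", "ENHANCED", "MIXED")))
  if (class_mix["MIXED"] > 0 && fold <= 2) {
    stop("fold threshold of ", fold, " leaves no room to plant MIXED ",
         "peptides (max/min must stay below fold/2 with at least two ",
         "detected tissues)")
  }
  peptides <- unique(peptides)
  n <- length(peptides)
  set.seed(stage_seed(seed, "plant_tissue_matrix"))
  raw <- class_mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- sample(rep(names(counts), counts))
  nt <- length(tissues)
  levels <- matrix(0, n, nt, dimnames = list(peptides, tissues))
  truth_tissue <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    base <- 10^stats::runif(1, 4.5, 6.5)
    if (classes[i] == "SPECIFIC") {
      t <- sample(nt, 1)
      levels[i, t] <- base
      truth_tissue[i] <- tissues[t]
    } else if (classes[i] == "ENHANCED") {
      t <- sample(nt, 1)
      others <- sample(setdiff(seq_len(nt), t), sample(1:(nt - 1), 1))
      levels[i, t] <- base
      levels[i, others] <- base / (2 * fold) * stats::runif(length(others),
                                                            0.2, 1)
      truth_tissue[i] <- tissues[t]
    } else {
      k <- sample(2:nt, 1)
      ts <- sample(nt, k)
      # ratios bounded well inside fold/2
      levels[i, ts] <- base * exp(stats::runif(k, 0, log(fold / 2 * 0.6)))
    }
  }
  reps <- do.call(rbind, lapply(seq_len(n), function(i) {
    det <- which(levels[i, ] > 0)
    do.call(rbind, lapply(det, function(t) {
      data.frame(
        peptide = peptides[i], tissue = tissues[t],
        sample = paste0(tissues[t], "_", seq_len(n_replicates)),
        abundance = levels[i, t] * exp(stats::rnorm(n_replicates, 0, sigma)),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(reps) <- NULL
  mat <- abundance_matrix(reps, tissues = tissues)
  mat <- mat[peptides, , drop = FALSE]
  list(matrix = mat, replicates = reps,
       truth = data.frame(peptide = peptides, class = classes,
                          tissue = truth_tissue, stringsAsFactors = FALSE))
}
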