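test_that("genome generation is deterministic with valid composition", {
  g1 <- generate_genome(3, n_chrom = 2, lengths = c(1e4, 2e4))
  g2 <- generate_genome(3, n_chrom = 2, lengths = c(1e4, 2e4))
  expect_identical(g1, g2)
  expect_equal(nchar(g1), c(chr1 = 1e4, chr2 = 2e4))
  expect_error(generate_genome(1, lengths = c(5e3, 1e4)), "10 kb")
  expect_error(generate_genome(1, gc = 1.2), "gc")
  expect_error(generate_genome(1, ambiguity_rate = 0.2), "ambiguity_rate")
})

test_that("GC content matches the binomial expectation", {
  g <- generate_genome(7, n_chrom = 1, lengths = 1e5, gc = 0.5,
                       ambiguity_rate = 0)
  chars <- strsplit(g[[1]], "")[[1]]
  gc_obs <- sum(chars %in% c("G", "C"))
  # within 3 sd of Binomial(1e5, 0.5)
  expect_lt(abs(gc_obs - 5e4), 3 * sqrt(1e5 * 0.25))
  expect_false(any(chars == "N"))
  g_amb <- generate_genome(7, n_chrom = 1, lengths = 1e5,
                           ambiguity_rate = 0.01)
  expect_gt(sum(strsplit(g_amb[[1]], "")[[1]] == "N"), 0)
})

test_that("planted gene models are structurally valid and stop-free", {
  g <- generate_genome(5, n_chrom = 2, lengths = rep(1e5, 2))
  pl <- plant_gene_models(g, 5, n_genes = 8)
  m <- pl$models
  expect_equal(nrow(m$genes), 8L)
  for (tid in m$transcripts$transcript_id) {
    cds <- m$features[m$features$transcript_id == tid &
                        m$features$type == "cds", ]
    cds <- cds[order(cds$start), ]
    spliced <- paste(vapply(seq_len(nrow(cds)), function(j) {
      substr(pl$genome[[cds$chrom[j]]], cds$start[j] + 1L, cds$end[j])
    }, character(1)), collapse = "")
    if (cds$strand[1] == "-") spliced <- oracle_revcomp(spliced)
    aa <- oracle_translate(spliced)
    expect_match(aa, "^M")                       # starts at ATG
    expect_false(grepl("*", aa, fixed = TRUE))   # no internal stops
    # phases consistent with cumulative CDS length in translation order
    ord <- if (cds$strand[1] == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    cum <- cumsum(c(0, (cds$end - cds$start)[ord]))
    expect_equal(cds$phase[ord], (3 - cum[-length(cum)] %% 3) %% 3)
  }
  # genes are separated and non-overlapping
  for (nm in unique(m$genes$chrom)) {
    gg <- m$genes[m$genes$chrom == nm, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] - gg$end[-nrow(gg)] >= 5000))
  }
})

test_that("planted models survive a GFF3 round-trip", {
  g <- generate_genome(9, n_chrom = 1, lengths = 1e5)
  pl <- plant_gene_models(g, 9, n_genes = 4)
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(pl$models, tf, chrom_lengths = c(chr1 = 1e5))
  back <- read_gff3(tf)
  reorder <- function(df) {
    df <- df[order(df$transcript_id, df$type, df$start), ]
    rownames(df) <- NULL
    df[, c("transcript_id", "type", "start", "end", "phase")]
  }
  expect_equal(reorder(back$features), reorder(pl$models$features))
})

test_that("n_genes = 0 leaves the genome untouched", {
  g <- generate_genome(2, n_chrom = 1, lengths = 1e4)
  pl <- plant_gene_models(g, 2, n_genes = 0)
  expect_identical(pl$genome, g)
  expect_equal(nrow(pl$models$genes), 0L)
})

test_that("planted peptides are translatable at their loci and unique in the DB", {
  g <- generate_genome(13, n_chrom = 2, lengths = rep(2e5, 2))
  pl <- plant_gene_models(g, 13, n_genes = 6)
  db <- build_sixframe_db(pl$genome, seed = 13)
  pep <- plant_peptidome(pl$genome, pl$models, 13, n_peptides = 60, db = db)
  tr <- pep$truth
  expect_equal(nrow(tr), 60L)
  for (i in seq_len(nrow(tr))) {
    nt <- substr(db$genome[[tr$chrom[i]]], tr$start[i] + 1L, tr$end[i])
    if (tr$strand[i] == "-") nt <- oracle_revcomp(nt)
    expect_identical(oracle_translate(nt), tr$peptide[i])
  }
  hits <- locate_peptides(tr$peptide, db)
  expect_equal(nrow(hits), 60L)   # multiplicity 1 each
  # same seed -> identical plant
  pep2 <- plant_peptidome(pl$genome, pl$models, 13, n_peptides = 60, db = db)
  expect_identical(pep$truth, pep2$truth)
  # the mix with only CP plants only CPs
  cp_only <- plant_peptidome(pl$genome, pl$models, 13, n_peptides = 10,
                             category_mix = c(CP = 1), db = db)
  expect_true(all(cp_only$truth$category == "CP"))
})

test_that("an impossible category errors with its name", {
  g <- generate_genome(4, n_chrom = 1, lengths = 5e4)
  pl <- plant_gene_models(g, 4, n_genes = 0)   # no introns anywhere
  db <- build_sixframe_db(pl$genome, seed = 4)
  expect_error(
    plant_peptidome(pl$genome, pl$models, 4, n_peptides = 5,
                    category_mix = c(INTRON = 1), db = db,
                    max_attempts = 50),
    "INTRON")
})
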