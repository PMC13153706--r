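test_that("ambiguity resolution is the identity on ACGT and deterministic", {
  expect_identical(resolve_ambiguity("ACGT", 5), "ACGT")
  r1 <- resolve_ambiguity("ANA", 5)
  expect_match(r1, "^A[ACGT]A$")
  expect_identical(resolve_ambiguity("ANA", 5), r1)
  expect_false(identical(resolve_ambiguity(strrep("N", 50), 1),
                         resolve_ambiguity(strrep("N", 50), 2)))
  expect_error(resolve_ambiguity("AXA", 1), "IUPAC")
})

test_that("R positions resolve to A or G only, both occurring uniformly", {
  res <- resolve_ambiguity(strrep("R", 10000), seed = 11)
  tab <- table(strsplit(res, "")[[1]])
  expect_setequal(names(tab), c("A", "G"))
  # binomial(10000, 1/2): both counts within 4 sd of 5000
  expect_true(all(abs(tab - 5000) < 4 * sqrt(10000 * 0.25)))
})

test_that("frame translation matches hand-derived segments on the toy genome", {
  s <- toy_genome[["chr1"]]
  f0 <- translate_frame(s, "chr1", "+", 0, min_len = 1)
  expect_equal(f0$aa_seq, c("MA", "G"))
  expect_equal(f0$start, c(0, 9))
  expect_equal(f0$end, c(6, 12))

  f1 <- translate_frame(s, "chr1", "+", 1, min_len = 1)
  expect_equal(f1$aa_seq, "WPK")
  expect_equal(c(f1$start, f1$end), c(1, 10))

  r0 <- translate_frame(s, "chr1", "-", 0, min_len = 1)
  expect_equal(r0$aa_seq, "PLGH")
  expect_equal(c(r0$start, r0$end), c(0, 12))

  r1 <- translate_frame(s, "chr1", "-", 1, min_len = 1)
  expect_equal(r1$aa_seq, c("P", "A"))
  expect_equal(r1$start, c(8, 2))
  expect_equal(r1$end, c(11, 5))
})

test_that("the toy database has the expected eight segments", {
  db <- build_sixframe_db(toy_genome, seed = 1, min_len = 1)
  expect_equal(nrow(db$segments), 8L)
  expect_setequal(db$segments$aa_seq,
                  c("MA", "G", "WPK", "GLR", "PLGH", "P", "A", "LRP"))
  by_frame <- table(db$segments$strand, db$segments$frame)
  expect_equal(as.integer(by_frame["+", ]), c(2L, 1L, 1L))
  expect_equal(as.integer(by_frame["-", ]), c(1L, 2L, 1L))
})

test_that("min_len filters short segments", {
  db <- build_sixframe_db(toy_genome, seed = 1, min_len = 3)
  expect_setequal(db$segments$aa_seq, c("WPK", "GLR", "PLGH", "LRP"))
})

test_that("a stop-free homopolymer yields one segment per forward frame", {
  g <- c(chr1 = strrep("T", 30))
  db <- build_sixframe_db(g, seed = 1, min_len = 1)
  fwd <- db$segments[db$segments$strand == "+", ]
  expect_equal(nrow(fwd), 3L)
  expect_true(all(grepl("^F+$", fwd$aa_seq)))
  rev <- db$segments[db$segments$strand == "-", ]
  expect_true(all(grepl("^K+$", rev$aa_seq)))   # reverse strand is all A
})

test_that("segment invariants hold and coordinates round-trip on random genomes", {
  for (seed in 1:20) {
    g <- random_genome(seed, len = 1000L)
    db <- build_sixframe_db(g, seed = seed, min_len = 5)
    s <- db$segments
    expect_true(all(s$end - s$start == 3L * nchar(s$aa_seq)))
    expect_true(all(s$start >= 0 & s$end <= nchar(g[[1]])))
    expect_false(any(grepl("*", s$aa_seq, fixed = TRUE)))
    # re-extract, reverse-complement where needed, and re-translate with
    # the independent seqinr oracle
    for (i in seq_len(nrow(s))) {
      nt <- substr(g[[s$chrom[i]]], s$start[i] + 1L, s$end[i])
      if (s$strand[i] == "-") nt <- oracle_revcomp(nt)
      expect_identical(oracle_translate(nt), s$aa_seq[i])
    }
    # every oracle run of >= min_len appears exactly once, per frame
    oracle <- oracle_sixframe_runs(g[[1]], min_len = 5)
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        got <- s$aa_seq[s$strand == strand & s$frame == frame]
        expect_identical(got, oracle[[paste(strand, frame)]])
      }
    }
  }
})

test_that("identical inputs give byte-identical FASTA exports", {
  g <- c(chr1 = paste0(substr(random_genome(3, 600)[[1]], 1, 550),
                       strrep("N", 50)))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_sixframe_fasta(build_sixframe_db(g, seed = 7), f1)
  write_sixframe_fasta(build_sixframe_db(g, seed = 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different ambiguity seed changes the database
  f3 <- withr::local_tempfile(fileext = ".fa")
  write_sixframe_fasta(build_sixframe_db(g, seed = 8), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("six-frame FASTA export round-trips through the header dialect", {
  db <- build_sixframe_db(toy_genome, seed = 1, min_len = 1)
  tf <- withr::local_tempfile(fileext = ".fa")
  write_sixframe_fasta(db, tf)
  expect_true(file.exists(paste0(tf, ".json")))
  back <- read_sixframe_fasta(tf)
  expect_equal(back$segments, db$segments)
  expect_identical(back$genome_digest, db$genome_digest)
  expect_equal(back$min_len, 1L)
})
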