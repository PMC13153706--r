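test_that("linear three-frame translation splits at stop codons", {
  # hand translation: frame 0 ATG GCC TAA -> MA|; frame 1 TGG CCT -> WP;
  # frame 2 GGC CTA -> GL
  expect_setequal(transcript_translations("ATGGCCTAA"), c("MA", "WP", "GL"))
  expect_warning(out <- transcript_translations("AT"), "shorter")
  expect_length(out, 0L)
})

test_that("circular mode exposes junction-spanning runs", {
  circ <- transcript_translations("ATGGA", circular = TRUE)
  lin <- transcript_translations("ATGGA", circular = FALSE)
  expect_true("MEW" %in% circ)     # ATG GAA TGG across the junction
  expect_false("MEW" %in% lin)
  expect_true("M" %in% lin)
})

test_that("multi-lap runs are truncated to one circle when frames repeat", {
  # L = 6 (divisible by 3), stop-free: doubled would give 4 codons of a
  # 2-codon monomer; runs are capped at 2 codons
  circ <- transcript_translations("ATGGCC", circular = TRUE)
  expect_true(all(nchar(circ) <= 2))
  expect_true("MA" %in% circ)
})

test_that("circular translations contain the linear ones as substrings", {
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(9:60, 1), replace = TRUE),
               collapse = "")
    lin <- transcript_translations(s)
    circ <- transcript_translations(s, circular = TRUE)
    for (run in lin) {
      expect_true(any(vapply(circ, grepl, logical(1), pattern = run,
                             fixed = TRUE)),
                  info = paste("monomer run", run, "missing for", s))
    }
  }
})

test_that("support matching is containment in translated runs, per kind", {
  transcripts <- data.frame(
    transcript_id = c("l1", "c1", "r1"),
    kind = c("lncRNA", "circRNA", "riboseq_orf"),
    sequence = c("ATGGCCTAA", "ATGGA", "TTTAAATTT"),
    stringsAsFactors = FALSE
  )
  res <- match_support(c("MA", "MEW", "FKF", "WWWW"), transcripts)
  fl <- res$flags
  expect_true(fl$lncRNA[fl$peptide == "MA"])
  expect_false(fl$circRNA[fl$peptide == "MA"])
  expect_true(fl$circRNA[fl$peptide == "MEW"])   # junction-spanning
  expect_true(fl$riboseq_orf[fl$peptide == "FKF"])
  expect_false(any(unlist(fl[fl$peptide == "WWWW", c("lncRNA", "circRNA",
                                                     "riboseq_orf")])))
  expect_equal(res$union_total, 3L)
  expect_equal(res$union_pct, 75.0)
})

test_that("adding transcripts never removes support", {
  peps <- c("MA", "GL", "KKKK")
  t1 <- data.frame(transcript_id = "l1", kind = "lncRNA",
                   sequence = "ATGGCCTAA", stringsAsFactors = FALSE)
  t2 <- rbind(t1, data.frame(transcript_id = "l2", kind = "lncRNA",
                             sequence = "AAAAAAAAAAAA",
                             stringsAsFactors = FALSE))
  f1 <- match_support(peps, t1)$flags
  f2 <- match_support(peps, t2)$flags
  expect_true(all(f2$lncRNA[f1$lncRNA]))
  expect_true(f2$lncRNA[f2$peptide == "KKKK"])
})

test_that("union accounting counts doubly-supported peptides once", {
  flags <- data.frame(
    peptide = c("A1", "A2", "A3"),
    lncRNA = c(TRUE, TRUE, FALSE),
    circRNA = c(TRUE, FALSE, TRUE),
    riboseq_orf = FALSE, stringsAsFactors = FALSE
  )
  s <- support_summary(flags, n_ncps = 30)
  expect_equal(unname(s$totals[c("lncRNA", "circRNA")]), c(2L, 2L))
  expect_equal(s$union_total, 3L)
  expect_equal(s$union_pct, 10.0)
})

test_that("peptides planted in transcripts are flagged, scrambled decoys are not", {
  set.seed(33)
  base <- paste(sample(sixpep:::sense_codons(), 40, replace = TRUE),
                collapse = "")
  planted <- substr(oracle_translate(base), 5, 14)
  decoy <- paste(rev(strsplit(planted, "")[[1]]), collapse = "")
  transcripts <- data.frame(transcript_id = "l1", kind = "lncRNA",
                            sequence = base, stringsAsFactors = FALSE)
  res <- match_support(c(planted, decoy), transcripts)
  expect_true(res$flags$lncRNA[res$flags$peptide == planted])
  # verify the decoy truly is absent before asserting non-support
  runs <- transcript_translations(base)
  if (!any(grepl(decoy, runs, fixed = TRUE))) {
    expect_false(res$flags$lncRNA[res$flags$peptide == decoy])
  }
})
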