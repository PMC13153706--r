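test_that("locus frame phase follows strand-aware modular arithmetic", {
  plus <- list(start = 130, end = 145, strand = "+")
  expect_equal(locus_frame_phase(plus, 130), 0)
  expect_equal(locus_frame_phase(plus, 131), 1)
  expect_equal(locus_frame_phase(plus, 133), 0)
  minus <- list(start = 0, end = 12, strand = "-")
  expect_equal(locus_frame_phase(minus, 11), 0)   # first base read
  expect_equal(locus_frame_phase(minus, 10), 1)
  expect_error(locus_frame_phase(plus, 146), "outside locus")
})

test_that("classification matches the decision rule on the example gene", {
  m <- example_models()
  cl <- function(start, end, strand) {
    classify_loci(make_locus("chr1", start, end, strand), m)$category
  }
  expect_equal(cl(133, 148, "+"), "CP")                 # in-frame CDS
  expect_equal(cl(134, 149, "+"), "OUT_OF_FRAME_EXON")  # phase shifted
  expect_equal(cl(133, 148, "-"), "OUT_OF_FRAME_EXON")  # antisense to CDS
  expect_equal(cl(220, 235, "+"), "INTRON")
  expect_equal(cl(220, 235, "-"), "INTRON")
  expect_equal(cl(103, 124, "+"), "UTR5")
  expect_equal(cl(352, 367, "+"), "UTR3")
  expect_equal(cl(5000, 5015, "+"), "INTERGENIC")
  # second CDS piece has phase 2: first in-frame position is 302
  expect_equal(cl(302, 311, "+"), "CP")
  expect_equal(cl(303, 312, "+"), "OUT_OF_FRAME_EXON")
})

test_that("boundary-straddling loci take the highest-ranked touched element", {
  m <- example_models()
  cl <- function(start, end, strand) {
    classify_loci(make_locus("chr1", start, end, strand), m)$category
  }
  # straddles CDS/intron boundary: touches CDS -> out-of-frame exon
  expect_equal(cl(190, 214, "+"), "OUT_OF_FRAME_EXON")
  # straddles UTR5/CDS boundary in frame with the CDS: cannot be CP
  # (not contained in CDS), touches CDS -> out-of-frame exon
  expect_equal(cl(124, 139, "+"), "OUT_OF_FRAME_EXON")
  # straddles intron/UTR3 boundary on the second exon? utr3 starts at
  # 340 inside exon2; locus [335,350) touches CDS [300,340)
  expect_equal(cl(335, 350, "+"), "OUT_OF_FRAME_EXON")
  # straddles gene start: touches UTR5 only
  expect_equal(cl(95, 110, "+"), "UTR5")
})

test_that("loci on unannotated chromosomes are rejected", {
  m <- example_models()
  expect_error(classify_loci(make_locus("chrZ", 0, 9, "+"), m),
               "annotation universe")
  # chr9 is in the universe but has no genes: intergenic
  expect_equal(classify_loci(make_locus("chr9", 0, 9, "+"), m)$category,
               "INTERGENIC")
})

test_that("CP calls imply the peptide is a substring of the spliced CDS translation", {
  study <- simulate_study(seed = 23, lengths = rep(2e5, 2), n_genes = 6,
                          n_peptides = 40,
                          config = pipeline_config(seed = 23))
  cps <- study$classified[study$classified$category == "CP", ]
  fe <- study$models$features
  expect_gt(nrow(cps), 0)   # the default mix always plants CPs
  for (i in seq_len(nrow(cps))) {
    tid <- study$models$transcripts$transcript_id[
      study$models$transcripts$gene_id == cps$gene_id[i]]
    cds <- fe[fe$transcript_id == tid & fe$type == "cds", ]
    cds <- cds[order(cds$start), ]
    spliced <- paste(vapply(seq_len(nrow(cds)), function(j) {
      substr(study$genome[[cds$chrom[j]]], cds$start[j] + 1L, cds$end[j])
    }, character(1)), collapse = "")
    if (cds$strand[1] == "-") spliced <- oracle_revcomp(spliced)
    expect_match(oracle_translate(spliced), cps$peptide[i], fixed = TRUE)
  }
})

test_that("partition tallies conserve counts and percentages", {
  classified <- data.frame(
    peptide = paste0("p", 1:10), chrom = "chr1",
    start = 1:10, end = 31:40,
    strand = c("+", "+", "-", "+", "-", "-", "+", "-", "-", "-"),
    category = c("CP", "CP", "CP", rep("INTRON", 4), rep("INTERGENIC", 3)),
    stringsAsFactors = FALSE
  )
  part <- cp_ncp_partition(classified)
  expect_equal(nrow(part$cp) + nrow(part$ncp), 10L)
  expect_equal(part$ncp_pct, 70.00)
  expect_equal(part$cp_pct, 30.00)
  expect_equal(sum(part$category_tally$n), 10L)
  st <- part$strand_tally
  expect_equal(sum(st$n), 10L)
  expect_equal(sum(st$n[st$class == "NCP"]), 7L)
})
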