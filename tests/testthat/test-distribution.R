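test_that("sliding windows follow the 6/3 Mb geometry with truncation", {
  cfg <- dist_config()
  w12 <- sixpep:::chrom_windows(12e6, cfg)
  expect_equal(w12$window_start, c(0, 3e6, 6e6))
  expect_equal(w12$window_end, c(6e6, 9e6, 12e6))
  w9 <- sixpep:::chrom_windows(9e6, cfg)
  expect_equal(w9$window_start, c(0, 3e6))
  expect_equal(w9$window_end, c(6e6, 9e6))
  w5 <- sixpep:::chrom_windows(5e6, cfg)   # short chromosome: truncated
  expect_equal(w5$window_start, 0)
  expect_equal(w5$window_end, 5e6)
})

test_that("window counts use start coordinates with half-open boundaries", {
  loci <- data.frame(chrom = "chr1",
                     start = c(rep(1e6, 11), 3e6), stringsAsFactors = FALSE)
  prof <- window_density(loci, c(chr1 = 12e6))
  expect_equal(prof$count, c(12, 1, 0))
  # a locus at exactly 3,000,000 falls in windows 1 and 2
  one <- window_density(data.frame(chrom = "chr1", start = 3e6),
                        c(chr1 = 12e6))
  expect_equal(one$count, c(1, 1, 0))
  expect_error(window_density(data.frame(chrom = "chr1", start = 13e6),
                              c(chr1 = 12e6)), "beyond")
})

test_that("interior loci are counted in exactly two overlapping windows", {
  set.seed(4)
  loci <- data.frame(chrom = "chr1",
                     start = sample(6e6:(9e6 - 1), 50), # away from both ends
                     stringsAsFactors = FALSE)
  prof <- window_density(loci, c(chr1 = 18e6))
  expect_equal(sum(prof$count), 2L * nrow(loci))
})

test_that("hotspot detection is strictly greater-than and monotone", {
  prof <- data.frame(chrom = "chr1", window_start = c(0, 3e6, 6e6),
                     window_end = c(6e6, 9e6, 12e6), count = c(11, 10, 2))
  hs <- detect_hotspots(prof)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$count, 11)
  expect_equal(nrow(detect_hotspots(prof[0, ])), 0L)
  # adding a locus never shrinks the hotspot set
  prof2 <- prof
  prof2$count <- prof2$count + 1
  expect_true(all(hs$window_start %in% detect_hotspots(prof2)$window_start))
})

test_that("adjacent spacing uses start-to-start nearest-neighbor gaps", {
  loci <- data.frame(chrom = "chr1", start = c(0, 5e4, 2e5))
  res <- adjacent_spacing(loci, cutoff = 1e5)
  expect_equal(res$distances, c(5e4, 5e4, 1.5e5))
  expect_equal(res$fraction_below, 2 / 3)
  # a chromosome's only locus counts in the denominator, never numerator
  res2 <- adjacent_spacing(rbind(loci, data.frame(chrom = "chr2", start = 1)),
                           cutoff = 1e5)
  expect_equal(res2$fraction_below, 2 / 4)
  expect_equal(res2$distances[4], Inf)
  # a regular 10-kb grid is entirely below a 100-kb cutoff
  grid <- data.frame(chrom = "chr1", start = seq(0, 1e6, by = 1e4))
  expect_equal(adjacent_spacing(grid, cutoff = 1e5)$fraction_below, 1)
})

test_that("TSS distances are to the nearest CDS start on the chromosome", {
  m <- example_models()   # CDS starts at 130 on the '+' strand
  res <- tss_distances(make_locus("chr1", 133, 148, "+"), m)
  expect_equal(res$distances, 3)
  # nearest of several TSSs
  m2 <- example_models()
  extra <- m2$features[m2$features$type == "cds", ][1, ]
  extra$start <- 5000
  extra$end <- 5300
  extra$transcript_id <- "g2.t1"
  m2$features <- rbind(m2$features, extra)
  res2 <- tss_distances(make_locus("chr1", 2600, 2615, "+"), m2)
  expect_equal(res2$distances, 2400)
  # chromosome without any CDS: undefined, counted
  res3 <- suppressMessages(
    tss_distances(make_locus("chr9", 100, 130, "+"), m))
  expect_true(is.na(res3$distances))
  expect_equal(res3$n_undefined, 1L)
})

test_that("arm-normalized positions map midpoint to 0 and telomeres to 1", {
  L <- c(chrA = 1e6)
  pos <- function(p) {
    arm_normalized_positions(data.frame(chrom = "chrA", start = p), L)
  }
  expect_equal(pos(5e5), 0)
  expect_equal(pos(0), 1)
  expect_equal(pos(1e6), 1)
  expect_equal(pos(7.5e5), 0.5)
  # reflection invariance
  set.seed(9)
  p <- sample(0:1e6, 25)
  expect_equal(pos(p), pos(1e6 - p))
})

test_that("count-length correlation agrees with the textbook formula", {
  expect_equal(count_length_correlation(c(1, 2, 3), c(10, 20, 30))$r, 1)
  expect_equal(count_length_correlation(c(3, 2, 1), c(10, 20, 30))$r, -1)
  x <- c(2, 1, 4, 3, 6, 5, 8, 7)
  y <- 1:8
  # independent covariance-formula implementation
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- count_length_correlation(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(6 / (1 - r_hand^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_stat), df = 6), tolerance = 1e-12)
  expect_error(count_length_correlation(c(1, 1, 1), y[1:3]), "variance")
})
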