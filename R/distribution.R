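#' Chromosome-distribution configuration
#'
#' Defaults mirror the study design: 6-Mb sliding windows advanced by
#' 3 Mb, a hotspot being a window with strictly more than 10 peptide
#' loci, a 100-kb adjacent-spacing cutoff, and a 700-bp window for
#' TSS-proximity reporting (TSS here meaning the translation initiation
#' site, i.e. the first base of an annotated CDS).
#'
#' @param window_size window length in nt.
#' @param step step between window starts in nt.
#' @param hotspot_threshold strict lower bound on the window count.
#' @param spacing_cutoff adjacent-spacing cutoff in nt.
#' @param tss_window TSS-proximity reporting window in nt.
#' @return a named list.
#' @export
dist_config <- function(window_size = 6e6, step = 3e6, hotspot_threshold = 10,
                        spacing_cutoff = 1e5, tss_window = 700) {
  stopifnot(window_size >= step, step > 0, hotspot_threshold > 0,
            spacing_cutoff > 0, tss_window > 0)
  list(window_size = window_size, step = step,
       hotspot_threshold = hotspot_threshold,
       spacing_cutoff = spacing_cutoff, tss_window = tss_window)
}

# Sliding-window list for one chromosome: starts advance by `step`
# until the previous window has reached the chromosome end; the final
# window is truncated, not discarded.
chrom_windows <- function(L, config) {
  starts <- ends <- numeric(0)
  s <- 0
  repeat {
    e <- min(s + config$window_size, L)
    starts <- c(starts, s)
    ends <- c(ends, e)
    if (e >= L) break
    s <- s + config$step
    if (s >= L) break
  }
  data.frame(window_start = starts, window_end = ends)
}

#' Sliding-window peptide density per chromosome
#'
#' A locus is counted in a window iff its start coordinate lies in
#' `[window_start, window_end)`; overlapping windows count it in each.
#'
#' @param loci data frame with `chrom` and `start`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param config a [dist_config()] list.
#' @param class_label optional label (e.g. "CP"/"NCP") recorded on the
#'   profile.
#' @return a data frame with columns `chrom`, `window_start`,
#'   `window_end`, `count` (and `class` if labelled).
#' @export
window_density <- function(loci, chrom_lengths, config = dist_config(),
                           class_label = NULL) {
  bad <- loci$start >= chrom_lengths[loci$chrom] | loci$start < 0
  if (any(is.na(bad)) || any(bad)) {
    stop("locus start beyond chromosome length (or unknown chromosome)")
  }
  out <- do.call(rbind, lapply(names(chrom_lengths), function(nm) {
    w <- chrom_windows(chrom_lengths[[nm]], config)
    p <- loci$start[loci$chrom == nm]
    w$count <- vapply(seq_len(nrow(w)), function(i) {
      sum(p >= w$window_start[i] & p < w$window_end[i])
    }, integer(1))
    cbind(chrom = nm, w, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(class_label)) out$class <- class_label
  out
}

#' Detect density hotspots
#'
#' A hotspot is a window whose count strictly exceeds the threshold
#' (a count of exactly 10 under the default is not a hotspot). The
#' reported statistic is the number of hotspot windows; a merged-region
#' count (overlapping hotspot windows fused) is attached as attribute
#' `n_merged_regions`.
#'
#' @param profile data frame from [window_density()].
#' @param config a [dist_config()] list.
#' @return the hotspot rows of `profile`.
#' @export
detect_hotspots <- function(profile, config = dist_config()) {
  hs <- profile[profile$count > config$hotspot_threshold, , drop = FALSE]
  rownames(hs) <- NULL
  n_merged <- 0L
  if (nrow(hs)) {
    for (nm in unique(hs$chrom)) {
      h <- hs[hs$chrom == nm, ]
      h <- h[order(h$window_start), ]
      gaps <- h$window_start[-1] > cumulMax(h$window_end)[-nrow(h)]
      n_merged <- n_merged + 1L + sum(gaps)
    }
  }
  attr(hs, "n_merged_regions") <- n_merged
  hs
}

cumulMax <- function(x) cummax(x)

#' Nearest-neighbor spacing between adjacent peptide loci
#'
#' For each locus, the start-to-start distance to the nearest other
#' locus on the same chromosome. A chromosome's sole locus gets an
#' infinite distance, so it enters the reported fraction's denominator
#' but never its numerator.
#'
#' @param loci data frame with `chrom` and `start`.
#' @param cutoff spacing cutoff in nt (default 100 kb).
#' @return a list with `distances` (per input locus, input order) and
#'   `fraction_below` (share of loci closer than `cutoff` to their
#'   nearest neighbor).
#' @export
adjacent_spacing <- function(loci, cutoff = 1e5) {
  n <- nrow(loci)
  d <- rep(Inf, n)
  for (nm in unique(loci$chrom)) {
    idx <- which(loci$chrom == nm)
    if (length(idx) < 2L) next
    ord <- idx[order(loci$start[idx])]
    s <- loci$start[ord]
    gap_prev <- c(Inf, diff(s))
    gap_next <- c(diff(s), Inf)
    d[ord] <- pmin(gap_prev, gap_next)
  }
  list(distances = d, fraction_below = mean(d < cutoff))
}

# Translation initiation sites (first base of each transcript's CDS)
tss_table <- function(models) {
  cds <- models$features[models$features$type == "cds", , drop = FALSE]
  if (nrow(cds) == 0L) {
    return(data.frame(chrom = character(0), tss = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(cds, cds$transcript_id), function(cc) {
    if (cc$strand[1] == "+") {
      data.frame(chrom = cc$chrom[1], tss = min(cc$start))
    } else {
      data.frame(chrom = cc$chrom[1], tss = max(cc$end) - 1)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Distances from peptide loci to the nearest translation initiation site
#'
#' "TSS" follows the study's usage: the translation initiation site,
#' the first base of an annotated CDS (not the transcription start).
#' Distance is the absolute difference between the locus start and the
#' nearest TSS on the same chromosome; loci on chromosomes without any
#' annotated CDS get `NA` and are excluded from the summary share.
#'
#' @param loci data frame with `chrom` and `start`.
#' @param models a `GeneModels` object.
#' @param config a [dist_config()] list (uses `tss_window`).
#' @return a list with `distances` (per locus), `share_within`
#'   (fraction of defined distances within `tss_window`) and
#'   `n_undefined`.
#' @export
tss_distances <- function(loci, models, config = dist_config()) {
  tss <- tss_table(models)
  d <- rep(NA_real_, nrow(loci))
  for (nm in unique(loci$chrom)) {
    t_nm <- tss$tss[tss$chrom == nm]
    idx <- which(loci$chrom == nm)
    if (length(t_nm) == 0L) next
    d[idx] <- vapply(loci$start[idx],
                     function(p) min(abs(p - t_nm)), numeric(1))
  }
  n_undef <- sum(is.na(d))
  if (n_undef) {
    message(n_undef, " locus/loci on chromosome(s) without any TSS; ",
            "distance undefined")
  }
  list(distances = d,
       share_within = if (all(is.na(d))) NA_real_ else
         mean(d[!is.na(d)] <= config$tss_window),
       n_undefined = n_undef)
}

#' Arm-normalized chromosomal positions
#'
#' Maps each locus start to `|p - L/2| / (L/2)`: 0 at the chromosome
#' midpoint, 1 at either telomere. Invariant under reflection of the
#' chromosome.
#'
#' @param loci data frame with `chrom` and `start`.
#' @param chrom_lengths named numeric vector.
#' @return numeric vector in `[0, 1]`, one value per locus.
#' @export
arm_normalized_positions <- function(loci, chrom_lengths) {
  L <- chrom_lengths[loci$chrom]
  unname(abs(loci$start - L / 2) / (L / 2))
}

#' Correlation between per-chromosome peptide counts and chromosome length
#'
#' Pearson product-moment correlation with the standard t-based
#' two-sided p-value.
#'
#' @param counts per-chromosome peptide counts.
#' @param lengths matching chromosome lengths.
#' @return a list with `r` and `p`.
#' @export
count_length_correlation <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), length(counts) >= 3L)
  if (stats::sd(counts) == 0 || stats::sd(lengths) == 0) {
    stop("zero variance in counts or lengths")
  }
  ct <- stats::cor.test(counts, lengths, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
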