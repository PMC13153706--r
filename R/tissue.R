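TISSUES_DEFAULT <- c("liver", "lung", "spleen", "muscle", "intestine",
                     "testis")

#' Build a peptide-by-tissue mean-abundance matrix from replicates
#'
#' A peptide is "detected" in a tissue if any replicate reports a
#' nonzero abundance; the tissue mean is the arithmetic mean of the
#' detected (nonzero) replicate intensities. Peptides detected in no
#' tissue are dropped with a warning.
#'
#' @param id_table data frame with `peptide`, `tissue`, `abundance`
#'   (one row per replicate observation); rows failing FDR should be
#'   filtered out beforehand.
#' @param tissues tissue universe (column order); defaults to the
#'   tissues present.
#' @return a numeric matrix, peptides as rows, tissues as columns;
#'   zero means "not detected".
#' @export
abundance_matrix <- function(id_table, tissues = NULL) {
  stopifnot(all(c("peptide", "tissue", "abundance") %in% names(id_table)))
  if (is.null(tissues)) tissues <- sort(unique(id_table$tissue))
  peptides <- unique(id_table$peptide)
  mat <- matrix(0, nrow = length(peptides), ncol = length(tissues),
                dimnames = list(peptides, tissues))
  det <- id_table[id_table$abundance > 0, ]
  if (nrow(det)) {
    agg <- stats::aggregate(abundance ~ peptide + tissue, det, mean)
    mat[cbind(agg$peptide, agg$tissue)] <- agg$abundance
  }
  empty <- rowSums(mat > 0) == 0L
  if (any(empty)) {
    warning(sum(empty), " peptide(s) detected in no tissue; excluded")
    mat <- mat[!empty, , drop = FALSE]
  }
  mat
}

#' Classify tissue-expression patterns
#'
#' A peptide detected in exactly one tissue is tissue-SPECIFIC. A
#' peptide detected in several tissues is tissue-ENHANCED if its top
#' tissue mean is at least `fold_threshold` times the comparison level
#' of the other detected tissues (their maximum by default, their mean
#' under `other = "mean"`); the boundary is inclusive, so exactly
#' 15-fold qualifies. Everything else is MIXED.
#'
#' @param matrix peptide-by-tissue mean-abundance matrix (zero =
#'   not detected), as from [abundance_matrix()].
#' @param fold_threshold fold-change threshold, default 15.
#' @param other how to summarize the other detected tissues: `"max"`
#'   (strictest, default) or `"mean"`.
#' @return a data frame with `peptide`, `class` (SPECIFIC / ENHANCED /
#'   MIXED) and `tissue` (the defining tissue; `NA` for MIXED).
#' @export
classify_tissue_pattern <- function(matrix, fold_threshold = 15,
                                    other = c("max", "mean")) {
  other <- match.arg(other)
  stopifnot(is.matrix(matrix), all(matrix >= 0), fold_threshold > 0)
  res <- lapply(seq_len(nrow(matrix)), function(i) {
    v <- matrix[i, ]
    det <- which(v > 0)
    if (length(det) == 0L) {
      stop("peptide '", rownames(matrix)[i], "' detected in no tissue")
    }
    if (length(det) == 1L) {
      return(list(class = "SPECIFIC", tissue = colnames(matrix)[det]))
    }
    top <- which.max(v)
    rest <- v[setdiff(det, top)]
    cmp <- if (other == "max") max(rest) else mean(rest)
    if (v[top] >= fold_threshold * cmp) {
      list(class = "ENHANCED", tissue = colnames(matrix)[top])
    } else {
      list(class = "MIXED", tissue = NA_character_)
    }
  })
  data.frame(
    peptide = rownames(matrix),
    class = vapply(res, `[[`, "", "class"),
    tissue = vapply(res, `[[`, NA_character_, "tissue"),
    stringsAsFactors = FALSE
  )
}

#' Tissue-overlap analysis of a detection mask
#'
#' Pairwise counts of peptides detected in both members of each tissue
#' pair (per-tissue totals on the diagonal), plus counts of peptides
#' detected in every member of each queried tissue subset.
#'
#' @param mask logical (or 0/1) peptide-by-tissue detection matrix.
#' @param subsets optional list of character vectors of tissue names.
#' @return a list with `pairwise` (symmetric integer matrix) and
#'   `subsets` (named integer vector, one per queried subset).
#' @export
overlap_analysis <- function(mask, subsets = NULL) {
  mask <- (mask > 0) * 1L
  pairwise <- crossprod(mask)
  sub_counts <- NULL
  if (!is.null(subsets)) {
    sub_counts <- vapply(subsets, function(ts) {
      unknown <- setdiff(ts, colnames(mask))
      if (length(unknown)) {
        stop("unknown tissue(s) in query: ", paste(unknown, collapse = ", "))
      }
      sum(rowSums(mask[, ts, drop = FALSE]) == length(ts))
    }, integer(1))
    names(sub_counts) <- vapply(subsets, paste, "", collapse = "+")
  }
  list(pairwise = pairwise, subsets = sub_counts)
}
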