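#' Pipeline configuration
#'
#' Collects every stage parameter in one serializable list. Defaults
#' are the study's printed thresholds: FDR < 0.05, 6-Mb windows with
#' 3-Mb steps, hotspot count > 10, 100-kb spacing cutoff, 700-bp TSS
#' window, 15-fold tissue-enhancement threshold.
#'
#' @param seed master seed; each stage derives its own seed from it via
#'   [stage_seed()].
#' @param min_len six-frame segment minimum length (residues).
#' @param min_pep_len minimum peptide length for mapping.
#' @param fdr_threshold strict FDR bound.
#' @param il_equiv Ile/Leu equivalence in mapping.
#' @param fold tissue-enhancement fold threshold.
#' @param ... overrides passed to [dist_config()].
#' @return a named list.
#' @export
pipeline_config <- function(seed = 1L, min_len = 5L, min_pep_len = 6L,
                            fdr_threshold = 0.05, il_equiv = FALSE,
                            fold = 15, ...) {
  c(list(seed = seed, min_len = min_len, min_pep_len = min_pep_len,
         fdr_threshold = fdr_threshold, il_equiv = il_equiv, fold = fold),
    dist_config(...))
}

#' Run the full peptidogenomic pipeline
#'
#' build-db, map, classify, chromosome statistics, physicochemical
#' properties, tissue patterns and (optionally) ncRNA/Ribo-seq support,
#' in order, with per-stage record accounting. Rerunning with the same
#' config and inputs reproduces the report exactly.
#'
#' @param genome named character vector of chromosome sequences.
#' @param models a `GeneModels` object.
#' @param id_table identification table (see [read_id_table()]).
#' @param abundance optional replicate-level abundance data frame
#'   (`peptide`, `tissue`, `abundance`).
#' @param transcripts optional transcript set for [match_support()].
#' @param config a [pipeline_config()] list.
#' @return a list with `report` (summary statistics), `classified`
#'   (per-peptide table), `profiles`, `hotspots`, `tissue_classes`,
#'   `support`, `stage_log`.
#' @export
run_pipeline <- function(genome, models, id_table, abundance = NULL,
                         transcripts = NULL, config = pipeline_config()) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, records_in = n_in, records_out = n_out,
      records_discarded = n_in - n_out, stringsAsFactors = FALSE
    )
  }

  db <- build_sixframe_db(genome, seed = config$seed,
                          min_len = config$min_len)
  if ("fdr" %in% names(id_table)) {
    id_table$pass_fdr <- id_table$fdr < config$fdr_threshold
  }
  mapping <- map_peptides(id_table, db, min_pep_len = config$min_pep_len,
                          il_equiv = config$il_equiv)
  note("map", mapping$stats$n_peptides, nrow(mapping$kept))
  loci <- mapping$kept
  attr(loci, "genome_digest") <- db$genome_digest

  classified <- classify_loci(loci, models)
  note("classify", nrow(loci), nrow(classified))
  part <- cp_ncp_partition(classified)

  chrom_lengths <- stats::setNames(nchar(db$genome), names(db$genome))
  cfg <- dist_config(window_size = config$window_size, step = config$step,
                     hotspot_threshold = config$hotspot_threshold,
                     spacing_cutoff = config$spacing_cutoff,
                     tss_window = config$tss_window)
  prof_cp <- window_density(part$cp, chrom_lengths, cfg, class_label = "CP")
  prof_ncp <- window_density(part$ncp, chrom_lengths, cfg, class_label = "NCP")
  hot_cp <- detect_hotspots(prof_cp, cfg)
  hot_ncp <- detect_hotspots(prof_ncp, cfg)
  spacing_ncp <- if (nrow(part$ncp) >= 2) {
    adjacent_spacing(part$ncp, cfg$spacing_cutoff)
  } else list(fraction_below = NA_real_)
  spacing_cp <- if (nrow(part$cp) >= 2) {
    adjacent_spacing(part$cp, cfg$spacing_cutoff)
  } else list(fraction_below = NA_real_)

  props <- peptide_properties(classified, genome = db$genome)
  note("properties", nrow(classified), nrow(props))

  tissue_classes <- NULL
  if (!is.null(abundance)) {
    ab <- abundance[abundance$peptide %in% classified$peptide, , drop = FALSE]
    mat <- abundance_matrix(ab)
    tissue_classes <- classify_tissue_pattern(mat, fold_threshold = config$fold)
    note("tissue", length(unique(abundance$peptide)), nrow(tissue_classes))
  }

  support <- NULL
  if (!is.null(transcripts) && nrow(part$ncp) > 0) {
    support <- match_support(part$ncp$peptide, transcripts)
    note("support", nrow(part$ncp), sum(support$flags$any_support))
  }

  aug <- if (nrow(props)) mean(props$is_aug) else NA_real_
  report <- list(
    n_input_peptides = mapping$stats$n_peptides,
    n_mapped_unique = nrow(classified),
    n_cp = nrow(part$cp), n_ncp = nrow(part$ncp),
    cp_pct = part$cp_pct, ncp_pct = part$ncp_pct,
    category_tally = part$category_tally,
    strand_tally = part$strand_tally,
    n_hotspots_cp = nrow(hot_cp), n_hotspots_ncp = nrow(hot_ncp),
    spacing_fraction_ncp = spacing_ncp$fraction_below,
    spacing_fraction_cp = spacing_cp$fraction_below,
    aug_fraction = round(aug, 4),
    non_aug_fraction = round(1 - aug, 4),
    tissue_class_counts = if (!is.null(tissue_classes)) {
      table(tissue_classes$class)
    } else NULL,
    support_totals = if (!is.null(support)) support$totals else NULL,
    support_union = if (!is.null(support)) support$union_total else NULL,
    support_union_pct = if (!is.null(support)) support$union_pct else NULL,
    config = config
  )
  list(report = report, classified = props, mapping = mapping,
       profiles = rbind(prof_cp, prof_ncp),
       hotspots = rbind(hot_cp, hot_ncp),
       tissue_classes = tissue_classes, support = support,
       stage_log = do.call(rbind, log), db = db)
}

#' Generate and analyze a complete synthetic study
#'
#' Convenience wrapper: genome, gene models, planted peptidome and
#' tissue matrix from one master seed, then [run_pipeline()] over the
#' result. The whole study is byte-reproducible from the seed.
#'
#' @param seed master seed.
#' @param n_chrom,lengths,n_genes,n_peptides scale of the synthetic
#'   study (defaults: 2 chromosomes of 10 Mb, 50 genes, 2,000
#'   peptides).
#' @param hotspot optional hotspot specification (see
#'   [plant_peptidome()]).
#' @param config a [pipeline_config()]; its seed is overridden by
#'   `seed`.
#' @return as [run_pipeline()], plus `truth` (planted labels),
#'   `tissue_truth`, `genome`, `models`.
#' @export
simulate_study <- function(seed = 17L, n_chrom = 2L,
                           lengths = rep(1e7, n_chrom), n_genes = 50L,
                           n_peptides = 2000L, hotspot = NULL,
                           config = pipeline_config()) {
  config$seed <- seed
  genome <- generate_genome(seed, n_chrom = n_chrom, lengths = lengths)
  planted <- plant_gene_models(genome, seed, n_genes = n_genes)
  db <- build_sixframe_db(planted$genome, seed = seed,
                          min_len = config$min_len)
  pep <- plant_peptidome(planted$genome, planted$models, seed,
                         n_peptides = n_peptides, db = db, hotspot = hotspot)
  tis <- plant_tissue_matrix(unique(pep$truth$peptide), seed)
  res <- run_pipeline(planted$genome, planted$models, pep$id_table,
                      abundance = tis$replicates, config = config)
  res$truth <- pep$truth
  res$tissue_truth <- tis$truth
  res$genome <- planted$genome
  res$models <- planted$models
  res
}
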