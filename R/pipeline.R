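#' Run the full SLR-discovery pipeline
#'
#' Chains the stages on a cohort: MAF/missingness filtering, the
#' windowed F_ST / coverage-ratio / SNP-density tracks, candidate-SLR
#' calling, locus classification inside each candidate, panel building
#' and per-individual sex-linkage scores, the cross-region
#' co-occurrence test (when two or more candidate regions exist),
#' male-specific and hemizygous region extraction, and male-class
#' assignment. All outputs (tracks, regions, scores, summary JSON) are
#' written under `outdir`.
#'
#' Inputs may be given as file paths (VCF, depth TSV, sample-sheet
#' TSV) or as in-memory objects from [simulate_cohort()] /
#' [read_genotypes()].
#'
#' @param vcf path to a VCF or a [genotype_matrix()].
#' @param depth path to a depth TSV or a [depth_table()].
#' @param samples path to a sample-sheet TSV or a [sample_sheet()].
#' @param outdir output directory.
#' @param filter_cfg,scan_cfg,class_cfg,cooc_cfg,marker_cfg stage
#'   configurations ([filter_config()], [window_scan_config()],
#'   [locus_class_config()], [cooccurrence_config()],
#'   [marker_config()]).
#' @param seed seed for the (seeded) subsampling steps.
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(vcf, depth, samples, outdir,
                         filter_cfg = filter_config(),
                         scan_cfg = window_scan_config(),
                         class_cfg = locus_class_config("relaxed"),
                         cooc_cfg = cooccurrence_config(),
                         marker_cfg = marker_config(),
                         seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gm <- stage("input", {
    if (inherits(vcf, "genotype_matrix")) vcf else read_genotypes(vcf)
  })
  dt <- stage("input", {
    if (inherits(depth, "depth_table")) depth else read_depth(depth)
  })
  sheet <- stage("input", {
    if (inherits(samples, "sample_sheet")) samples
    else read_sample_sheet(samples)
  })
  check_samples_match(gm$samples, sheet, exact = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  gmf <- stage("filter", filter_maf_missing(gm, filter_cfg))
  track <- stage("tracks", build_window_track(gmf, dt, sheet, scan_cfg))
  cls <- stage("classify", classify_loci(gmf, sheet, class_cfg))
  track$n_sex_snps <- sex_snp_window_counts(cls, dt$windows)
  write_tracks(track, file.path(outdir, "tracks.tsv"))

  slr <- stage("call_slr", call_slr(track, scan_cfg))
  write_regions(slr, file.path(outdir, "slr_candidates.bed"))

  panels <- list()
  score_tabs <- list()
  for (i in seq_len(nrow(slr))) {
    reg <- slr[i, ]
    pan <- stage("panel", suppressWarnings(
      build_panel(gmf, sheet, reg, class_cfg)))
    if (!length(pan$loci)) next
    key <- paste0(reg$chrom, ":", reg$start, "-", reg$end)
    panels[[key]] <- pan
    score_tabs[[key]] <- stage("scores", sample_scores(gmf, pan))
  }
  if (length(score_tabs)) {
    all_scores <- do.call(rbind, Map(function(k, s)
      cbind(panel = k, s), names(score_tabs), score_tabs))
    write.table(all_scores, file.path(outdir, "scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cooc <- NULL
  if (length(score_tabs) >= 2) {
    # the two largest panels carry the main cross-chromosome signal
    sizes <- vapply(panels, function(p) length(p$loci), numeric(1))
    top2 <- names(sort(sizes, decreasing = TRUE))[1:2]
    cooc <- stage("cooccurrence",
                  cooccurrence(score_tabs[[top2[1]]],
                               score_tabs[[top2[2]]], cooc_cfg))
  }

  msr <- stage("marker", male_specific_regions(dt, sheet, marker_cfg))
  hemi <- stage("marker", hemizygous_regions(track, marker_cfg))
  write_regions(rbind(msr, hemi), file.path(outdir, "markers.bed"))

  classes <- NULL
  if (length(score_tabs)) {
    main <- names(sort(vapply(panels, function(p) length(p$loci),
                              numeric(1)), decreasing = TRUE))[1]
    classes <- stage("male_classes",
                     assign_male_classes(sheet,
                                         scores = score_tabs[[main]],
                                         thr = cooc_cfg$thr_a))
  }

  summary <- list(
    n_loci_in = nrow(gm$loci),
    n_loci_filtered = nrow(gmf$loci),
    slr_candidates = slr,
    panel_sizes = lapply(panels, function(p) length(p$loci)),
    cooccurrence = if (!is.null(cooc))
      list(table = as.vector(cooc$table), fisher_p = cooc$fisher_p,
           spearman_rho = cooc$spearman_rho,
           spearman_p = cooc$spearman_p,
           n_discordant = cooc$n_discordant),
    male_specific_regions = msr,
    hemizygous_regions = hemi,
    male_classes = as.list(classes %||% character(0)),
    provenance = list(seed = seed,
                      package_version =
                        as.character(utils::packageVersion("slrscan")),
                      config = list(filter = unclass(filter_cfg),
                                    scan = unclass(scan_cfg),
                                    class = unclass(class_cfg),
                                    cooccurrence = unclass(cooc_cfg),
                                    marker = unclass(marker_cfg))))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(summary)
}
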