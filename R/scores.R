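#' Build an XY-like locus panel from a defining contrast
#'
#' Runs the locus classifier restricted to a genomic region using only
#' a defining subset of samples (typically all females versus the
#' strongly male-associated M2 males) and keeps the loci whose label is
#' not `none`. The panel is fixed once built: scoring other samples on
#' it never changes its membership, and every defining female is by
#' construction fixed homozygous at every panel locus.
#'
#' @param gm a [genotype_matrix()].
#' @param sexes a [sample_sheet()].
#' @param region list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param cfg a [locus_class_config()] (mode relaxed or strict).
#' @param defining_samples sample ids of the defining cohort; default
#'   all females plus all M2 males.
#' @return list of class `locus_panel`: `loci` (character ids),
#'   `region`, `mode`, `defining_samples`.
#' @export
build_panel <- function(gm, sexes, region,
                        cfg = locus_class_config("relaxed"),
                        defining_samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(defining_samples)) {
    defining_samples <- sexes$sample_id[
      sexes$sex == "F" |
        (!is.na(sexes$male_class) & sexes$male_class == "M2")]
  }
  sub_sheet <- sexes[sexes$sample_id %in% defining_samples, ,
                     drop = FALSE]
  class(sub_sheet) <- class(sexes)
  reg_gm <- genotypes_in_region(gm, region$chrom, region$start,
                                region$end)
  if (!nrow(reg_gm$loci)) {
    warning("no variants in panel region ", region$chrom, ":",
            region$start, "-", region$end)
    return(structure(list(loci = character(0), region = region,
                          mode = cfg$mode,
                          defining_samples = defining_samples),
                     class = "locus_panel"))
  }
  def_gm <- subset_genotypes(reg_gm,
                             samples = intersect(reg_gm$samples,
                                                 defining_samples))
  cls <- classify_loci(def_gm, sub_sheet, cfg)
  keep <- cls$label != "none"
  if (!any(keep)) warning("panel is empty after classification")
  structure(list(loci = locus_ids(def_gm$loci)[keep], region = region,
                 mode = cfg$mode, defining_samples = defining_samples),
            class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("locus_panel: %d loci on %s:%s-%s (mode %s, %d defining samples)\n",
              length(x$loci), x$region$chrom,
              format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE), x$mode,
              length(x$defining_samples)))
  invisible(x)
}

#' Per-individual sex-linkage score on a locus panel
#'
#' The score of a sample is the proportion of heterozygous genotypes
#' among its called genotypes across the panel loci. Samples with no
#' called panel locus get an undefined (NA) score.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [build_panel()] result (or character locus ids).
#' @param samples sample ids to score; default all samples of `gm`.
#' @return data.frame: sample_id, n_called, n_het, score.
#' @export
sample_scores <- function(gm, panel, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- if (inherits(panel, "locus_panel")) panel$loci else panel
  samples <- samples %||% gm$samples
  if (!length(loci)) {
    return(data.frame(sample_id = samples, n_called = 0L, n_het = 0L,
                      score = NA_real_))
  }
  sub <- subset_genotypes(gm, loci = loci, samples = samples)
  n_called <- colSums(!is.na(sub$codes))
  n_het <- colSums(sub$codes == GT_HET, na.rm = TRUE)
  data.frame(sample_id = samples, n_called = as.integer(n_called),
             n_het = as.integer(n_het),
             score = ifelse(n_called > 0, n_het / n_called, NA_real_))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities,
#' over all tables with the observed margins, of tables no more
#' probable than the observed one (with a relative tolerance for
#' floating-point ties). An all-zero table gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (sum(table) == 0) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks); the two-sided p-value comes from t = rho * sqrt((n - 2) /
#' (1 - rho^2)) on n - 2 degrees of freedom, with p = 0 at rho = +/-1.
#'
#' @param x,y equal-length numeric vectors, n >= 3 after pairwise
#'   removal of missing values.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_rank needs at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) return(list(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Co-occurrence configuration
#'
#' @param thr_a,thr_b dichotomization thresholds for the two score
#'   sets; a score >= its threshold is "high".
#' @return list of class `cooccurrence_config`.
#' @export
cooccurrence_config <- function(thr_a = 0.6, thr_b = 0.3) {
  stopifnot(thr_a >= 0, thr_a <= 1, thr_b >= 0, thr_b <= 1)
  structure(list(thr_a = thr_a, thr_b = thr_b),
            class = "cooccurrence_config")
}

#' Cross-chromosome co-occurrence of sex-linkage signals
#'
#' Dichotomizes each individual's scores on two panels (high when
#' score >= threshold), tabulates the 2x2 high/low table, and tests
#' association with the two-sided Fisher exact test on the table and
#' Spearman correlation on the raw scores. Individuals with an
#' undefined score on either panel are excluded pairwise.
#'
#' @param scores_a,scores_b data.frames from [sample_scores()] over the
#'   same samples.
#' @param cfg a [cooccurrence_config()].
#' @return list: `table` (2x2 counts, rows = panel a high/low, columns
#'   = panel b high/low), `fisher_p`, `spearman_rho`, `spearman_p`,
#'   `n_discordant`, `n_excluded`.
#' @export
cooccurrence <- function(scores_a, scores_b,
                         cfg = cooccurrence_config()) {
  m <- merge(scores_a[, c("sample_id", "score")],
             scores_b[, c("sample_id", "score")],
             by = "sample_id", suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(scores_a) || nrow(m) != nrow(scores_b))
    stop("score sets cover different samples")
  ok <- !is.na(m$score_a) & !is.na(m$score_b)
  n_excluded <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  high_a <- m$score_a >= cfg$thr_a
  high_b <- m$score_b >= cfg$thr_b
  tab <- matrix(c(sum(high_a & high_b), sum(high_a & !high_b),
                  sum(!high_a & high_b), sum(!high_a & !high_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("high", "low"),
                                b = c("high", "low")))
  sp <- spearman_rank(m$score_a, m$score_b)
  list(table = tab, fisher_p = fisher_exact_2x2(tab),
       spearman_rho = sp$rho, spearman_p = sp$p,
       n_discordant = tab["high", "low"] + tab["low", "high"],
       n_excluded = n_excluded)
}
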