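#' Variant-filter configuration
#'
#' @param min_maf minimum minor-allele frequency over called genotypes;
#'   loci strictly below are dropped (the boundary is kept).
#' @param max_missing_frac maximum tolerated missing-call fraction;
#'   loci strictly above are dropped.
#' @param ld_prune_window,ld_prune_step sliding window and step, in SNP
#'   counts, for greedy LD pruning.
#' @param ld_prune_r2 dosage-r2 threshold above which one SNP of a pair
#'   is pruned.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_maf = 0.05, max_missing_frac = 0.25,
                          ld_prune_window = 50, ld_prune_step = 10,
                          ld_prune_r2 = 0.2) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_missing_frac >= 0, max_missing_frac <= 1,
            ld_prune_window >= 2, ld_prune_step >= 1,
            ld_prune_r2 >= 0, ld_prune_r2 <= 1)
  structure(list(min_maf = min_maf, max_missing_frac = max_missing_frac,
                 ld_prune_window = ld_prune_window,
                 ld_prune_step = ld_prune_step,
                 ld_prune_r2 = ld_prune_r2),
            class = "filter_config")
}

#' Filter loci on minor-allele frequency and missingness
#'
#' MAF is computed by allele counting over called genotypes. A locus is
#' dropped when MAF < `min_maf` or when its missing-call fraction
#' exceeds `max_missing_frac`; both boundaries are retained, matching
#' the convention of the usual VCF filtering tools.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return Filtered `genotype_matrix`; attribute `filter_report` gives
#'   counts dropped per rule.
#' @export
filter_maf_missing <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- ncol(gm$codes)
  n_called <- rowSums(!is.na(gm$codes))
  alt <- rowSums(gm$codes, na.rm = TRUE)
  af <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  miss_frac <- 1 - n_called / n
  drop_miss <- miss_frac > cfg$max_missing_frac
  drop_maf <- !drop_miss & (n_called == 0 | maf < cfg$min_maf)
  keep <- !(drop_miss | drop_maf)
  if (!any(keep))
    warning("all loci removed by MAF/missingness filter")
  out <- subset_genotypes(gm, loci = keep)
  attr(out, "filter_report") <- list(n_in = nrow(gm$loci),
                                     n_dropped_missing = sum(drop_miss),
                                     n_dropped_maf = sum(drop_maf),
                                     n_out = sum(keep))
  out
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `ld_prune_window` consecutive surviving SNPs,
#' pairs with dosage r2 above `ld_prune_r2` are resolved by removing
#' one member: the locus with more missing calls, or the later
#' position on a tie. The window advances by `ld_prune_step` SNPs and
#' never spans chromosomes. Sweeps repeat until no further locus is
#' removed, so the filter is a fixed point (idempotent): no window of
#' consecutive surviving SNPs retains a pair above the threshold.
#'
#' @param gm a [genotype_matrix()] with loci sorted by position.
#' @param cfg a [filter_config()].
#' @return Pruned `genotype_matrix`; attribute `n_pruned` counts the
#'   removed loci.
#' @export
ld_prune <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  nl <- nrow(gm$loci)
  keep <- rep(TRUE, nl)
  n_miss <- rowSums(is.na(gm$codes))
  prune_window <- function(win) {
    # pairwise dosage r2 for the window in one shot
    r2 <- suppressWarnings(
      cor(t(gm$codes[win, , drop = FALSE]),
          use = "pairwise.complete.obs"))^2
    alive <- rep(TRUE, length(win))
    repeat {
      r2a <- r2
      r2a[!alive, ] <- NA
      r2a[, !alive] <- NA
      r2a[lower.tri(r2a, diag = TRUE)] <- NA
      hit <- which(!is.na(r2a) & r2a > cfg$ld_prune_r2,
                   arr.ind = TRUE)
      if (!nrow(hit)) break
      a <- hit[1, 1]
      b <- hit[1, 2]
      # drop the noisier locus; tie -> later position
      drop <- if (n_miss[win[a]] > n_miss[win[b]]) a else b
      alive[drop] <- FALSE
    }
    win[!alive]
  }
  for (ch in unique(gm$loci$chrom)) {
    idx0 <- which(gm$loci$chrom == ch)
    repeat {
      removed_any <- FALSE
      idx <- idx0[keep[idx0]]
      start <- 1L
      while (length(idx) > 1) {
        win <- idx[seq(start, min(start + cfg$ld_prune_window - 1L,
                                  length(idx)))]
        dropped <- prune_window(win)
        if (length(dropped)) {
          keep[dropped] <- FALSE
          idx <- idx0[keep[idx0]]
          removed_any <- TRUE
        }
        if (start + cfg$ld_prune_window - 1L >= length(idx)) break
        start <- start + cfg$ld_prune_step
      }
      if (!removed_any) break
    }
  }
  out <- subset_genotypes(gm, loci = keep)
  attr(out, "n_pruned") <- sum(!keep)
  out
}

#' Within-sex genotype-consistency filter and XY-pattern screen
#'
#' Retains loci with no missing call in any sample and complete
#' genotype consistency within each sex (all males share one genotype
#' and all females share one genotype). Among retained loci, the
#' XY-pattern subset comprises those whose shared male genotype is
#' heterozygous while the shared female genotype is homozygous (either
#' 0/0 or 1/1) — the signature of an X/Y-differentiated site.
#'
#' @param gm a [genotype_matrix()].
#' @param sexes a [sample_sheet()] covering the matrix samples.
#' @return list with `retained` and `xy_pattern` character vectors of
#'   locus ids ("chrom:pos"), plus `counts`.
#' @export
consistency_filter <- function(gm, sexes) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_samples_match(gm$samples, sexes)
  grp <- split_sexes(sexes)
  fcodes <- gm$codes[, gm$samples %in% grp$F, drop = FALSE]
  mcodes <- gm$codes[, gm$samples %in% grp$M, drop = FALSE]
  # missingness is judged over the contrast cohort, not bystanders
  no_missing <- rowSums(is.na(fcodes)) + rowSums(is.na(mcodes)) == 0L
  f_rng <- row_code_range(fcodes)
  m_rng <- row_code_range(mcodes)
  retained <- no_missing & f_rng$min == f_rng$max &
    m_rng$min == m_rng$max
  retained[is.na(retained)] <- FALSE
  f_geno <- fcodes[, 1]
  m_geno <- mcodes[, 1]
  xy <- retained & m_geno == GT_HET &
    (f_geno == GT_HOM_REF | f_geno == GT_HOM_ALT)
  xy[is.na(xy)] <- FALSE
  ids <- locus_ids(gm$loci)
  list(retained = ids[retained], xy_pattern = ids[xy],
       counts = c(n_in = nrow(gm$loci), n_retained = sum(retained),
                  n_xy_pattern = sum(xy)))
}
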