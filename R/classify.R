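#' Locus-classification configuration
#'
#' @param mode `"relaxed"` (XY-like: females fixed homozygous, males
#'   enriched for heterozygotes), `"strict"` (all called males
#'   heterozygous, all called females fixed for one homozygote) or
#'   `"zw_strict"` (the same with sexes swapped).
#' @param min_called_per_sex loci with fewer called genotypes in either
#'   sex are left unclassified.
#' @param male_het_enrichment minimum fraction of called males that
#'   must be heterozygous in relaxed mode.
#' @return list of class `locus_class_config`.
#' @export
locus_class_config <- function(mode = c("relaxed", "strict", "zw_strict"),
                               min_called_per_sex = 3,
                               male_het_enrichment = 0.5) {
  stopifnot(min_called_per_sex >= 1,
            male_het_enrichment >= 0, male_het_enrichment <= 1)
  structure(list(mode = match.arg(mode),
                 min_called_per_sex = min_called_per_sex,
                 male_het_enrichment = male_het_enrichment),
            class = "locus_class_config")
}

#' Classify loci by sex-genotype pattern
#'
#' Screens every locus for the XY (or ZW) inheritance signature. A
#' locus is `xy_like` when all called females share one homozygous
#' genotype (all 0/0 or all 1/1 — a criterion invariant to which allele
#' is REF) and the fraction of called males that are heterozygous is at
#' least `male_het_enrichment`; `xy_strict` additionally requires every
#' called male to be heterozygous. `zw_strict` applies the strict rule
#' with the sexes swapped. Loci with fewer than `min_called_per_sex`
#' called genotypes in either sex are labelled `none`.
#'
#' @param gm a [genotype_matrix()].
#' @param sexes a [sample_sheet()]; may cover a subset of the matrix
#'   samples, in which case only those samples define the pattern.
#' @param cfg a [locus_class_config()].
#' @return data.frame: chrom, pos, label, called_f, called_m,
#'   male_het_frac (het fraction of the homogametic-candidate sex for
#'   `zw_strict`).
#' @export
classify_loci <- function(gm, sexes, cfg = locus_class_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- split_sexes(sexes)
  fcodes <- gm$codes[, gm$samples %in% grp$F, drop = FALSE]
  mcodes <- gm$codes[, gm$samples %in% grp$M, drop = FALSE]
  if (cfg$mode == "zw_strict") {
    tmp <- fcodes
    fcodes <- mcodes
    mcodes <- tmp
  }
  called_f <- rowSums(!is.na(fcodes))
  called_m <- rowSums(!is.na(mcodes))
  # homogametic sex fixed for a single homozygote
  f_rng <- row_code_range(fcodes)
  f_fixed_hom <- called_f > 0 & !is.na(f_rng$min) &
    f_rng$min == f_rng$max & f_rng$min != GT_HET
  het_m <- rowSums(mcodes == GT_HET, na.rm = TRUE)
  het_frac <- ifelse(called_m > 0, het_m / called_m, NA_real_)
  enough <- called_f >= cfg$min_called_per_sex &
    called_m >= cfg$min_called_per_sex
  strict <- enough & f_fixed_hom & het_m == called_m
  relaxed <- enough & f_fixed_hom & !is.na(het_frac) &
    het_frac >= cfg$male_het_enrichment
  label <- rep("none", nrow(gm$loci))
  if (cfg$mode == "strict") {
    label[strict] <- "xy_strict"
  } else if (cfg$mode == "zw_strict") {
    label[strict] <- "zw_strict"
  } else {
    label[relaxed] <- "xy_like"
    label[strict] <- "xy_strict"
  }
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos, label = label,
             called_f = as.integer(if (cfg$mode == "zw_strict") called_m
                                   else called_f),
             called_m = as.integer(if (cfg$mode == "zw_strict") called_f
                                   else called_m),
             male_het_frac = het_frac)
}

#' Per-window count of sex-pattern loci
#'
#' @param classes output of [classify_loci()].
#' @param windows window grid data.frame.
#' @return integer vector aligned to `windows`: number of loci with a
#'   label other than `none` in each window.
#' @export
sex_snp_window_counts <- function(classes, windows) {
  widx <- window_of(windows, classes$chrom, classes$pos - 1L)
  n <- rep(0L, nrow(windows))
  ok <- !is.na(widx) & classes$label != "none"
  if (any(ok)) {
    t <- table(widx[ok])
    n[as.integer(names(t))] <- as.integer(t)
  }
  n
}

#' Build an ordered genotype matrix for heat-map visualization
#'
#' Selects the classified loci (subsampling uniformly without
#' replacement down to `n_subsample` when there are more), orders rows
#' by genomic position and columns as the female block followed by the
#' male block (M1 before M2 when male classes are known), and returns
#' the dosage codes ready for plotting with the usual genotype colour
#' convention (0/0, 0/1, 1/1, missing).
#'
#' @param gm a [genotype_matrix()].
#' @param loci character locus ids ("chrom:pos") to display.
#' @param sexes a [sample_sheet()].
#' @param n_subsample maximum number of loci to keep (default 20000).
#' @param seed seed for the subsample.
#' @return list with `codes` (ordered matrix), `loci` (data.frame) and
#'   `sample_order`.
#' @export
heatmap_matrix <- function(gm, loci, sexes, n_subsample = 20000,
                           seed = 1) {
  stopifnot(length(loci) > 0)
  if (length(loci) > n_subsample) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    loci <- sample(loci, n_subsample)
  }
  sub <- subset_genotypes(gm, loci = loci)
  sheet <- sexes[match(sub$samples, sexes$sample_id), , drop = FALSE]
  mc <- ifelse(is.na(sheet$male_class), "zz", sheet$male_class)
  ord <- order(sheet$sex != "F", mc, sheet$sample_id)
  list(codes = sub$codes[, ord, drop = FALSE],
       loci = sub$loci, sample_order = sub$samples[ord])
}
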