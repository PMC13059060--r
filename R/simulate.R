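#' Specification of a planted sex-linked interval
#'
#' @param chrom chromosome name (must exist in the simulated genome).
#' @param start,end 0-based half-open interval in bp.
#' @param kind one of:
#'   * `"XY_DIFFERENTIAL"` — X/Y-differentiated SNPs at density
#'     `snp_rate`: males carrying a divergent Y are heterozygous,
#'     females are fixed homozygous for the X allele;
#'   * `"Y_HEMIZYGOUS"` — Y-specific sequence: read coverage only in
#'     males carrying the divergent Y (M2), none in females;
#'   * `"X_LIKE_BACKGROUND"` — ordinary autosomal-like variation
#'     (useful to embed undifferentiated stretches inside an SLR).
#' @param snp_rate expected SNPs per kb for `XY_DIFFERENTIAL` /
#'   `X_LIKE_BACKGROUND` intervals.
#' @return list of class `slr_spec`.
#' @export
slr_spec <- function(chrom, start, end,
                     kind = c("XY_DIFFERENTIAL", "Y_HEMIZYGOUS",
                              "X_LIKE_BACKGROUND"),
                     snp_rate = 0.3) {
  kind <- match.arg(kind)
  stopifnot(start >= 0, end > start, snp_rate >= 0)
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 snp_rate = snp_rate), class = "slr_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the resequencing cohort the package's scans are
#' designed for: 5 females plus 17 males in two Y-haplotype classes
#' (12 M1 with a mostly X-like, weakly differentiated Y; 5 M2 with a
#' divergent Y), mean per-individual depth 16.1x, 50-kb windows, an
#' XY-differentiated SLR of 2 Mb on one chromosome and, on a second
#' chromosome, a small degenerate XY segment next to a 200-kb
#' Y-hemizygous segment.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_size depth/scan window size in bp.
#' @param n_females,n_m1,n_m2 cohort composition.
#' @param autosomal_snp_rate expected background SNPs per kb; the
#'   default of 13/kb matches the genome-wide SNP density of a typical
#'   deep amphibian resequencing cohort (tens of millions of SNPs on a
#'   multi-Gb assembly), so that 50-kb windows hold enough sites for
#'   windowed F_ST noise to average out.
#' @param allele_freq_alpha,allele_freq_beta Beta parameters for
#'   autosomal alternate-allele frequencies.
#' @param mean_depth mean per-individual sequencing depth (x).
#' @param depth_dispersion gamma overdispersion of per-window depth
#'   (variance of the gamma multiplier; 0 = pure Poisson counting noise).
#' @param slr_specs list of [slr_spec()] intervals to plant.
#' @param m1_y_similarity fraction of XY-differentiated loci at which an
#'   M1 male carries the X-like (female) genotype rather than a
#'   heterozygous X/Y call.
#' @param genotype_error per-call probability of replacing the true
#'   genotype with one of the two other codes.
#' @param missing_rate per-call missing probability.
#' @param hemi_female_noise upper bound (x) of the uniform residual
#'   depth females and M1 males receive inside Y-hemizygous windows;
#'   0 means literally no female reads.
#' @param read_length read length (bp) used to convert window depth to
#'   a Poisson read count and back.
#' @param seed integer seed; every simulated quantity is reproducible
#'   from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr2 = 18e6, chr4 = 18e6,
                                         chr6 = 24e6),
                       window_size = 50000,
                       n_females = 5, n_m1 = 12, n_m2 = 5,
                       autosomal_snp_rate = 13,
                       allele_freq_alpha = 0.8, allele_freq_beta = 0.8,
                       mean_depth = 16.1, depth_dispersion = 0.1,
                       slr_specs = list(
                         slr_spec("chr6", 4e6, 6e6, "XY_DIFFERENTIAL",
                                  snp_rate = 3),
                         slr_spec("chr2", 1e6, 1.1e6, "XY_DIFFERENTIAL",
                                  snp_rate = 0.3),
                         slr_spec("chr2", 2e6, 2.2e6, "Y_HEMIZYGOUS")),
                       m1_y_similarity = 0.95,
                       genotype_error = 0.001, missing_rate = 0.02,
                       hemi_female_noise = 0.25,
                       read_length = 150, seed = 1L) {
  cfg <- list(chrom_lengths = chrom_lengths, window_size = window_size,
              n_females = n_females, n_m1 = n_m1, n_m2 = n_m2,
              autosomal_snp_rate = autosomal_snp_rate,
              allele_freq_alpha = allele_freq_alpha,
              allele_freq_beta = allele_freq_beta,
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              slr_specs = slr_specs,
              m1_y_similarity = m1_y_similarity,
              genotype_error = genotype_error,
              missing_rate = missing_rate,
              hemi_female_noise = hemi_female_noise,
              read_length = read_length, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$m1_y_similarity, cfg$genotype_error, cfg$missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(cfg$mean_depth > 0, cfg$window_size > 0,
            cfg$depth_dispersion >= 0,
            cfg$n_females >= 1, cfg$n_m1 + cfg$n_m2 >= 1,
            !is.null(names(cfg$chrom_lengths)))
  for (s in cfg$slr_specs) {
    len <- unname(cfg$chrom_lengths[s$chrom])
    if (length(len) != 1 || is.na(len))
      stop("SLR spec names unknown chromosome ", s$chrom)
    if (s$end > len)
      stop("SLR interval ", s$chrom, ":", s$start, "-", s$end,
           " extends beyond the chromosome")
  }
  invisible(TRUE)
}

#' Simulate a resequencing cohort with planted sex-linked regions
#'
#' Forward-simulates genotypes and per-window depth with the structure
#' the downstream scans assume, plus ground truth for recovery tests.
#' Autosomal loci follow Hardy-Weinberg proportions at Beta-distributed
#' allele frequencies, identically in both sexes. At XY-differentiated
#' loci females are fixed homozygous for the X allele, M2 males are
#' heterozygous, and M1 males carry the female (X-like) genotype at a
#' fraction `m1_y_similarity` of loci and a heterozygous call
#' otherwise. Depth is gamma-mixed Poisson per window and sample;
#' Y-hemizygous windows give females and M1 males only a uniform
#' residual below `hemi_female_noise` while M2 males keep full depth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `genotypes`
#'   ([genotype_matrix()]), `depth` ([depth_table()]), `samples`
#'   ([sample_sheet()]) and `truth` (planted intervals, per-locus class
#'   labels, per-sample male classes, hemizygous regions).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  ids <- c(sprintf("F%02d", seq_len(config$n_females)),
           sprintf("M1_%02d", seq_len(config$n_m1)),
           sprintf("M2_%02d", seq_len(config$n_m2)))
  sex <- c(rep("F", config$n_females),
           rep("M", config$n_m1 + config$n_m2))
  mclass <- c(rep(NA_character_, config$n_females),
              rep("M1", config$n_m1), rep("M2", config$n_m2))
  sheet <- sample_sheet(ids, sex, population = rep("TP", length(ids)),
                        male_class = mclass)
  is_f <- sex == "F"
  is_m1 <- !is.na(mclass) & mclass == "M1"
  is_m2 <- !is.na(mclass) & mclass == "M2"
  ns <- length(ids)

  xy_specs <- Filter(function(s) s$kind == "XY_DIFFERENTIAL",
                     config$slr_specs)
  bg_specs <- Filter(function(s) s$kind == "X_LIKE_BACKGROUND",
                     config$slr_specs)
  hemi_specs <- Filter(function(s) s$kind == "Y_HEMIZYGOUS",
                       config$slr_specs)

  loci_parts <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    n_bg <- rpois(1, config$autosomal_snp_rate * len / 1000)
    pos_bg <- if (n_bg) sample.int(len, min(n_bg, len)) else integer(0)
    cls_bg <- rep("autosomal", length(pos_bg))
    pos_xy <- integer(0)
    for (s in xy_specs) {
      if (s$chrom != ch) next
      n_xy <- rpois(1, s$snp_rate * (s$end - s$start) / 1000)
      if (n_xy)
        pos_xy <- c(pos_xy, s$start + sample.int(s$end - s$start, n_xy))
    }
    for (s in bg_specs) {
      if (s$chrom != ch) next
      n_b <- rpois(1, s$snp_rate * (s$end - s$start) / 1000)
      if (n_b) {
        p <- s$start + sample.int(s$end - s$start, n_b)
        pos_bg <- c(pos_bg, p)
        cls_bg <- c(cls_bg, rep("autosomal", n_b))
      }
    }
    # drop background loci colliding with XY positions; XY wins
    keep <- !pos_bg %in% pos_xy
    pos_bg <- pos_bg[keep]
    cls_bg <- cls_bg[keep]
    pos_xy <- unique(pos_xy)
    part <- data.frame(
      chrom = ch, pos = c(pos_bg, pos_xy),
      class = c(cls_bg, rep("xy_differential", length(pos_xy))))
    loci_parts[[ch]] <- part[!duplicated(part$pos), , drop = FALSE]
  }
  loci <- do.call(rbind, loci_parts)
  o <- order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  nl <- nrow(loci)

  nt <- c("A", "C", "G", "T")
  ref_i <- sample.int(4, nl, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3, nl, replace = TRUE)) %% 4L + 1L
  ref <- nt[ref_i]
  alt <- nt[alt_i]

  codes <- matrix(NA_integer_, nl, ns)
  auto <- loci$class == "autosomal"
  n_auto <- sum(auto)
  if (n_auto) {
    p <- rbeta(n_auto, config$allele_freq_alpha, config$allele_freq_beta)
    codes[auto, ] <- rbinom(n_auto * ns, 2, rep(p, ns))
  }
  xy <- which(loci$class == "xy_differential")
  if (length(xy)) {
    # X allele is ref or alt with equal probability; females are
    # homozygous for it, divergent-Y males heterozygous
    female_code <- ifelse(runif(length(xy)) < 0.5, GT_HOM_REF, GT_HOM_ALT)
    codes[xy, is_f] <- rep(female_code, sum(is_f))
    codes[xy, is_m2] <- GT_HET
    if (any(is_m1)) {
      xlike <- matrix(runif(length(xy) * sum(is_m1)) <
                        config$m1_y_similarity,
                      length(xy), sum(is_m1))
      m1_codes <- matrix(rep(female_code, sum(is_m1)), length(xy))
      m1_codes[!xlike] <- GT_HET
      codes[xy, is_m1] <- m1_codes
    }
  }
  if (config$genotype_error > 0) {
    flip <- which(runif(nl * ns) < config$genotype_error)
    if (length(flip)) {
      shift <- sample(1:2, length(flip), replace = TRUE)
      codes[flip] <- (codes[flip] + shift) %% 3L
    }
  }
  if (config$missing_rate > 0)
    codes[runif(nl * ns) < config$missing_rate] <- NA_integer_

  gm <- genotype_matrix(
    data.frame(chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt),
    ids, codes)
  # carry locus classes in the same (chrom, pos) order as gm
  cls <- loci$class[order(loci$chrom, loci$pos)]

  win <- make_windows(config$chrom_lengths, config$window_size)
  nw <- nrow(win)
  shape <- if (config$depth_dispersion > 0)
    1 / config$depth_dispersion else Inf
  g <- if (is.finite(shape))
    matrix(rgamma(nw * ns, shape = shape, scale = 1 / shape), nw, ns)
  else matrix(1, nw, ns)
  lam <- config$mean_depth * g * (win$end - win$start) / config$read_length
  depth <- matrix(rpois(nw * ns, lam), nw, ns) * config$read_length /
    (win$end - win$start)
  hemi_regions <- region_df()
  for (s in hemi_specs) {
    wsel <- win$chrom == s$chrom & win$start < s$end & win$end > s$start
    no_y <- is_f | is_m1
    depth[wsel, no_y] <- runif(sum(wsel) * sum(no_y),
                               0, config$hemi_female_noise)
    hemi_regions <- rbind(hemi_regions,
                          region_df(s$chrom, s$start, s$end,
                                    "HEMIZYGOUS", NA_real_))
  }
  colnames(depth) <- ids
  dt <- depth_table(win[, c("chrom", "start", "end")], depth)

  truth <- list(slr_specs = config$slr_specs,
                locus_class = setNames(cls, locus_ids(gm$loci)),
                male_class = setNames(mclass, ids),
                hemizygous_regions = hemi_regions,
                config = config)
  structure(list(genotypes = gm, depth = dt, samples = sheet,
                 truth = truth), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the three pipeline inputs (VCF genotypes, BED-like depth TSV,
#' sample sheet TSV) plus the ground truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the four paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             depth = file.path(dir, "depth.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(cohort$genotypes, paths[["vcf"]],
            contig_lengths = cohort$truth$config$chrom_lengths)
  write_depth(cohort$depth, paths[["depth"]])
  write.table(as.data.frame(cohort$samples), paths[["samples"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  tr$slr_specs <- lapply(tr$slr_specs, unclass)
  tr$config <- unclass(tr$config)
  tr$config$slr_specs <- lapply(tr$config$slr_specs, unclass)
  tr$config$chrom_lengths <- as.list(tr$config$chrom_lengths)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  paths
}
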