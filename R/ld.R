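#' Composite (dosage) r2 between two loci
#'
#' Squared Pearson correlation of alternate-allele dosages over the
#' samples called at both loci — the composite LD measure appropriate
#' for unphased genotypes. Undefined (NA) when fewer than two samples
#' are co-called or either locus is monomorphic after pairwise
#' deletion. Invariant under REF/ALT relabelling of either locus.
#'
#' @param g_i,g_j integer genotype-code vectors (0/1/2, NA missing).
#' @return r2 in \[0, 1\], or NA.
#' @export
dosage_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- g_i[ok]
  y <- g_j[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Pairwise r2 matrix over a region
#'
#' @param gm a [genotype_matrix()].
#' @param region optional list/row with `chrom`, `start`, `end`
#'   (0-based half-open); default uses all loci of `gm`.
#' @return list with `r2` (symmetric matrix, unit diagonal, NA where
#'   undefined) and `loci` (data.frame of the loci used).
#' @export
r2_matrix <- function(gm, region = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sub <- if (is.null(region)) gm else
    genotypes_in_region(gm, region$chrom, region$start, region$end)
  nl <- nrow(sub$loci)
  if (nl < 2) stop("r2_matrix needs at least 2 loci in the region")
  m <- diag(1, nl)
  dimnames(m) <- list(locus_ids(sub$loci), locus_ids(sub$loci))
  for (i in seq_len(nl - 1)) {
    for (j in seq(i + 1, nl)) {
      m[i, j] <- m[j, i] <- dosage_r2(sub$codes[i, ], sub$codes[j, ])
    }
  }
  list(r2 = m, loci = sub$loci)
}

#' Distance-binned LD decay curve
#'
#' Mean pairwise dosage r2 as a function of inter-locus distance,
#' within a region, optionally restricted to the samples of one sex.
#' Pairs on different chromosomes or farther apart than `max_dist` are
#' ignored; bins containing no pair are omitted.
#'
#' @param gm a [genotype_matrix()].
#' @param region optional region (as in [r2_matrix()]).
#' @param max_dist maximum pair distance in bp.
#' @param bin_size distance-bin width in bp.
#' @param sexes optional [sample_sheet()] used with `group`.
#' @param group optional "F" or "M": restrict to that sex's samples.
#' @return data.frame: bin_start, bin_end, n_pairs, mean_r2.
#' @export
ld_decay <- function(gm, region = NULL, max_dist = 500000,
                     bin_size = 10000, sexes = NULL, group = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sub <- if (is.null(region)) gm else
    genotypes_in_region(gm, region$chrom, region$start, region$end)
  if (!is.null(group)) {
    stopifnot(!is.null(sexes), group %in% c("F", "M"))
    sub <- subset_genotypes(
      sub, samples = intersect(sub$samples,
                               sexes$sample_id[sexes$sex == group]))
  }
  nl <- nrow(sub$loci)
  if (nl < 2) stop("ld_decay needs at least 2 loci")
  n_bins <- ceiling(max_dist / bin_size)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (i in seq_len(nl - 1)) {
    for (j in seq(i + 1, nl)) {
      if (sub$loci$chrom[i] != sub$loci$chrom[j]) next
      d <- abs(sub$loci$pos[j] - sub$loci$pos[i])
      if (d > max_dist) next
      r2 <- dosage_r2(sub$codes[i, ], sub$codes[j, ])
      if (is.na(r2)) next
      b <- min(max(1L, ceiling(d / bin_size)), n_bins)
      sums[b] <- sums[b] + r2
      counts[b] <- counts[b] + 1L
    }
  }
  keep <- counts > 0
  data.frame(bin_start = (which(keep) - 1) * bin_size,
             bin_end = pmin(which(keep) * bin_size, max_dist),
             n_pairs = counts[keep], mean_r2 = sums[keep] / counts[keep])
}
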