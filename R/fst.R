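#' Weir-Cockerham variance components at one biallelic site
#'
#' Computes the among-population (a), among-individual-within-
#' population (b) and within-individual (c) variance components of
#' Weir & Cockerham (1984) for two groups of diploid genotypes, from
#' the per-group called sample sizes, alternate-allele frequencies and
#' observed heterozygote frequencies. Missing calls are excluded from
#' the group counts. The per-site estimate is theta = a / (a + b + c),
#' undefined when the denominator is zero (monomorphic site) or when a
#' group has no called genotype; negative estimates are a legitimate
#' finite-sample outcome and are returned unclipped.
#'
#' @param g1,g2 integer genotype-code vectors (0/1/2, NA missing) for
#'   the two groups.
#' @return list with `a`, `b`, `c`, `fst` (NA when undefined) and the
#'   called sample sizes `n1`, `n2`.
#' @export
wc_site_components <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  n1 <- length(g1)
  n2 <- length(g2)
  if (n1 == 0L || n2 == 0L)
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                fst = NA_real_, n1 = n1, n2 = n2))
  r <- 2
  n_i <- c(n1, n2)
  p_i <- c(sum(g1), sum(g2)) / (2 * n_i)
  h_i <- c(sum(g1 == 1L), sum(g2 == 1L)) / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) {
    # single diploid per group: components degenerate
    return(list(a = NA_real_, b = NA_real_, c = hbar / 2,
                fst = NA_real_, n1 = n1, n2 = n2))
  }
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  fst <- if (isTRUE(all.equal(tot, 0)) || tot == 0) NA_real_ else a / tot
  list(a = a, b = b, c = cc, fst = fst, n1 = n1, n2 = n2)
}

#' Per-site Weir-Cockerham components between the sexes
#'
#' Applies [wc_site_components()] at every locus of a genotype matrix,
#' contrasting females against males (or any two groups given
#' explicitly).
#'
#' @param gm a [genotype_matrix()].
#' @param sexes a [sample_sheet()]; group 1 = females, group 2 = males.
#' @param group1,group2 optional explicit sample-id vectors overriding
#'   the sex split.
#' @return data.frame with chrom, pos, a, b, c, fst per locus.
#' @export
site_fst <- function(gm, sexes, group1 = NULL, group2 = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(group1) || is.null(group2)) {
    grp <- split_sexes(sexes)
    group1 <- grp$F
    group2 <- grp$M
  }
  i1 <- match(group1, gm$samples)
  i2 <- match(group2, gm$samples)
  if (anyNA(i1) || anyNA(i2)) stop("group sample ids not in matrix")
  # vectorized Weir-Cockerham components over all loci; identical math
  # to wc_site_components (asserted by the test suite)
  g1 <- gm$codes[, i1, drop = FALSE]
  g2 <- gm$codes[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  r <- 2
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- n1 == 0L | n2 == 0L | nbar <= 1 | nc == 0
  a[bad] <- NA_real_
  b[bad] <- NA_real_
  tot <- a + b + cc
  fst <- ifelse(is.na(tot) | abs(tot) < 1.5e-8, NA_real_, a / tot)
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
             a = a, b = b, c = cc, fst = fst)
}

#' Aggregate per-site F_ST components in genomic windows
#'
#' `weighted` mode (the conventional windowed Weir-Cockerham estimate)
#' is sum(a) / sum(a + b + c) over the sites in a window; `mean` mode
#' averages the defined per-site ratios. Windows containing no site
#' with defined components get `NA`.
#'
#' @param components output of [site_fst()].
#' @param windows window grid from [make_windows()] (or a
#'   `depth_table`'s `windows`).
#' @param mode `"weighted"` or `"mean"`.
#' @return numeric vector aligned to `windows` rows.
#' @export
windowed_fst <- function(components, windows,
                         mode = c("weighted", "mean")) {
  mode <- match.arg(mode)
  widx <- window_of(windows, components$chrom, components$pos - 1L)
  out <- rep(NA_real_, nrow(windows))
  ok <- !is.na(widx) & !is.na(components$a)
  if (!any(ok)) return(out)
  if (mode == "weighted") {
    num <- tapply(components$a[ok], widx[ok], sum)
    den <- tapply((components$a + components$b + components$c)[ok],
                  widx[ok], sum)
    val <- ifelse(den == 0, NA_real_, num / den)
    out[as.integer(names(num))] <- val
  } else {
    ok2 <- ok & !is.na(components$fst)
    if (any(ok2)) {
      m <- tapply(components$fst[ok2], widx[ok2], mean)
      out[as.integer(names(m))] <- m
    }
  }
  out
}
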