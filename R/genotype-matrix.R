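#' Construct a genotype matrix
#'
#' The central substrate of all SNP-based stages: a loci x samples
#' matrix of diploid genotype codes together with locus coordinates.
#' Codes are alternate-allele dosages: 0 = hom ref (0/0), 1 = het
#' (0/1), 2 = hom alt (1/1), `NA` = missing (./.). Loci must be
#' biallelic SNPs sorted by (chrom, pos).
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt` (single nucleotides each).
#' @param samples character vector of unique sample ids.
#' @param codes integer matrix, `nrow(loci)` x `length(samples)`, over
#'   \{0, 1, 2, NA\}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, samples, codes) {
  loci <- as.data.frame(loci)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(loci) || ncol(codes) != length(samples))
    stop("codes dimensions do not match loci/samples")
  if (any(!is.na(codes) & !(codes %in% 0:2)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(loci)) {
    if (any(loci$pos < 1)) stop("locus pos must be >= 1")
    bad <- nchar(loci$ref) != 1L | nchar(loci$alt) != 1L |
      loci$ref == loci$alt
    if (any(bad)) stop("loci must be biallelic SNPs with ref != alt")
    o <- order(loci$chrom, loci$pos)
    loci <- loci[o, , drop = FALSE]
    codes <- codes[o, , drop = FALSE]
  }
  rownames(loci) <- NULL
  dimnames(codes) <- list(locus_ids(loci), samples)
  structure(list(loci = loci, samples = samples, codes = codes),
            class = "genotype_matrix")
}

locus_ids <- function(loci) {
  if (!nrow(loci)) return(character(0))
  paste0(loci$chrom, ":", loci$pos)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples (%d chromosomes)\n",
              nrow(x$loci), length(x$samples),
              length(unique(x$loci$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by locus index and/or sample id
#'
#' @param gm a [genotype_matrix()].
#' @param loci integer or logical index into loci, or character locus
#'   ids ("chrom:pos").
#' @param samples character sample ids or index.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, loci = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  li <- seq_len(nrow(gm$loci))
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, locus_ids(gm$loci)) else li[loci]
    if (anyNA(li)) stop("unknown locus id in selection")
  }
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples) else si[samples]
    if (anyNA(si)) stop("unknown sample id in selection")
  }
  genotype_matrix(gm$loci[li, , drop = FALSE], gm$samples[si],
                  gm$codes[li, si, drop = FALSE])
}

#' Restrict a genotype matrix to a genomic region
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval; defaults span the
#'   chromosome.
#' @return A `genotype_matrix` with the loci whose (0-based) position
#'   falls in \[start, end).
#' @export
genotypes_in_region <- function(gm, chrom, start = 0, end = Inf) {
  pos0 <- gm$loci$pos - 1L
  keep <- gm$loci$chrom == chrom & pos0 >= start & pos0 < end
  subset_genotypes(gm, loci = keep)
}
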