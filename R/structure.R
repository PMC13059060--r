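#' PCA on genotype dosages
#'
#' Missing dosages are mean-imputed per locus, loci are centered on
#' twice their alternate-allele frequency and scaled by
#' sqrt(2 p (1 - p)) — the usual variance standardization for genotype
#' PCA — and monomorphic loci are skipped. Coordinates are the top-k
#' left singular vectors scaled by their singular values, with a
#' deterministic sign convention (the largest-magnitude locus loading
#' of each component is positive).
#'
#' @param gm a [genotype_matrix()] with >= 2 samples and >= 1
#'   polymorphic locus.
#' @param k number of components.
#' @return list of class `pca_result`: `coordinates` (samples x k,
#'   rownames = sample ids), `variance_explained` (length k).
#' @export
pca_genotypes <- function(gm, k = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), k >= 1,
            length(gm$samples) >= 2)
  x <- t(gm$codes) # samples x loci
  storage.mode(x) <- "double"
  cm <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0))
    x[is.na(x[, j]), j] <- cm[j]
  p <- cm / 2
  keep <- p > 0 & p < 1 & apply(x, 2, var) > 0
  if (!any(keep)) stop("no polymorphic loci for PCA")
  x <- sweep(x[, keep, drop = FALSE], 2, 2 * p[keep])
  x <- sweep(x, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-10
  rank <- sum(pos)
  kk <- min(k, rank)
  if (k > rank)
    warning("requested ", k, " components but rank is ", rank,
            "; trailing components zero-filled")
  coords <- matrix(0, nrow(x), k,
                   dimnames = list(gm$samples[seq_len(nrow(x))],
                                   paste0("PC", seq_len(k))))
  ve <- numeric(k)
  for (comp in seq_len(kk)) {
    v <- sv$v[, comp]
    if (v[which.max(abs(v))] < 0) {
      v <- -v
      sv$u[, comp] <- -sv$u[, comp]
    }
    coords[, comp] <- sv$u[, comp] * sv$d[comp]
  }
  ve[seq_len(kk)] <- (sv$d[seq_len(kk)]^2) / sum(sv$d^2)
  rownames(coords) <- gm$samples
  structure(list(coordinates = coords, variance_explained = ve),
            class = "pca_result")
}

#' Identity-by-state allele-sharing distance matrix
#'
#' Distance between two samples is 1 - (shared alleles) / (2 x loci
#' called in both); for dosage codes this is mean(|g1 - g2|) / 2 over
#' co-called loci (pairwise deletion).
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$samples) >= 2)
  ns <- length(gm$samples)
  d <- matrix(0, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      ok <- !is.na(gm$codes[, i]) & !is.na(gm$codes[, j])
      if (!any(ok))
        stop("samples ", gm$samples[i], " and ", gm$samples[j],
             " share no called locus")
      d[i, j] <- d[j, i] <-
        mean(abs(gm$codes[ok, i] - gm$codes[ok, j])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion; ties are
#' broken by the lowest-index pair, and negative branch lengths are
#' clamped to zero with the deficit transferred to the sibling branch.
#' On additive distance matrices the generating tree's path lengths
#' are recovered exactly.
#'
#' @param d symmetric distance matrix with labels, >= 3 taxa.
#' @return Newick string (with branch lengths, terminated by ";").
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 3, isTRUE(all.equal(d, t(d))))
  if (anyNA(d)) stop("distance matrix has undefined entries")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  node <- labels
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    c(li, lj)
  }
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among ties, scanning i < j in row-major order
    best <- c(NA, NA)
    bq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (q[i, j] < bq - 1e-12) { bq <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    l <- clamp2(li, lj)
    new_lab <- sprintf("(%s:%.10g,%s:%.10g)", node[i], l[1],
                       node[j], l[2])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    node <- c(node[keep], new_lab)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- pmax(c(la, lb, lc), 0)
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", node[1], ls[1], node[2],
          ls[2], node[3], ls[3])
}

#' Assign males to genotypic classes M1 / M2
#'
#' Default rule: a male whose sex-linkage score on the SLR panel is at
#' least `thr` is labelled M2 (divergent Y haplotype), otherwise M1
#' (X-like, weakly differentiated Y). The alternative PCA rule splits
#' the males by 2-means clustering on PC1 of SLR SNPs and labels the
#' cluster nearer the female centroid M1.
#'
#' @param sexes a [sample_sheet()].
#' @param scores [sample_scores()] data.frame (score rule).
#' @param pca a [pca_genotypes()] result on SLR SNPs (PCA rule).
#' @param thr score threshold for M2 (default 0.6).
#' @param method `"score"` or `"pca"`.
#' @return named character vector over males: "M1", "M2" (or
#'   "unknown" when fewer than 2 males or a male's score is undefined).
#' @export
assign_male_classes <- function(sexes, scores = NULL, pca = NULL,
                                thr = 0.6, method = c("score", "pca")) {
  method <- match.arg(method)
  males <- sexes$sample_id[sexes$sex == "M"]
  if (length(males) < 2)
    return(setNames(rep("unknown", length(males)), males))
  if (method == "score") {
    stopifnot(!is.null(scores))
    s <- scores$score[match(males, scores$sample_id)]
    lab <- ifelse(is.na(s), "unknown", ifelse(s >= thr, "M2", "M1"))
    return(setNames(lab, males))
  }
  stopifnot(!is.null(pca))
  pc1 <- pca$coordinates[, 1]
  females <- sexes$sample_id[sexes$sex == "F"]
  f_centroid <- mean(pc1[females])
  mvals <- pc1[males]
  km <- kmeans(mvals, centers = 2, nstart = 5)
  m1_cluster <- which.min(abs(km$centers - f_centroid))
  setNames(ifelse(km$cluster == m1_cluster, "M1", "M2"), males)
}
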