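test_that("genotype PCA matches a direct eigendecomposition", {
  codes <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L)) # loci x samples
  gm <- gm_fix(codes, samples = c("a", "b", "c"))
  # the two loci are perfectly anticorrelated, so the rank is 1 and
  # the second component is zero-filled with a warning
  expect_warning(res <- pca_genotypes(gm, k = 2), "rank")
  # oracle: scale the dosage matrix the same way, then eigendecompose
  # the sample-sample covariance (Gram) matrix directly
  x <- t(codes)
  p <- colMeans(x) / 2
  xs <- sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  gram <- xs %*% t(xs)
  eig <- eigen(gram, symmetric = TRUE)
  # coordinates reproduce the Gram matrix: C C^T = G
  expect_equal(res$coordinates %*% t(res$coordinates), gram,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$coordinates[, 1]^2 / sum(res$coordinates[, 1]^2),
               eig$vectors[, 1]^2, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$variance_explained,
               eig$values[1:2] / sum(pmax(eig$values, 0)),
               tolerance = 1e-8)
})

test_that("PCA is stable to reordering and ignores monomorphic loci", {
  co <- simulate_cohort(tiny_config(seed = 81, n_m1 = 6, n_m2 = 5))
  gm <- subset_genotypes(co$genotypes, loci = 1:200)
  res <- pca_genotypes(gm, k = 3)
  perm <- sample(seq_along(gm$samples))
  res_p <- pca_genotypes(subset_genotypes(gm, samples = perm), k = 3)
  expect_equal(res_p$coordinates[gm$samples, ], res$coordinates,
               tolerance = 1e-8)
  # duplicated samples land on identical coordinates
  codes <- cbind(c(0L, 0L, 2L), c(0L, 0L, 2L), c(2L, 2L, 0L),
                 c(2L, 2L, 0L))
  gm2 <- gm_fix(codes, samples = c("a1", "a2", "b1", "b2"))
  r2 <- pca_genotypes(gm2, k = 1)
  expect_equal(r2$coordinates["a1", ], r2$coordinates["a2", ])
  expect_equal(r2$coordinates["a1", 1], -r2$coordinates["b1", 1],
               tolerance = 1e-10)
  # adding monomorphic loci changes nothing
  gm3 <- gm_fix(rbind(codes, rep(0L, 4), rep(2L, 4)),
                samples = c("a1", "a2", "b1", "b2"))
  expect_equal(pca_genotypes(gm3, k = 1)$coordinates, r2$coordinates)
})

test_that("IBS distances count shared alleles", {
  gm <- gm_fix(rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L)),
               samples = c("a", "b"))
  expect_equal(ibs_distance(gm)["a", "b"], 0)
  gm2 <- gm_fix(matrix(c(0L, 2L), 1), samples = c("a", "b"))
  expect_equal(ibs_distance(gm2)["a", "b"], 1)
  gm3 <- gm_fix(matrix(c(0L, 1L), 1), samples = c("a", "b"))
  expect_equal(ibs_distance(gm3)["a", "b"], 0.5)
  gm4 <- gm_fix(rbind(c(0L, NA), c(NA, 1L)), samples = c("a", "b"))
  expect_error(ibs_distance(gm4), "no called locus")
})

test_that("neighbor joining recovers additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) gives these pairwise path lengths
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  nwk <- nj_tree(d)
  tr <- ape::read.tree(text = nwk)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # AB|CD split present: the path A-B avoids C,D and vice versa
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))

  # taxon-order permutation yields an isomorphic tree
  perm <- c(3, 1, 4, 2)
  nwk2 <- nj_tree(d[perm, perm])
  tr2 <- ape::read.tree(text = nwk2)
  expect_equal(cophenetic(tr2)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("neighbor joining agrees with the reference implementation
           on random additive matrices", {
  set.seed(91)
  for (i in 1:5) {
    n <- 8
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
    d <- cophenetic(tr)
    got <- ape::read.tree(text = nj_tree(d))
    expect_equal(cophenetic(got)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("three-taxon trees solve the three-point equations", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- ape::read.tree(text = nj_tree(d))
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("male classes follow the score rule and the PCA rule", {
  co <- simulate_cohort(tiny_config(seed = 93, n_m1 = 12, n_m2 = 5,
                                    genotype_error = 0.005,
                                    missing_rate = 0.02))
  sheet <- co$samples
  pan <- build_panel(co$genotypes, sheet,
                     list(chrom = "chrA", start = 5e5, end = 1e6))
  sc <- sample_scores(co$genotypes, pan)
  cls <- assign_male_classes(sheet, scores = sc)
  expect_equal(cls, co$truth$male_class[names(cls)])

  # PCA route on SLR SNPs separates the same classes
  slr_gm <- genotypes_in_region(co$genotypes, "chrA", 5e5, 1e6)
  pca <- pca_genotypes(slr_gm, k = 2)
  cls2 <- assign_male_classes(sheet, pca = pca, method = "pca")
  expect_equal(cls2, co$truth$male_class[names(cls2)])

  # degenerate cases
  all_zero <- sc
  all_zero$score <- 0
  expect_true(all(assign_male_classes(sheet, scores = all_zero) == "M1"))
  one_male <- sheet[sheet$sample_id %in%
                      c("F01", sheet$sample_id[sheet$sex == "M"][1]), ]
  class(one_male) <- class(sheet)
  expect_equal(unname(assign_male_classes(one_male, scores = sc)),
               "unknown")
})
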