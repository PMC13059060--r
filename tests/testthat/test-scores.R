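test_that("panels are built from the defining contrast only", {
  co <- simulate_cohort(tiny_config(seed = 41, n_m1 = 12, n_m2 = 5,
                                    genotype_error = 0.005,
                                    missing_rate = 0.02))
  region <- list(chrom = "chrA", start = 5e5, end = 1e6)
  pan <- build_panel(co$genotypes, co$samples, region)
  planted <- names(co$truth$locus_class)[co$truth$locus_class ==
                                           "xy_differential"]
  # relaxed panel from the F-vs-M2 contrast contains nearly all planted
  # loci (a few are lost to injected noise in the defining samples)
  expect_gt(length(intersect(pan$loci, planted)),
            0.9 * length(planted))

  # panel membership ignores the genotypes of non-defining samples
  gm2 <- co$genotypes
  m1_cols <- colnames(gm2$codes) %in%
    co$samples$sample_id[!is.na(co$samples$male_class) &
                           co$samples$male_class == "M1"]
  gm2$codes[, m1_cols] <- 2L
  pan2 <- build_panel(gm2, co$samples, region)
  expect_identical(pan2$loci, pan$loci)

  # no variants in the region -> empty panel with a warning
  expect_warning(
    pan3 <- build_panel(co$genotypes, co$samples,
                        list(chrom = "chrB", start = 1, end = 2)),
    "no variants")
  expect_length(pan3$loci, 0)
})

test_that("scores are heterozygote proportions over called panel loci", {
  codes <- cbind(c(rep(0L, 8), NA, NA),
                 c(1L, 1L, rep(0L, 6), NA, NA))
  gm <- gm_fix(codes, samples = c("a", "b"))
  sc <- sample_scores(gm, locus_ids(gm$loci))
  expect_equal(sc$n_called, c(8L, 8L))
  expect_equal(sc$score[sc$sample_id == "b"], 0.25)
  # a sample with no called panel locus has an undefined score
  gm2 <- gm_fix(cbind(c(NA, NA), c(0L, 1L)), samples = c("a", "b"))
  sc2 <- sample_scores(gm2, locus_ids(gm2$loci))
  expect_true(is.na(sc2$score[sc2$sample_id == "a"]))
})

test_that("defining-cohort females score exactly zero on their panel", {
  for (seed in c(1, 2, 3)) {
    co <- simulate_cohort(tiny_config(seed = seed, n_m1 = 12, n_m2 = 5,
                                      genotype_error = 0.01,
                                      missing_rate = 0.05))
    pan <- build_panel(co$genotypes, co$samples,
                       list(chrom = "chrA", start = 5e5, end = 1e6))
    sc <- sample_scores(co$genotypes, pan)
    females <- co$samples$sample_id[co$samples$sex == "F"]
    f_scores <- sc$score[sc$sample_id %in% females]
    expect_true(all(f_scores == 0))
  }
})

test_that("Fisher exact p-values match enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 0, 0), 2)), 1)
  tab <- matrix(c(5, 0, 0, 17), 2)
  expect_equal(fisher_exact_2x2(tab), 1 / choose(22, 5),
               tolerance = 1e-9)
  # invariance under transposition and row/column swaps
  set.seed(3)
  for (i in 1:20) {
    t0 <- matrix(rpois(4, 4), 2)
    p <- fisher_exact_2x2(t0)
    expect_equal(fisher_exact_2x2(t(t0)), p)
    expect_equal(fisher_exact_2x2(t0[2:1, ]), p)
    expect_equal(fisher_exact_2x2(t0[, 2:1]), p)
  }
})

test_that("Spearman rho matches hand values and the brute-rank oracle", {
  expect_equal(spearman_rank(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_rank(1:5, (1:5)^2)$p, 0)
  expect_equal(spearman_rank(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  expect_equal(spearman_rank(c(1, 1, 2), c(1, 2, 3))$rho, 1.5 / sqrt(3))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE) # ties likely
    y <- sample(1:4, n, replace = TRUE)
    rx <- brute_ranks(x)
    ry <- brute_ranks(y)
    if (var(rx) == 0 || var(ry) == 0) next
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_rank(x, y)$rho, num / den, tolerance = 1e-12)
  }
})

test_that("the t-approximation reproduces the published co-occurrence p", {
  # 22 individuals with rho = 0.725 gives p ~ 1.3e-4
  p <- 2 * pt(-abs(0.725 * sqrt(20 / (1 - 0.725^2))), df = 20)
  expect_lt(abs(log10(p) - log10(1.37e-4)), 0.15)
})

test_that("co-occurrence dichotomization and tests behave as published", {
  ids <- sprintf("i%02d", 1:22)
  sa <- data.frame(sample_id = ids, n_called = 10L, n_het = 0L,
                   score = c(rep(0.9, 5), rep(0.05, 17)))
  sb <- data.frame(sample_id = ids, n_called = 10L, n_het = 0L,
                   score = c(rep(0.8, 5), rep(0.03, 17)))
  res <- cooccurrence(sa, sb)
  expect_equal(as.vector(res$table), c(5, 0, 0, 17))
  expect_equal(res$n_discordant, 0)
  expect_equal(res$fisher_p, 1 / choose(22, 5), tolerance = 1e-9)
  expect_equal(res$spearman_rho, 1) # identical orderings

  # all low/low: no association signal
  sc <- data.frame(sample_id = ids, n_called = 10L, n_het = 0L,
                   score = rep(0.1, 22))
  res2 <- cooccurrence(sc, sc, cooccurrence_config(0.6, 0.3))
  expect_equal(res2$fisher_p, 1)

  # undefined scores are excluded pairwise
  sa2 <- sa
  sa2$score[1] <- NA
  res3 <- cooccurrence(sa2, sb)
  expect_equal(res3$n_excluded, 1)
  expect_equal(sum(res3$table), 21)
})
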