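mk_depth <- function(m_cov, f_cov, n_win = 1) {
  win <- make_windows(c(chr1 = n_win * 50000), 50000)
  depth <- cbind(matrix(rep(f_cov, each = n_win), n_win, 2),
                 matrix(rep(m_cov, each = n_win), n_win, 2))
  colnames(depth) <- c("f1", "f2", "m1", "m2")
  depth_table(win, depth)
}
scan_sheet <- sample_sheet(c("f1", "f2", "m1", "m2"),
                           c("F", "F", "M", "M"))

test_that("log2 coverage ratio follows the pseudocount formula", {
  expect_equal(depth_log2_ratio(mk_depth(16, 16), scan_sheet), 0)
  expect_equal(depth_log2_ratio(mk_depth(2, 1), scan_sheet),
               log2(2.01 / 1.01))
  # hemizygous signature: male 16x, female absent
  expect_equal(depth_log2_ratio(mk_depth(16, 0), scan_sheet),
               log2(16.01 / 0.01))
  expect_equal(round(log2(16.01 / 0.01), 3), 10.645)
})

test_that("coverage ratio is antisymmetric under sex-label swap", {
  set.seed(99)
  win <- make_windows(c(chr1 = 1e6), 50000)
  depth <- matrix(runif(20 * 4, 0, 40), 20, 4,
                  dimnames = list(NULL, c("f1", "f2", "m1", "m2")))
  dt <- depth_table(win, depth)
  swapped <- sample_sheet(c("f1", "f2", "m1", "m2"),
                          c("M", "M", "F", "F"))
  expect_equal(depth_log2_ratio(dt, scan_sheet),
               -depth_log2_ratio(dt, swapped))
})

test_that("SNP density counts within-sex polymorphism per Mb", {
  # 1 Mb chromosome, one window; 10 male-polymorphic loci, females
  # fixed hom-ref at all of them
  codes <- cbind(matrix(0L, 10, 2), matrix(rep(c(1L, 2L), 5), 10, 2,
                                           byrow = TRUE))
  gm <- gm_fix(codes, samples = c("f1", "f2", "m1", "m2"))
  win <- make_windows(c(chr1 = 1e6), 1e6)
  d <- snp_density_tracks(gm, win, scan_sheet)
  expect_equal(d$snp_density_m, 10)
  expect_equal(d$snp_density_f, 0)
  expect_equal(d$log2_snp_ratio, log2(10.01 / 0.01))
  expect_equal(round(d$log2_snp_ratio, 2), 9.97)

  # both sexes polymorphic at the same loci -> ratio 0
  codes2 <- matrix(rep(c(0L, 1L, 1L, 0L), 5), 5, 4, byrow = TRUE)
  gm2 <- gm_fix(codes2, samples = c("f1", "f2", "m1", "m2"))
  d2 <- snp_density_tracks(gm2, win, scan_sheet)
  expect_equal(d2$log2_snp_ratio, 0)

  # empty window
  gm3 <- gm_fix(matrix(0:1, 1, 4), samples = c("f1", "f2", "m1", "m2"))
  win2 <- make_windows(c(chr1 = 2e6), 1e6)
  d3 <- snp_density_tracks(gm3, win2, scan_sheet)
  expect_equal(d3$snp_density_m[2], 0)
  expect_equal(d3$log2_snp_ratio[2], 0)
})

test_that("call_slr flags the top quantile and merges runs", {
  # 200 windows, 5 consecutive elevated ones
  win <- make_windows(c(chr1 = 1e7), 50000)
  fst <- rep(0, 200) + seq(0, 0.001, length.out = 200) # break ties
  fst[101:105] <- 0.8
  track <- data.frame(chrom = win$chrom, start = win$start,
                      end = win$end, fst = fst)
  reg <- call_slr(track, window_scan_config(fst_quantile = 0.975))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, win$start[101])
  expect_equal(reg$end, win$end[105])
  expect_equal(reg$score, 0.8, tolerance = 1e-6)

  # isolated flagged windows never form a region at min run 2
  fst2 <- rep(0, 200) + seq(0, 0.001, length.out = 200)
  fst2[c(20, 80, 140, 199)] <- 0.8
  track2 <- data.frame(chrom = win$chrom, start = win$start,
                       end = win$end, fst = fst2)
  reg2 <- call_slr(track2, window_scan_config(fst_quantile = 0.98))
  expect_equal(nrow(reg2), 0)

  # a one-window gap inside a run is bridged
  fst3 <- rep(0, 200) + seq(0, 0.001, length.out = 200)
  fst3[c(50, 51, 53, 54)] <- 0.8
  track3 <- data.frame(chrom = win$chrom, start = win$start,
                       end = win$end, fst = fst3)
  reg3 <- call_slr(track3, window_scan_config(fst_quantile = 0.98))
  expect_equal(nrow(reg3), 1)
  expect_equal(reg3$start, win$start[50])
  expect_equal(reg3$end, win$end[54])

  expect_error(call_slr(track[1:5, ]), "at least 10")
})

test_that("called regions are disjoint and sorted", {
  co <- simulate_cohort(tiny_config(seed = 23, n_m1 = 0))
  track <- build_window_track(co$genotypes, co$depth, co$samples)
  reg <- call_slr(track, window_scan_config(fst_quantile = 0.9))
  if (nrow(reg) > 1) {
    for (ch in unique(reg$chrom)) {
      r <- reg[reg$chrom == ch, ]
      expect_true(all(diff(r$start) > 0))
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
  }
  expect_true(all(reg$end > reg$start))
})
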