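# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

# Small genotype matrix from a codes matrix (loci x samples); positions
# default to 1 kb spacing on one chromosome.
gm_fix <- function(codes, chrom = NULL, pos = NULL, samples = NULL) {
  codes <- as.matrix(codes)
  nl <- nrow(codes)
  chrom <- chrom %||% rep("chr1", nl)
  pos <- pos %||% seq(1000, by = 1000, length.out = nl)
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(codes)))
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
    samples, codes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample sheet for n_f females then n_m males matching gm_fix naming.
sheet_fix <- function(n_f, n_m, male_class = NULL) {
  n <- n_f + n_m
  sample_sheet(sprintf("s%02d", seq_len(n)),
               c(rep("F", n_f), rep("M", n_m)),
               male_class = c(rep(NA_character_, n_f), male_class))
}

# Compact cohort for integration tests: 4 Mb over two chromosomes,
# error-free unless stated, 5 F + 5 M2 (no M1) so strict XY patterns
# are exact.
tiny_config <- function(seed = 1, n_m1 = 0, n_m2 = 5,
                        genotype_error = 0, missing_rate = 0, ...) {
  sim_config(chrom_lengths = c(chrA = 2e6, chrB = 2e6),
             window_size = 50000,
             n_females = 5, n_m1 = n_m1, n_m2 = n_m2,
             autosomal_snp_rate = 1,
             slr_specs = list(
               slr_spec("chrA", 5e5, 1e6, "XY_DIFFERENTIAL",
                        snp_rate = 3),
               slr_spec("chrB", 5e5, 6e5, "Y_HEMIZYGOUS")),
             genotype_error = genotype_error,
             missing_rate = missing_rate,
             hemi_female_noise = 0, seed = seed, ...)
}

# Restrict a sample sheet to the defining cohort (females + M2 males).
defining_sheet <- function(sheet) {
  d <- sheet[sheet$sex == "F" |
               (!is.na(sheet$male_class) & sheet$male_class == "M2"), ]
  class(d) <- class(sheet)
  d
}

# Independent mid-rank computation by explicit counting (oracle for
# spearman_rank): rank_i = 1 + #{x_j < x_i} + #{j != i : x_j == x_i}/2.
brute_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2, numeric(1))
}

# Exhaustive best single mean-split of a series by SSE (oracle for
# binseg_mean with Q = 1).
brute_single_split <- function(series, min_segment = 2) {
  n <- length(series)
  sse <- function(v) sum((v - mean(v))^2)
  lo <- min_segment
  hi <- n - min_segment
  if (lo > hi) return(NULL)
  costs <- vapply(lo:hi, function(t)
    sse(series[1:t]) + sse(series[(t + 1):n]), numeric(1))
  (lo:hi)[which.min(costs)]
}
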