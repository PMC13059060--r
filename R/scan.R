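#' Window-scan configuration
#'
#' @param window_size window size in bp (default 50 kb).
#' @param pseudocount added to both numerator and denominator of log2
#'   ratios (coverage and SNP density) to guard zeros; the value 0.01
#'   also sets the scale of the hemizygous signature, log2(d + 0.01)
#'   - log2(0.01).
#' @param fst_quantile quantile of the windowed F_ST distribution above
#'   which windows are flagged as candidate SLR members (default 0.99,
#'   the "top 1 percent" rule).
#' @param min_flagged_windows minimum number of flagged windows in a
#'   merged run for it to be reported.
#' @param max_gap_windows maximum number of consecutive unflagged
#'   windows bridged when merging flagged runs.
#' @param quantile_scope `"genome"` (one threshold for the whole scan)
#'   or `"chromosome"` (one threshold per chromosome).
#' @param density_mode `"polymorphic"` counts loci at which a sex shows
#'   both alleles among its called genotypes; `"alt_carrier"` counts
#'   loci at which at least one individual of the sex carries the
#'   alternate allele.
#' @return list of class `window_scan_config`.
#' @export
window_scan_config <- function(window_size = 50000, pseudocount = 0.01,
                               fst_quantile = 0.99,
                               min_flagged_windows = 2,
                               max_gap_windows = 1,
                               quantile_scope = c("genome", "chromosome"),
                               density_mode = c("polymorphic",
                                                "alt_carrier")) {
  stopifnot(pseudocount > 0, fst_quantile > 0, fst_quantile < 1,
            min_flagged_windows >= 1, max_gap_windows >= 0)
  structure(list(window_size = window_size, pseudocount = pseudocount,
                 fst_quantile = fst_quantile,
                 min_flagged_windows = min_flagged_windows,
                 max_gap_windows = max_gap_windows,
                 quantile_scope = match.arg(quantile_scope),
                 density_mode = match.arg(density_mode)),
            class = "window_scan_config")
}

#' Per-window log2 male:female coverage ratio
#'
#' For each window, male coverage is the mean depth over males and
#' female coverage the mean over females; the track value is
#' log2(male coverage + pseudocount) - log2(female coverage +
#' pseudocount). With the default pseudocount of 0.01, a hemizygous
#' window (male depth ~16x, female depth 0) scores ~10.6 while equal
#' coverage scores 0; the statistic is antisymmetric under swapping the
#' sex labels.
#'
#' @param depth a [depth_table()].
#' @param sexes a [sample_sheet()].
#' @param cfg a [window_scan_config()] (only `pseudocount` is used).
#' @return numeric vector aligned to `depth$windows`.
#' @export
depth_log2_ratio <- function(depth, sexes, cfg = window_scan_config()) {
  stopifnot(inherits(depth, "depth_table"))
  check_samples_match(depth$samples, sexes)
  grp <- split_sexes(sexes)
  m_cov <- rowMeans(depth$depth[, depth$samples %in% grp$M, drop = FALSE])
  f_cov <- rowMeans(depth$depth[, depth$samples %in% grp$F, drop = FALSE])
  log2(m_cov + cfg$pseudocount) - log2(f_cov + cfg$pseudocount)
}

#' Within-sex SNP-density tracks and their log2 ratio
#'
#' Per window and sex, density is the number of loci variable within
#' that sex (both alleles observed among its called genotypes, or
#' alt-carrier count under `density_mode = "alt_carrier"`), divided by
#' the window length in Mb. The ratio track is log2((dM + eps) /
#' (dF + eps)) with eps = `pseudocount`; windows with no loci score 0.
#'
#' @param gm a [genotype_matrix()] (normally already MAF-filtered).
#' @param windows window grid data.frame.
#' @param sexes a [sample_sheet()].
#' @param cfg a [window_scan_config()].
#' @return data.frame with columns `snp_density_m`, `snp_density_f`,
#'   `log2_snp_ratio` aligned to `windows`.
#' @export
snp_density_tracks <- function(gm, windows, sexes,
                               cfg = window_scan_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp <- split_sexes(sexes)
  polym <- function(codes) {
    if (cfg$density_mode == "alt_carrier")
      return(rowSums(codes > 0, na.rm = TRUE) > 0)
    has_ref <- rowSums(codes < 2, na.rm = TRUE) > 0
    has_alt <- rowSums(codes > 0, na.rm = TRUE) > 0
    has_ref & has_alt
  }
  v_m <- polym(gm$codes[, gm$samples %in% grp$M, drop = FALSE])
  v_f <- polym(gm$codes[, gm$samples %in% grp$F, drop = FALSE])
  widx <- window_of(windows, gm$loci$chrom, gm$loci$pos - 1L)
  count_in <- function(flag) {
    n <- rep(0, nrow(windows))
    ok <- !is.na(widx) & flag
    if (any(ok)) {
      t <- table(widx[ok])
      n[as.integer(names(t))] <- as.numeric(t)
    }
    n
  }
  mb <- (windows$end - windows$start) / 1e6
  dm <- count_in(v_m) / mb
  df <- count_in(v_f) / mb
  data.frame(snp_density_m = dm, snp_density_f = df,
             log2_snp_ratio = log2((dm + cfg$pseudocount) /
                                     (df + cfg$pseudocount)))
}

#' Assemble the standard genome-scan track table
#'
#' Convenience wrapper producing the window-aligned data.frame with
#' F_ST, log2 coverage-ratio and SNP-density columns used by
#' [call_slr()] and the track writers.
#'
#' @param gm a [genotype_matrix()].
#' @param depth a [depth_table()]; its window grid defines the track.
#' @param sexes a [sample_sheet()].
#' @param cfg a [window_scan_config()].
#' @param fst_mode passed to [windowed_fst()].
#' @return data.frame: chrom, start, end, fst, log2_cov_ratio,
#'   snp_density_m, snp_density_f, log2_snp_ratio.
#' @export
build_window_track <- function(gm, depth, sexes,
                               cfg = window_scan_config(),
                               fst_mode = "weighted") {
  windows <- depth$windows
  comp <- site_fst(gm, sexes)
  track <- data.frame(chrom = windows$chrom, start = windows$start,
                      end = windows$end,
                      fst = windowed_fst(comp, windows, mode = fst_mode),
                      log2_cov_ratio = depth_log2_ratio(depth, sexes, cfg))
  cbind(track, snp_density_tracks(gm, windows, sexes, cfg))
}

#' Call candidate sex-linked regions from a windowed F_ST track
#'
#' Windows at or above the `fst_quantile` empirical quantile (linear
#' interpolation between order statistics) of the non-missing windowed
#' F_ST values are flagged; flagged windows separated by at most
#' `max_gap_windows` unflagged (or missing) windows on the same
#' chromosome are merged, and merged runs containing at least
#' `min_flagged_windows` flagged windows are reported as candidate
#' regions scored by their mean windowed F_ST.
#'
#' @param track data.frame from [build_window_track()] (needs chrom,
#'   start, end, fst).
#' @param cfg a [window_scan_config()].
#' @return Region data.frame (chrom, start, end, label =
#'   "SLR_CANDIDATE", score), disjoint and sorted; attribute
#'   `threshold` records the cutoff(s) used.
#' @export
call_slr <- function(track, cfg = window_scan_config()) {
  stopifnot(all(c("chrom", "start", "end", "fst") %in% names(track)))
  ok <- !is.na(track$fst)
  if (sum(ok) < 10)
    stop("call_slr needs at least 10 windows with defined F_ST")
  if (cfg$quantile_scope == "genome") {
    thr <- quantile(track$fst[ok], cfg$fst_quantile, names = FALSE)
    thr_by <- setNames(rep(thr, length(unique(track$chrom))),
                       unique(track$chrom))
  } else {
    thr_by <- vapply(unique(track$chrom), function(ch) {
      v <- track$fst[ok & track$chrom == ch]
      if (length(v) < 2) return(Inf)
      quantile(v, cfg$fst_quantile, names = FALSE)
    }, numeric(1))
  }
  flagged <- ok & track$fst >= thr_by[track$chrom]
  regions <- region_df()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    fl <- which(flagged[sel])
    if (!length(fl)) next
    # merge flagged windows bridged by <= max_gap_windows others
    runs <- split(fl, cumsum(c(1, diff(fl) > cfg$max_gap_windows + 1)))
    for (r in runs) {
      if (length(r) < cfg$min_flagged_windows) next
      rows <- sel[min(r):max(r)]
      regions <- rbind(regions, region_df(
        ch, track$start[sel[min(r)]], track$end[sel[max(r)]],
        "SLR_CANDIDATE", mean(track$fst[rows], na.rm = TRUE)))
    }
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  attr(regions, "threshold") <- thr_by
  regions
}
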