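#' Coverage-marker configuration
#'
#' @param min_male_depth minimum depth a male needs for a window to
#'   count him as covered.
#' @param max_female_depth maximum female depth tolerated in a
#'   male-specific window (0 = literally no female coverage).
#' @param min_male_fraction fraction of males that must be covered.
#' @param min_length minimum region length in bp (default one window).
#' @param merge_gap maximum gap in bp bridged when merging flagged
#'   windows.
#' @param hemi_log2_threshold minimum log2(M:F) coverage ratio for a
#'   window to count as hemizygous (3.0 = at least ~8-fold excess).
#' @param hemi_min_windows minimum run length, in windows, of a
#'   hemizygous region.
#' @return list of class `marker_config`.
#' @export
marker_config <- function(min_male_depth = 5, max_female_depth = 0,
                          min_male_fraction = 1.0, min_length = NULL,
                          merge_gap = NULL, hemi_log2_threshold = 3.0,
                          hemi_min_windows = 2) {
  stopifnot(min_male_depth >= 0, max_female_depth >= 0,
            min_male_fraction >= 0, min_male_fraction <= 1,
            hemi_log2_threshold >= 0, hemi_min_windows >= 1)
  structure(list(min_male_depth = min_male_depth,
                 max_female_depth = max_female_depth,
                 min_male_fraction = min_male_fraction,
                 min_length = min_length, merge_gap = merge_gap,
                 hemi_log2_threshold = hemi_log2_threshold,
                 hemi_min_windows = hemi_min_windows),
            class = "marker_config")
}

# Merge flagged windows of one grid into regions: windows separated by
# <= merge_gap bp are joined; regions shorter than min_length dropped.
merge_flagged_windows <- function(windows, flagged, label, score = NULL,
                                  merge_gap, min_length) {
  regions <- region_df()
  for (ch in unique(windows$chrom)) {
    sel <- which(windows$chrom == ch & flagged)
    if (!length(sel)) next
    sel <- sel[order(windows$start[sel])]
    gaps <- windows$start[sel][-1] - windows$end[sel][-length(sel)]
    runs <- split(sel, cumsum(c(1, gaps > merge_gap)))
    for (r in runs) {
      start <- windows$start[r[1]]
      end <- windows$end[r[length(r)]]
      if (end - start < min_length) next
      sc <- if (is.null(score)) NA_real_ else mean(score[r], na.rm = TRUE)
      regions <- rbind(regions, region_df(ch, start, end, label, sc))
    }
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Extract male-specific (Y-specific) regions from depth profiles
#'
#' Flags windows covered essentially only by male reads: every
#' female's depth at or below `max_female_depth` and at least
#' `min_male_fraction` of the males at or above `min_male_depth`.
#' Flagged windows separated by at most `merge_gap` bp are merged and
#' regions shorter than `min_length` dropped. Swapping the sex labels
#' in `sexes` turns this into a female-specific (W-direction) screen.
#'
#' @param depth a [depth_table()].
#' @param sexes a [sample_sheet()]; may cover a subset of the depth
#'   samples (e.g. females plus M2 males only), in which case only
#'   those samples are consulted.
#' @param cfg a [marker_config()].
#' @return Region data.frame (label `MALE_SPECIFIC`, score = mean male
#'   depth), disjoint and sorted.
#' @export
male_specific_regions <- function(depth, sexes, cfg = marker_config()) {
  stopifnot(inherits(depth, "depth_table"))
  grp <- split_sexes(sexes)
  fdep <- depth$depth[, depth$samples %in% grp$F, drop = FALSE]
  mdep <- depth$depth[, depth$samples %in% grp$M, drop = FALSE]
  if (!ncol(fdep) || !ncol(mdep))
    stop("sample sheet matches no depth columns for one sex")
  wsize <- max(depth$windows$end - depth$windows$start)
  min_length <- cfg$min_length %||% wsize
  merge_gap <- cfg$merge_gap %||% wsize
  f_ok <- apply(fdep, 1, function(x) all(x <= cfg$max_female_depth))
  m_frac <- rowMeans(mdep >= cfg$min_male_depth)
  flagged <- f_ok & m_frac >= cfg$min_male_fraction
  merge_flagged_windows(depth$windows, flagged, "MALE_SPECIFIC",
                        score = rowMeans(mdep), merge_gap = merge_gap,
                        min_length = min_length)
}

#' Call hemizygous regions from a log2 coverage-ratio track
#'
#' Reports runs of at least `hemi_min_windows` consecutive windows
#' whose log2(M:F) coverage ratio is at or above
#' `hemi_log2_threshold`; the default threshold of 3 requires at least
#' an ~8-fold male excess, well below the ~10-fold signature of a
#' Y-hemizygous segment at typical depth but above any diploid
#' fluctuation.
#'
#' @param track data.frame with chrom, start, end and `log2_cov_ratio`.
#' @param cfg a [marker_config()].
#' @return Region data.frame (label `HEMIZYGOUS`, score = mean log2
#'   ratio), disjoint and sorted.
#' @export
hemizygous_regions <- function(track, cfg = marker_config()) {
  stopifnot(all(c("chrom", "start", "end", "log2_cov_ratio") %in%
                  names(track)))
  wsize <- max(track$end - track$start)
  merge_gap <- cfg$merge_gap %||% wsize
  flagged <- !is.na(track$log2_cov_ratio) &
    track$log2_cov_ratio >= cfg$hemi_log2_threshold
  min_length <- cfg$hemi_min_windows * wsize
  merge_flagged_windows(track[, c("chrom", "start", "end")], flagged,
                        "HEMIZYGOUS", score = track$log2_cov_ratio,
                        merge_gap = 0, min_length = min_length)
}
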