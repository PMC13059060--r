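#' Build a tiling window grid over chromosomes
#'
#' Windows are non-overlapping, half-open \[start, end) intervals of
#' `window_size` bp tiling each chromosome; the last window of a
#' chromosome may be shorter.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window size in bp (default 50 kb).
#' @return data.frame with columns `chrom`, `start`, `end`, `index`
#'   (1-based row index on the grid).
#' @export
make_windows <- function(chrom_lengths, window_size = 50000) {
  stopifnot(window_size > 0, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)))
  parts <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  })
  w <- do.call(rbind, parts)
  w$index <- seq_len(nrow(w))
  w
}

# Map (chrom, 0-based pos) onto a window grid; NA when off-grid.
# The grid must be a tiling produced by make_windows (or validated on
# read), so a position's window is found by chromosome + floor division.
window_of <- function(windows, chrom, pos0) {
  idx <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(wch)) next
    size <- wch$end[1] - wch$start[1]
    sel <- chrom == ch
    k <- pos0[sel] %/% size + 1L
    ok <- k >= 1L & k <= nrow(wch) & pos0[sel] >= 0
    idx[sel][ok] <- wch$index[k[ok]]
  }
  idx
}

# Row-wise min/max of a genotype-code matrix ignoring NA; all-NA rows
# yield NA (callers must treat NA comparisons as FALSE).
row_code_range <- function(codes) {
  cols <- asplit(codes, 2)
  list(min = Reduce(function(a, b) pmin(a, b, na.rm = TRUE), cols),
       max = Reduce(function(a, b) pmax(a, b, na.rm = TRUE), cols))
}

# Check that a window data.frame is a sorted non-overlapping tiling per
# chromosome with one common window size (last window may be ragged).
validate_window_grid <- function(windows) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  if (any(windows$end <= windows$start)) stop("window end must exceed start")
  sizes <- integer(0)
  for (ch in unique(windows$chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    o <- order(wch$start)
    wch <- wch[o, , drop = FALSE]
    if (nrow(wch) > 1) {
      if (any(wch$start[-1] < wch$end[-nrow(wch)]))
        stop("overlapping windows on ", ch)
      if (any(wch$start[-1] != wch$end[-nrow(wch)]))
        stop("window grid has gaps on ", ch)
      sizes <- c(sizes, wch$end[-nrow(wch)] - wch$start[-nrow(wch)])
    }
    last <- nrow(wch)
    if (wch$end[last] - wch$start[last] > max(c(sizes, wch$end[last])))
      stop("ragged window larger than grid size on ", ch)
  }
  if (length(sizes) && length(unique(sizes)) > 1)
    stop("window grid mixes window sizes")
  invisible(TRUE)
}
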