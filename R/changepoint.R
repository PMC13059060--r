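#' Binary-segmentation change-points in the mean of a series
#'
#' Greedy binary segmentation for mean shifts: the cost of a segment
#' is its within-segment sum of squared deviations (the Gaussian
#' mean-change likelihood up to constants); at each step the split
#' giving the largest total cost reduction anywhere in the current
#' segmentation is applied, with ties broken by the leftmost split.
#' Stopping is either after `Q` splits (`penalty = "none"`) or when
#' the best reduction falls below beta = log(n) per change-point
#' (`penalty = "sic"`). Splits creating a segment shorter than
#' `min_segment` are never considered.
#'
#' @param series numeric vector (e.g. a windowed repeat-content or GC
#'   track).
#' @param Q maximum number of change-points.
#' @param penalty `"none"` (exactly up to `Q` splits, as long as any
#'   split reduces the cost) or `"sic"`.
#' @param min_segment minimum segment length in windows.
#' @return list of class `changepoint_result`: `breakpoints` (sorted
#'   last-index-of-segment positions, excluding n) and `segment_means`.
#' @export
binseg_mean <- function(series, Q = 5, penalty = c("none", "sic"),
                        min_segment = 2) {
  penalty <- match.arg(penalty)
  stopifnot(Q >= 0, min_segment >= 1)
  series <- as.numeric(series)
  n <- length(series)
  result <- function(bps) {
    bounds <- c(0, sort(bps), n)
    means <- vapply(seq_len(length(bounds) - 1), function(k)
      mean(series[(bounds[k] + 1):bounds[k + 1]]), numeric(1))
    structure(list(breakpoints = sort(bps), segment_means = means),
              class = "changepoint_result")
  }
  if (n < 2 * min_segment || Q == 0) return(result(integer(0)))
  csum <- cumsum(series)
  csum2 <- cumsum(series^2)
  seg_cost <- function(i, j) { # inclusive 1-based range
    s <- csum[j] - if (i > 1) csum[i - 1] else 0
    s2 <- csum2[j] - if (i > 1) csum2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # best split of segment [i, j]: returns c(gain, split last-index)
  best_split <- function(i, j) {
    lo <- i + min_segment - 1
    hi <- j - min_segment
    if (lo > hi) return(c(-Inf, NA))
    gains <- vapply(lo:hi, function(t)
      seg_cost(i, j) - seg_cost(i, t) - seg_cost(t + 1, j), numeric(1))
    k <- which.max(gains) # which.max takes the leftmost tie
    c(gains[k], (lo:hi)[k])
  }
  beta <- log(n)
  # gains below this are floating-point residue, not real splits
  tol <- 1e-10 * max(1, seg_cost(1, n))
  bps <- integer(0)
  for (step in seq_len(Q)) {
    bounds <- c(0, sort(bps), n)
    cand <- t(vapply(seq_len(length(bounds) - 1), function(k)
      best_split(bounds[k] + 1, bounds[k + 1]), numeric(2)))
    if (all(!is.finite(cand[, 1]))) break
    best <- which(cand[, 1] == max(cand[, 1], na.rm = TRUE))[1]
    gain <- cand[best, 1]
    if (gain <= tol) break
    if (penalty == "sic" && gain < beta) break
    bps <- c(bps, as.integer(cand[best, 2]))
  }
  result(bps)
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("changepoint_result: %d change-point(s); segment means %s\n",
              length(x$breakpoints),
              paste(signif(x$segment_means, 4), collapse = ", ")))
  invisible(x)
}
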