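# Local-maximum detection with topographic prominence and a minimum peak
# separation, in the spirit of MATLAB findpeaks. Used for BVP foot points
# (on the negated signal) and for phasic EDA peaks.

#' Find local peaks with prominence and distance constraints
#'
#' @param x Numeric signal.
#' @param min_dist Minimum separation between retained peaks, in samples.
#' @param min_prominence Minimum topographic prominence.
#' @return Integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_dist = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # rising then (weakly) falling; plateau peaks anchored at first sample
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))

  if (min_dist > 1) {
    ord <- order(x[cand], prom, decreasing = TRUE)
    taken <- logical(length(cand))
    accepted <- integer(0)
    for (j in ord) {
      if (taken[j]) next
      accepted <- c(accepted, cand[j])
      taken[abs(cand - cand[j]) < min_dist] <- TRUE
    }
    cand <- sort(accepted)
  }
  cand
}

peak_prominence <- function(x, p) {
  n <- length(x)
  h <- x[p]
  # left base: minimum between p and the nearest strictly higher sample
  lmin <- h
  i <- p - 1L
  while (i >= 1L && x[i] <= h) {
    if (x[i] < lmin) lmin <- x[i]
    i <- i - 1L
  }
  rmin <- h
  i <- p + 1L
  while (i <= n && x[i] <= h) {
    if (x[i] < rmin) rmin <- x[i]
    i <- i + 1L
  }
  h - max(lmin, rmin)
}
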