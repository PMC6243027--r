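#' Find rectified-signal peaks of a band-passed channel
#'
#' Local maxima of |x(t)|, strictly greater than both neighbours; for a
#' plateau of equal values that rises before and falls after, the centre
#' sample is reported.  Two rectified peaks correspond to one oscillation
#' cycle, so the detector's "eight consecutive peaks" rule matches the
#' visual "at least four consecutive oscillations" rule.
#'
#' @param x numeric vector, already band-pass filtered.
#' @param fs sampling rate in Hz.
#' @param rectify take |x| first (default TRUE).
#' @return data frame with columns `time` (s, 0-based), `amp`
#'   (microvolts) and `index` (1-based sample index), ordered in time.
#' @export
find_peaks <- function(x, fs, rectify = TRUE) {
  y <- if (rectify) abs(x) else x
  n <- length(y)
  empty <- data.frame(time = numeric(0), amp = numeric(0), index = integer(0))
  if (n < 3L) return(empty)
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  is_peak <- c(FALSE, v[2:(k - 1L)] > v[1:(k - 2L)] & v[2:(k - 1L)] > v[3:k],
               FALSE)
  j <- which(is_peak)
  idx <- (starts[j] + ends[j]) %/% 2L
  data.frame(time = (idx - 1L) / fs, amp = y[idx], index = idx)
}
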