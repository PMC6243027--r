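#' Morlet wavelet time-frequency power map
#'
#' Continuous wavelet transform of the raw (unfiltered) signal with an
#' analytic Morlet mother wavelet (omega0 = 6 cycles), computed by FFT
#' convolution per frequency on a 1 Hz grid.  The wavelet is
#' L2-normalized so that stationary noise yields frequency-flat expected
#' power, making power comparable across frequencies.
#'
#' @param x numeric vector, raw signal (microvolts).
#' @param fs sampling rate in Hz; must satisfy `fs >= 2 * max(freqs)`.
#' @param freqs frequency grid in Hz (1 Hz step; default 1--600 Hz).
#' @param omega0 mother-wavelet centre frequency in radians (cycles
#'   parameter), default 6.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `hfo_spectrum`: list with `power`
#'   (frequency x time matrix, power units), `freqs` and `times`.
#' @export
morlet_spectrum <- function(x, fs, freqs = 1:600, omega0 = 6, t0 = 0) {
  if (fs < 2 * max(freqs))
    stop("fs = ", fs, " Hz too low for the requested grid (max ",
         max(freqs), " Hz)")
  if (length(freqs) > 1L && any(diff(freqs) != 1))
    stop("frequency grid must have a 1 Hz step")
  n <- length(x)
  X <- stats::fft(x)
  w <- 2 * pi * fs * (seq_len(n) - 1L) / n      # angular frequency per bin
  w[w > pi * fs] <- w[w > pi * fs] - 2 * pi * fs
  pos <- w > 0
  pow <- matrix(0, nrow = length(freqs), ncol = n)
  norm <- pi^(-0.25)
  # Fourier factor: scale s such that the power response to a tone at
  # grid frequency f peaks exactly at f (not omega0/(2*pi*f), which
  # biases peaks low by ~1/(2*omega0^2))
  wc <- (omega0 + sqrt(2 + omega0^2)) / 2
  for (k in seq_along(freqs)) {
    s <- wc / (2 * pi * freqs[k])               # scale in seconds
    psi <- numeric(n)
    psi[pos] <- sqrt(2 * pi * s * fs) * norm * exp(-0.5 * (s * w[pos] - omega0)^2)
    W <- stats::fft(X * psi, inverse = TRUE) / n
    pow[k, ] <- Mod(W)^2
  }
  structure(list(power = pow, freqs = freqs, times = t0 + (seq_len(n) - 1L) / fs),
            class = "hfo_spectrum")
}

#' @export
print.hfo_spectrum <- function(x, ...) {
  cat(sprintf("<hfo_spectrum> %d freqs (%g-%g Hz) x %d time points\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times)))
  invisible(x)
}

#' Power spectral density slice of an event
#'
#' Extracts the spectrum column at the time nearest to the event's
#' middle time point (ties resolved to the earlier sample), or the mean
#' over the event period.
#'
#' @param map an `hfo_spectrum`.
#' @param event a one-row event (list or data frame row) with `start`
#'   and `end` in seconds, inside the map's time range.
#' @param method `"midpoint"` (default) or `"mean"` over \[start, end).
#' @return an object of class `hfo_psd`: list with `power` (per
#'   frequency) and `freqs`.
#' @export
psd_slice <- function(map, event, method = c("midpoint", "mean")) {
  method <- match.arg(method)
  mid <- (event$start + event$end) / 2
  if (mid < min(map$times) || mid > max(map$times))
    stop("event midpoint outside the spectral map time range")
  if (method == "midpoint") {
    j <- which.min(abs(map$times - mid))          # first index on ties
    p <- map$power[, j]
  } else {
    sel <- map$times >= event$start & map$times < event$end
    if (!any(sel)) sel <- which.min(abs(map$times - mid))
    p <- rowMeans(map$power[, sel, drop = FALSE])
  }
  structure(list(power = p, freqs = map$freqs), class = "hfo_psd")
}
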