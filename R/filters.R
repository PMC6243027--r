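#' HFO band definitions
#'
#' The two canonical high-frequency oscillation bands: ripples at
#' 80--200 Hz and fast ripples at 200--500 Hz.
#'
#' @param name `"ripple"`, `"fast_ripple"`, or a custom name with
#'   explicit edges.
#' @param f_low,f_high band edges in Hz (only for custom bands).
#' @return an object of class `hfo_band` with `name`, `f_low`, `f_high`.
#' @export
band_definition <- function(name = c("ripple", "fast_ripple"),
                            f_low = NULL, f_high = NULL) {
  if (is.null(f_low)) {
    name <- match.arg(name)
    edges <- switch(name, ripple = c(80, 200), fast_ripple = c(200, 500))
    f_low <- edges[1L]; f_high <- edges[2L]
  }
  if (!(f_low < f_high)) stop("band requires f_low < f_high")
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "hfo_band")
}

as_band <- function(band) {
  if (inherits(band, "hfo_band")) band else band_definition(band)
}

#' Design the zero-phase band-pass FIR filter for a band
#'
#' Windowed-sinc (Hamming) design.  The order is chosen from the
#' requested transition width (default 10 Hz): roughly 3.3 * fs / width
#' taps, giving about 53 dB stopband attenuation per pass, doubled by
#' forward-backward application.
#'
#' @param band an `hfo_band` or band name.
#' @param fs sampling rate in Hz.
#' @param transition transition width in Hz.
#' @return numeric vector of filter coefficients.
#' @export
design_fir <- function(band, fs, transition = 10) {
  band <- as_band(band)
  if (fs <= 2 * band$f_high)
    stop("fs = ", fs, " Hz too low for the ", band$name,
         " band (need > ", 2 * band$f_high, " Hz)")
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2L == 1L) n <- n + 1L
  signal::fir1(n, c(band$f_low, band$f_high) / (fs / 2), type = "pass",
               window = signal::hamming(n + 1L))
}

#' Zero-phase band-pass filter a recording or signal
#'
#' Forward-backward (zero-phase) application of the windowed-sinc FIR
#' filter.  Passband gain is within 5% of unity and the peak of an
#' in-band component is not shifted in time.
#'
#' @param x an `hfo_recording` or a numeric vector.
#' @param band an `hfo_band` or band name.
#' @param fs sampling rate in Hz (ignored for recordings).
#' @param transition transition width in Hz.
#' @return object of the same shape as `x`, filtered.
#' @export
bandpass <- function(x, band, fs = NULL, transition = 10) {
  band <- as_band(band)
  if (inherits(x, "hfo_recording")) {
    h <- design_fir(band, x$fs, transition)
    check_filter_length(ncol(x$samples), h, x$fs)
    out <- x
    for (i in seq_len(nrow(x$samples)))
      out$samples[i, ] <- signal::filtfilt(h, x$samples[i, ])
    return(out)
  }
  stopifnot(is.numeric(x), !is.null(fs))
  h <- design_fir(band, fs, transition)
  check_filter_length(length(x), h, fs)
  signal::filtfilt(h, x)
}

check_filter_length <- function(n, h, fs) {
  need <- 3L * length(h)
  if (n < need)
    stop(sprintf(
      "segment too short for zero-phase filtering: %d samples, need >= %d (%.2f s at %g Hz)",
      n, need, need / fs, fs))
  invisible(TRUE)
}

# ---- slow-wave segment selection ------------------------------------------

band_power_fft <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= f_lo & f <= f_hi])
}

#' Select slow-wave-sleep analysis epochs by delta-band dominance
#'
#' The recording is cut into fixed epochs (30 s by default); an epoch
#' qualifies when its delta-band (0.5--4 Hz) power exceeds `threshold`
#' (25%) of its total 0.5--fs/2 power, averaged across channels.
#' Qualifying epochs are taken in time order up to `target_duration`
#' (300 s).  An alternative `"quantile"` mode selects epochs whose delta
#' fraction exceeds the upper quartile of all epochs.
#'
#' @param rec an `hfo_recording`.
#' @param epoch_length epoch length in seconds.
#' @param threshold delta-power fraction an epoch must exceed.
#' @param target_duration total duration to select, seconds.
#' @param delta delta-band edges in Hz.
#' @param mode `"fraction"` (default) or `"quantile"`.
#' @return an object of class `hfo_segments`: data frame `epochs`
#'   (start, end, delta_fraction, selected) plus `selected` intervals.
#' @export
select_segments <- function(rec, epoch_length = 30, threshold = 0.25,
                            target_duration = 300, delta = c(0.5, 4),
                            mode = c("fraction", "quantile")) {
  mode <- match.arg(mode)
  n_ep <- floor(duration(rec) / epoch_length)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  spe <- round(epoch_length * rec$fs)
  frac <- vapply(seq_len(n_ep), function(e) {
    sel <- ((e - 1L) * spe + 1L):(e * spe)
    fr <- vapply(seq_len(nrow(rec$samples)), function(i) {
      x <- rec$samples[i, sel]
      tot <- band_power_fft(x, rec$fs, delta[1L], rec$fs / 2)
      if (tot == 0) return(0)
      band_power_fft(x, rec$fs, delta[1L], delta[2L]) / tot
    }, 0)
    mean(fr)
  }, 0)
  thr <- if (mode == "quantile") stats::quantile(frac, 0.75) else threshold
  sel <- frac > thr
  epochs <- data.frame(start = (seq_len(n_ep) - 1L) * epoch_length,
                       end = seq_len(n_ep) * epoch_length,
                       delta_fraction = frac, selected = sel)
  keep <- which(sel)
  if (!length(keep)) warning("no epoch exceeds the delta-power criterion")
  n_keep <- min(length(keep), floor(target_duration / epoch_length))
  chosen <- keep[seq_len(n_keep)]
  structure(list(epochs = epochs,
                 selected = epochs[chosen, c("start", "end"), drop = FALSE],
                 epoch_length = epoch_length, threshold = threshold,
                 target_duration = target_duration),
            class = "hfo_segments")
}

#' @export
print.hfo_segments <- function(x, ...) {
  cat(sprintf("<hfo_segments> %d/%d epochs selected (%.0f s of %.0f s target)\n",
              nrow(x$selected), nrow(x$epochs),
              nrow(x$selected) * x$epoch_length, x$target_duration))
  invisible(x)
}

#' Concatenate the selected epochs of a recording
#' @param rec an `hfo_recording`.
#' @param seg an `hfo_segments` from [select_segments()].
#' @return an `hfo_recording` containing only the selected samples.
#' @export
extract_segments <- function(rec, seg) {
  if (!nrow(seg$selected)) stop("no selected epochs to extract")
  idx <- unlist(lapply(seq_len(nrow(seg$selected)), function(k) {
    (round(seg$selected$start[k] * rec$fs) + 1L):round(seg$selected$end[k] * rec$fs)
  }))
  recording(rec$samples[, idx, drop = FALSE], fs = rec$fs,
            labels = rec$labels, montage = rec$montage, t0 = rec$t0)
}
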