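#' Estimate the channel baseline from maximum-distributed peak points
#'
#' Most automated detectors derive the baseline from the whole segment,
#' which fails on HFO-dense channels.  Here the baseline is anchored at
#' the *modal* rectified-peak amplitude — the amplitude around which
#' peaks are maximally distributed — which is insensitive to a minority
#' of high-amplitude events.  Peaks no larger than `mode_cutoff` times
#' the modal amplitude are declared baseline peaks; their mean and SD set
#' the detection thresholds, and maximal runs of consecutive baseline
#' peaks spanning at least 200 ms become baseline segments.  When a raw
#' signal is supplied, the per-frequency mean Morlet power over those
#' segments is computed for the false-HFO baseline-power constraint.
#'
#' @param filtered numeric vector: band-pass filtered channel.
#' @param fs sampling rate in Hz.
#' @param band an `hfo_band` or band name.
#' @param raw optional raw (unfiltered) channel of the same length, used
#'   to compute `mean_power` on `freqs`.
#' @param freqs frequency grid for `mean_power` (1 Hz step).
#' @param mode_cutoff multiple of the modal peak amplitude below which a
#'   peak counts as baseline (default 2).
#' @param segment_cutoff multiple of the modal peak amplitude above
#'   which a peak counts as high-frequency *activity* interrupting a
#'   baseline segment (default 4).  Kept looser than `mode_cutoff`: in
#'   band-limited noise roughly one peak in eight exceeds twice the
#'   mode by chance, so requiring 200 ms of exclusively sub-2x-mode
#'   peaks would leave no segments, while 4x the mode is exceeded only
#'   by genuine events.
#' @param min_segment minimum baseline-segment span in seconds (0.2).
#' @param max_power_segments cap on the number of (longest) segments
#'   used for the mean-power estimate.
#' @param channel channel label carried through to results.
#' @return an object of class `hfo_baseline`: `mean_amp`, `sd_amp`
#'   (microvolts), `segments` (data frame start/end in s), `mean_power`
#'   (per-frequency, or NULL), `freqs`, `band`, `channel`, `n_peaks`.
#' @export
estimate_baseline <- function(filtered, fs, band, raw = NULL,
                              freqs = 1:600, mode_cutoff = 2,
                              segment_cutoff = 4,
                              min_segment = 0.2, max_power_segments = 10,
                              channel = NA_character_) {
  band <- as_band(band)
  if (length(filtered) < 10 * fs)
    stop("estimate_baseline requires at least 10 s of signal")
  pk <- find_peaks(filtered, fs)
  if (nrow(pk) < 50L)
    stop("too few peaks (", nrow(pk), ") to estimate a baseline; need >= 50")
  d <- stats::density(pk$amp)
  a_mode <- d$x[which.max(d$y)]
  is_base <- pk$amp <= mode_cutoff * a_mode
  quiet <- pk$amp <= segment_cutoff * a_mode
  segs <- baseline_runs(pk, quiet, min_segment)
  if (!nrow(segs)) {
    warning("no baseline run spans ", min_segment * 1000,
            " ms; falling back to lowest-decile peaks")
    is_base <- pk$amp <= stats::quantile(pk$amp, 0.1)
    segs <- baseline_runs(pk, is_base, min_segment)
    if (!nrow(segs)) {
      r <- baseline_runs(pk, is_base, 0)
      segs <- r[which.max(r$end - r$start), , drop = FALSE]
    }
  }
  amps <- pk$amp[is_base]
  mean_power <- NULL
  if (!is.null(raw)) {
    stopifnot(length(raw) == length(filtered))
    mean_power <- segment_mean_power(raw, fs, segs, freqs, max_power_segments)
  }
  structure(list(mean_amp = mean(amps), sd_amp = stats::sd(amps),
                 segments = segs, mean_power = mean_power, freqs = freqs,
                 band = band, channel = channel, n_peaks = nrow(pk),
                 a_mode = a_mode),
            class = "hfo_baseline")
}

#' @export
print.hfo_baseline <- function(x, ...) {
  cat(sprintf(
    "<hfo_baseline> %s band: mean %.2f uV, SD %.2f uV, %d segment(s) >= 200 ms\n",
    x$band$name, x$mean_amp, x$sd_amp, nrow(x$segments)))
  invisible(x)
}

baseline_runs <- function(pk, is_base, min_segment) {
  r <- rle(is_base)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = numeric(0), end = numeric(0)))
  out <- data.frame(start = pk$time[starts[keep]], end = pk$time[ends[keep]])
  out[out$end - out$start >= min_segment, , drop = FALSE]
}

segment_mean_power <- function(raw, fs, segs, freqs, max_power_segments,
                               pad = 0.25, max_core = 1) {
  ord <- order(segs$end - segs$start, decreasing = TRUE)
  segs <- segs[utils::head(ord, max_power_segments), , drop = FALSE]
  segs$end <- pmin(segs$end, segs$start + max_core)   # cap CWT cost
  total <- numeric(length(freqs)); n_cols <- 0L
  dur <- length(raw) / fs
  for (k in seq_len(nrow(segs))) {
    a <- max(0, segs$start[k] - pad)
    b <- min(dur, segs$end[k] + pad)
    i0 <- floor(a * fs) + 1L; i1 <- min(length(raw), ceiling(b * fs))
    sp <- morlet_spectrum(raw[i0:i1], fs, freqs, t0 = (i0 - 1L) / fs)
    core <- sp$times >= segs$start[k] & sp$times <= segs$end[k]
    total <- total + rowSums(sp$power[, core, drop = FALSE])
    n_cols <- n_cols + sum(core)
  }
  total / max(n_cols, 1L)
}
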