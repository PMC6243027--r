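#' Detection parameters (consecutive-peak thresholds)
#'
#' The detector marks a candidate event wherever at least `n_low`
#' consecutive rectified peaks all exceed `mean_amp + k_low * sd_amp` of
#' the baseline and that run contains at least `n_high` consecutive
#' peaks above `mean_amp + k_high * sd_amp`.  Defaults are the values
#' optimized for SEEG electrodes: ripples 8 peaks above 3 SD with 6
#' above 10 SD; fast ripples 8 above 3 SD with 6 above 9.5 SD.
#'
#' @param band an `hfo_band` or band name; sets the band defaults.
#' @param n_low,k_low run length and SD multiplier of the low threshold.
#' @param n_high,k_high sub-run length and SD multiplier of the high
#'   threshold (`n_high <= n_low`, `k_low < k_high`).
#' @param merge_gap events closer than this gap (s) are merged (10 ms).
#' @return an object of class `hfo_params`.
#' @export
detection_params <- function(band = "ripple", n_low = 8L, k_low = 3,
                             n_high = 6L, k_high = NULL, merge_gap = 0.01) {
  band <- as_band(band)
  if (is.null(k_high))
    k_high <- switch(band$name, ripple = 10, fast_ripple = 9.5, 10)
  if (n_high > n_low) stop("n_high must be <= n_low")
  if (k_low >= k_high) stop("k_low must be < k_high")
  structure(list(band = band, n_low = as.integer(n_low), k_low = k_low,
                 n_high = as.integer(n_high), k_high = k_high,
                 merge_gap = merge_gap),
            class = "hfo_params")
}

#' @export
print.hfo_params <- function(x, ...) {
  cat(sprintf("<hfo_params> %s: %d peaks > %g SD, %d peaks > %g SD, merge %g ms\n",
              x$band$name, x$n_low, x$k_low, x$n_high, x$k_high,
              x$merge_gap * 1000))
  invisible(x)
}

empty_events <- function() {
  data.frame(channel = character(0), band = character(0),
             start = numeric(0), end = numeric(0), n_peaks = integer(0),
             peak_max = numeric(0), verdict = character(0),
             accumulated_power = numeric(0),
             peak_times = I(list()), peak_amps = I(list()))
}

#' Detect HFO events on a band-pass filtered channel
#'
#' Applies the consecutive-peak amplitude rule against the channel's
#' baseline model.  Event boundaries run from the first to the last peak
#' of the low-threshold run; events separated by less than `merge_gap`
#' are merged.
#'
#' @param filtered numeric vector, band-pass filtered channel.
#' @param fs sampling rate in Hz.
#' @param base an `hfo_baseline` for the same band.
#' @param params an `hfo_params` for the same band.
#' @param channel channel label attached to the events.
#' @return a data frame of events (possibly empty) with columns
#'   `channel, band, start, end, n_peaks, peak_max, verdict,
#'   accumulated_power` plus list-columns `peak_times`, `peak_amps`,
#'   sorted by start time.
#' @export
detect_hfos <- function(filtered, fs, base, params,
                        channel = base$channel) {
  stopifnot(inherits(base, "hfo_baseline"), inherits(params, "hfo_params"))
  if (base$band$name != params$band$name)
    stop("baseline and parameters refer to different bands")
  pk <- find_peaks(filtered, fs)
  if (!nrow(pk)) return(empty_events())
  thr_low <- base$mean_amp + params$k_low * base$sd_amp
  thr_high <- base$mean_amp + params$k_high * base$sd_amp
  lo <- pk$amp > thr_low
  r <- rle(lo)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= params$n_low)
  rows <- list()
  for (j in cand) {
    sel <- starts[j]:ends[j]
    hi <- pk$amp[sel] > thr_high
    rh <- rle(hi)
    if (!any(rh$values & rh$lengths >= params$n_high)) next
    rows[[length(rows) + 1L]] <- list(
      start = pk$time[sel[1L]], end = pk$time[sel[length(sel)]],
      peak_times = pk$time[sel], peak_amps = pk$amp[sel])
  }
  if (!length(rows)) return(empty_events())
  # merge events separated by less than merge_gap
  merged <- list(rows[[1L]])
  for (ev in rows[-1L]) {
    last <- merged[[length(merged)]]
    if (ev$start - last$end < params$merge_gap) {
      last$end <- ev$end
      last$peak_times <- c(last$peak_times, ev$peak_times)
      last$peak_amps <- c(last$peak_amps, ev$peak_amps)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- ev
  }
  out <- data.frame(
    channel = rep(channel %||% NA_character_, length(merged)),
    band = params$band$name,
    start = vapply(merged, `[[`, 0, "start"),
    end = vapply(merged, `[[`, 0, "end"),
    n_peaks = vapply(merged, function(e) length(e$peak_times), 0L),
    peak_max = vapply(merged, function(e) max(e$peak_amps), 0),
    verdict = "unclassified", accumulated_power = NA_real_)
  out$peak_times <- I(lapply(merged, `[[`, "peak_times"))
  out$peak_amps <- I(lapply(merged, `[[`, "peak_amps"))
  out[order(out$start), , drop = FALSE]
}

#' Detect HFOs across a whole recording
#'
#' Filters every channel into the requested band, estimates its baseline
#' and runs the detector.  Returns the event table plus the per-channel
#' baseline models (needed downstream by the false-HFO classifier).
#'
#' @param rec an `hfo_recording` (raw, microvolts).
#' @param band an `hfo_band` or band name.
#' @param params an `hfo_params`; defaults to the band's optimized set.
#' @param with_power also compute baseline mean Morlet power (required
#'   for false-HFO classification).
#' @param freqs frequency grid for baseline mean power.
#' @return list with `events` (data frame) and `baselines` (named list
#'   of `hfo_baseline` keyed by channel label).
#' @export
detect_recording <- function(rec, band, params = NULL, with_power = TRUE,
                             freqs = 1:600) {
  band <- as_band(band)
  if (is.null(params)) params <- detection_params(band)
  filt <- bandpass(rec, band)
  baselines <- list(); evs <- list()
  for (i in seq_len(nrow(rec$samples))) {
    lab <- rec$labels[i]
    base <- estimate_baseline(filt$samples[i, ], rec$fs, band,
                              raw = if (with_power) rec$samples[i, ],
                              freqs = freqs, channel = lab)
    baselines[[lab]] <- base
    evs[[lab]] <- detect_hfos(filt$samples[i, ], rec$fs, base, params,
                              channel = lab)
  }
  list(events = do.call(rbind, evs), baselines = baselines)
}
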