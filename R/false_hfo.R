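#' Frequency-offset parameters for false-HFO identification
#'
#' A genuine HFO raises power in its own band above the neighbouring
#' lower frequencies, while a filtering artefact (Gibbs ringing of a
#' sharp transient) inherits the transient's monotonically decreasing
#' spectrum.  The classifier sweeps the offset power difference
#' Power(f) - Power(f - df) over the event's band, with df from 1--200 Hz
#' for ripples and 200--600 Hz for fast ripples (1 Hz steps).
#'
#' @param band an `hfo_band` or band name.
#' @param f_range frequencies f swept, Hz; defaults to the event band.
#' @param df_range offsets df swept, Hz; band defaults as above.  Pass
#'   `c(1, 600)` to sweep the full published offset range for fast
#'   ripples.
#' @param f_floor minimum valid f - df in Hz; pairs reaching below are
#'   skipped.  Default 5 Hz: a 6-cycle Morlet wavelet below ~5 Hz is
#'   longer than the 1 s event analysis window, so power there is not
#'   estimable and spurious positive differences against those bins
#'   would leak through.
#' @return an object of class `hfo_offset_params`.
#' @export
offset_params <- function(band, f_range = NULL, df_range = NULL,
                          f_floor = 5) {
  band <- as_band(band)
  if (is.null(f_range)) f_range <- c(band$f_low, band$f_high)
  if (is.null(df_range))
    df_range <- switch(band$name, ripple = c(1, 200),
                       fast_ripple = c(200, 600), c(1, 600))
  if (df_range[1L] > df_range[2L] || df_range[1L] < 1)
    stop("invalid df_range")
  structure(list(band = band, f_range = f_range, df_range = df_range,
                 f_floor = f_floor, step = 1),
            class = "hfo_offset_params")
}

#' Accumulated frequency-offset power difference of a PSD slice
#'
#' For every frequency f in the event band and offset df in the offset
#' range with f - df at or above the floor, the difference
#' D(f, df) = Power(f) - Power(f - df) is computed; differences below
#' zero or below the baseline mean power at f are set to zero, and the
#' remainder is accumulated.  A result of exactly zero signals no energy
#' increase in the band — the event is a filtering artefact.
#'
#' @param slice an `hfo_psd` from [psd_slice()] (or a list with `power`
#'   and `freqs` on a 1 Hz grid).
#' @param base an `hfo_baseline` carrying `mean_power` on the same grid,
#'   or a numeric vector of per-frequency baseline mean power.
#' @param params an `hfo_offset_params`.
#' @return the accumulated power S (>= 0).
#' @export
offset_power_difference <- function(slice, base, params) {
  stopifnot(inherits(params, "hfo_offset_params"))
  freqs <- slice$freqs
  P <- slice$power
  mp <- if (inherits(base, "hfo_baseline")) base$mean_power else base
  if (is.null(mp)) stop("baseline mean power unavailable")
  if (length(mp) != length(P))
    stop("PSD slice and baseline mean power are on different grids")
  f_vals <- seq(max(params$f_range[1L], min(freqs)),
                min(params$f_range[2L], max(freqs)))
  df_vals <- seq(params$df_range[1L], params$df_range[2L])
  fi <- match(f_vals, freqs)
  if (anyNA(fi)) stop("f range not covered by the PSD grid")
  S <- 0; any_valid <- FALSE
  for (df in df_vals) {
    src <- f_vals - df
    ok <- src >= params$f_floor & src >= min(freqs)
    if (!any(ok)) next
    any_valid <- TRUE
    D <- P[fi[ok]] - P[match(src[ok], freqs)]
    D[D < 0] <- 0
    D[D < mp[fi[ok]]] <- 0
    S <- S + sum(D)
  }
  if (!any_valid)
    stop("no valid (f, df) pair: offset range ",
         params$df_range[1L], "-", params$df_range[2L],
         " Hz is incompatible with the ", params$band$name, " band")
  S
}

#' Classify one detected event as a true or false HFO
#'
#' Computes the Morlet spectrum of the raw signal in a window around the
#' event, takes the event's PSD (mean over the event period by default;
#' `"midpoint"` uses the single middle-time column), and accumulates
#' the frequency-offset power difference against the channel's baseline
#' mean power.  A zero accumulation means no energy increase in the
#' band: the event is declared a false (filtering-induced) HFO.
#'
#' @param event one-row event data frame (from [detect_hfos()]).
#' @param raw numeric vector: the raw (unfiltered) channel.
#' @param fs sampling rate in Hz.
#' @param base `hfo_baseline` with `mean_power` for this channel/band.
#' @param params an `hfo_offset_params`; defaults to the event band's.
#' @param window analysis window length around the event midpoint, s.
#' @param method PSD slice method, `"mean"` (default) or `"midpoint"`.
#' @return list with `verdict` (`"true_hfo"` or `"false_hfo"`) and
#'   `accumulated_power`.
#' @export
classify_event <- function(event, raw, fs, base, params = NULL,
                           window = 1, method = "mean") {
  if (is.null(params)) params <- offset_params(event$band)
  mid <- (event$start + event$end) / 2
  half <- window / 2
  i0 <- max(1L, floor((mid - half) * fs) + 1L)
  i1 <- min(length(raw), ceiling((mid + half) * fs))
  sp <- morlet_spectrum(raw[i0:i1], fs, base$freqs, t0 = (i0 - 1L) / fs)
  slice <- psd_slice(sp, event, method = method)
  S <- offset_power_difference(slice, base, params)
  list(verdict = if (S <= 0) "false_hfo" else "true_hfo",
       accumulated_power = S)
}

#' Remove filtering-induced false HFOs from an event table
#'
#' Classifies every detected event and partitions the table into true
#' and false events, reporting the percentage of false events per band.
#'
#' @param events event data frame from [detect_hfos()] /
#'   [detect_recording()].
#' @param rec the raw `hfo_recording` the events were detected on.
#' @param baselines named list of `hfo_baseline` keyed by channel label
#'   (with `mean_power` present), as returned by [detect_recording()].
#' @param params optional named list of `hfo_offset_params` per band.
#' @param window,method passed to [classify_event()].
#' @return list of class `hfo_classification`: `events` (all events with
#'   verdicts and accumulated power filled), `true_events`,
#'   `false_events`, and `false_fraction` (percent, named by band).
#' @export
remove_false <- function(events, rec, baselines, params = NULL,
                         window = 1, method = "mean") {
  if (!nrow(events))
    return(structure(list(events = events, true_events = events,
                          false_events = events,
                          false_fraction = numeric(0)),
                     class = "hfo_classification"))
  for (i in seq_len(nrow(events))) {
    ch <- as.character(events$channel[i])
    bd <- as.character(events$band[i])
    base <- baselines[[ch]]
    if (is.null(base)) base <- baselines[[paste(ch, bd, sep = "|")]]
    if (is.null(base)) stop("no baseline model for channel ", ch)
    p <- if (!is.null(params)) params[[bd]] else offset_params(bd)
    cl <- classify_event(events[i, , drop = FALSE],
                         rec$samples[ch, ], rec$fs, base, p,
                         window = window, method = method)
    events$verdict[i] <- cl$verdict
    events$accumulated_power[i] <- cl$accumulated_power
  }
  frac <- vapply(split(events$verdict, events$band),
                 function(v) 100 * mean(v == "false_hfo"), 0)
  structure(list(events = events,
                 true_events = events[events$verdict == "true_hfo", ,
                                      drop = FALSE],
                 false_events = events[events$verdict == "false_hfo", ,
                                       drop = FALSE],
                 false_fraction = frac),
            class = "hfo_classification")
}

#' @export
print.hfo_classification <- function(x, ...) {
  cat(sprintf("<hfo_classification> %d events: %d true, %d false\n",
              nrow(x$events), nrow(x$true_events), nrow(x$false_events)))
  for (b in names(x$false_fraction))
    cat(sprintf("  %s: %.2f%% false\n", b, x$false_fraction[[b]]))
  invisible(x)
}
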