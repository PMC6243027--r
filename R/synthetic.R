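#' Specification for a synthetic iEEG recording
#'
#' Describes a multichannel recording of 1/f background activity with
#' seeded oscillatory bursts (genuine HFOs) and sharp biphasic
#' transients (false-HFO generators after band-pass filtering), plus a
#' known ground truth.  Burst amplitudes are expressed in baseline-SD
#' units — a burst "at 12 SD" peaks at 12 times the SD of the
#' band-filtered background — so generator knobs map directly onto the
#' detector's SD-based thresholds.
#'
#' @param n_channels number of channels.
#' @param dur duration in seconds.
#' @param fs sampling rate in Hz (default 2000).
#' @param alpha 1/f^alpha background exponent (>= 0, default 1).
#' @param bg_sd broadband background SD in microvolts (default 30).
#' @param bursts data frame (channel, time, freq, n_cycles, amp_sd) or
#'   NULL.
#' @param spikes data frame (channel, time, width_ms, amp_uv) or NULL.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return an object of class `hfo_synth_spec`.
#' @export
synth_spec <- function(n_channels = 4L, dur = 60, fs = 2000,
                       alpha = 1, bg_sd = 30, bursts = NULL,
                       spikes = NULL, seed = 1L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.null(bursts)) {
    stopifnot(all(bursts$freq >= 80 & bursts$freq <= 500),
              all(bursts$time >= 0 & bursts$time < dur))
  }
  if (!is.null(spikes))
    stopifnot(all(spikes$time >= 0 & spikes$time < dur))
  structure(list(n_channels = as.integer(n_channels), dur = dur, fs = fs,
                 alpha = alpha, bg_sd = bg_sd, bursts = bursts,
                 spikes = spikes, seed = as.integer(seed)),
            class = "hfo_synth_spec")
}

#' Generate 1/f background activity
#'
#' Per-channel Gaussian noise with a power-law spectrum (power ~
#' 1/f^alpha), produced by FFT amplitude shaping of white noise and
#' rescaled to the requested broadband SD.  Fully deterministic under
#' the spec's seed.
#'
#' @param spec an `hfo_synth_spec`.
#' @return an `hfo_recording`.
#' @export
gen_background <- function(spec) {
  set.seed(spec$seed)
  n <- round(spec$dur * spec$fs)
  m <- matrix(0, nrow = spec$n_channels, ncol = n)
  f <- (seq_len(n) - 1L) * spec$fs / n
  f[f > spec$fs / 2] <- spec$fs - f[f > spec$fs / 2]   # mirror
  shape <- c(0, f[-1L]^(-spec$alpha / 2))
  for (i in seq_len(spec$n_channels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    m[i, ] <- x / stats::sd(x) * spec$bg_sd
  }
  recording(m, fs = spec$fs)
}

tukey_window <- function(n, taper = 0.25) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < taper / 2
  hi <- x > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / taper - 1)))
  w
}

#' Baseline amplitude scale of the background, per band
#'
#' Band-pass filters each channel and measures the standard deviation
#' of the filtered background signal — the band baseline SD in which
#' inserted burst amplitudes are expressed.
#'
#' @param rec an `hfo_recording` (background only).
#' @param bands character vector of band names.
#' @return nested list `stats[[channel]][[band]]` with `sig_sd`
#'   (microvolts).
#' @export
band_baseline_stats <- function(rec, bands = c("ripple", "fast_ripple")) {
  out <- list()
  for (b in bands) {
    filt <- bandpass(rec, b)
    for (i in seq_len(nrow(rec$samples))) {
      lab <- rec$labels[i]
      out[[lab]][[b]] <- list(sig_sd = stats::sd(filt$samples[i, ]))
    }
  }
  out
}

burst_band <- function(freq) if (freq <= 200) "ripple" else "fast_ripple"

#' Insert an oscillatory burst (a genuine HFO) into a recording
#'
#' Adds a Tukey-windowed (25% taper) sinusoid of `n_cycles` cycles at
#' `freq` Hz whose plateau peak amplitude is `amp_sd` times the SD of
#' the band-filtered background (the band baseline SD), so generator
#' amplitudes map directly onto the detector's SD-based thresholds.
#'
#' @param rec an `hfo_recording`.
#' @param channel channel label.
#' @param time burst onset in seconds.
#' @param freq centre frequency in Hz (< fs/2).
#' @param n_cycles number of oscillation cycles.
#' @param amp_sd amplitude in baseline-SD units.
#' @param stats optional precomputed [band_baseline_stats()] output.
#' @return list with `rec` (recording with the burst added) and
#'   `annotation` (one-row data frame: channel, band, start, end,
#'   freq, amp_sd).
#' @export
insert_burst <- function(rec, channel, time, freq, n_cycles, amp_sd,
                         stats = NULL) {
  stopifnot(freq < rec$fs / 2)
  band <- burst_band(freq)
  if (is.null(stats)) stats <- band_baseline_stats(rec, band)
  st <- stats[[channel]][[band]]
  amp <- amp_sd * st$sig_sd
  dur <- n_cycles / freq
  if (time + dur > duration(rec)) stop("burst does not fit in the recording")
  i0 <- round(time * rec$fs) + 1L
  n <- round(dur * rec$fs)
  t <- (seq_len(n) - 1L) / rec$fs
  rec$samples[channel, i0:(i0 + n - 1L)] <-
    rec$samples[channel, i0:(i0 + n - 1L)] +
    amp * tukey_window(n) * sin(2 * pi * freq * t)
  list(rec = rec,
       annotation = data.frame(channel = channel, band = band,
                               start = time, end = time + dur,
                               freq = freq, amp_sd = amp_sd))
}

#' Insert a sharp epileptiform transient (a false-HFO generator)
#'
#' Adds a spike-shaped transient with no sustained oscillation: a sharp
#' exponential cusp (apex) carrying the strong, monotonically decaying
#' low-frequency power of an interictal discharge, plus a biphasic
#' Gaussian-derivative fast component that makes the transient ring in
#' the ripple band after band-pass filtering.  The composite keeps the
#' mountain-shaped (decreasing) spectrum characteristic of filtering
#' artefacts, which is the signature the false-HFO classifier rejects —
#' a pure band-limited wiggle would instead be a genuine oscillation.
#'
#' @param rec an `hfo_recording`.
#' @param channel channel label.
#' @param time transient centre in seconds.
#' @param width_ms transient width in milliseconds; the cusp decay
#'   constant is width/2 ms and the fast-component sigma width/6 ms.
#'   The 20 ms default maximizes ripple-band ringing, the band most
#'   susceptible to the Gibbs artefact.
#' @param amp_uv apex amplitude in microvolts.
#' @param fast_frac amplitude of the fast biphasic component relative
#'   to the apex (default 0.6).
#' @return list with `rec` and `annotation` (channel, start, end,
#'   width_ms, amp_uv).
#' @export
insert_spike <- function(rec, channel, time, width_ms = 20, amp_uv = 800,
                         fast_frac = 0.6) {
  sigma <- width_ms / 1000 / 6
  tau <- width_ms / 1000 / 2
  half <- 5 * tau
  i0 <- max(1L, round((time - half) * rec$fs) + 1L)
  i1 <- min(ncol(rec$samples), round((time + half) * rec$fs) + 1L)
  t <- (seq(i0, i1) - 1L) / rec$fs - time
  s <- amp_uv * exp(-abs(t) / tau) -
    fast_frac * amp_uv * (t / sigma) * exp(0.5 - t^2 / (2 * sigma^2))
  rec$samples[channel, i0:i1] <- rec$samples[channel, i0:i1] + s
  list(rec = rec,
       annotation = data.frame(channel = channel, start = time - half,
                               end = time + half, width_ms = width_ms,
                               amp_uv = amp_uv))
}

#' Generate a synthetic recording with ground truth
#'
#' Builds the 1/f background, measures per-band baseline statistics on
#' it, then inserts every burst and spike listed in the spec.
#'
#' @param spec an `hfo_synth_spec`.
#' @return list of class `hfo_synth`: `rec` (the recording), `truth`
#'   (list with `events` and `transients` annotation tables), `spec`.
#' @export
gen_recording <- function(spec) {
  rec <- gen_background(spec)
  bands <- unique(c(
    if (!is.null(spec$bursts)) vapply(spec$bursts$freq, burst_band, ""),
    if (!is.null(spec$spikes)) c("ripple", "fast_ripple")))
  stats <- if (length(bands)) band_baseline_stats(rec, bands)
  events <- NULL; transients <- NULL
  if (!is.null(spec$bursts)) {
    for (k in seq_len(nrow(spec$bursts))) {
      b <- spec$bursts[k, ]
      r <- insert_burst(rec, as.character(b$channel), b$time, b$freq,
                        b$n_cycles, b$amp_sd, stats = stats)
      rec <- r$rec
      events <- rbind(events, r$annotation)
    }
  }
  if (!is.null(spec$spikes)) {
    for (k in seq_len(nrow(spec$spikes))) {
      s <- spec$spikes[k, ]
      r <- insert_spike(rec, as.character(s$channel), s$time, s$width_ms,
                        s$amp_uv)
      rec <- r$rec
      transients <- rbind(transients, r$annotation)
    }
  }
  structure(list(rec = rec, truth = list(events = events,
                                         transients = transients),
                 spec = spec),
            class = "hfo_synth")
}

#' Generate a synthetic surgical cohort with known outcome direction
#'
#' Emulates the structure of a resection-outcome dataset: each patient
#' has a set of channels with HFO rates above 1/min and resection flags
#' arranged so that the continuous resection ratio equals a designed
#' target — near 1 for good-outcome patients (Engel I) and near 0.1 for
#' poor-outcome patients (Engel >= II).  Patients whose designed ratio
#' reaches 0.72 are labelled good, the rest poor.
#'
#' @param n_good,n_poor patients per outcome group.
#' @param band band label attached to the rates.
#' @param n_channels_range min/max channels per patient.
#' @param seed RNG seed.
#' @return list of class `hfo_cohort`: `rates` (patient, channel, band,
#'   rate, removed) and `outcomes` (patient, engel_class, group,
#'   designed_ratio).
#' @export
gen_cohort <- function(n_good = 10L, n_poor = 10L, band = "fast_ripple",
                       n_channels_range = c(8L, 14L), seed = 1L) {
  set.seed(seed)
  rates <- NULL; outcomes <- NULL
  total <- n_good + n_poor
  for (p in seq_len(total)) {
    good <- p <= n_good
    nc <- sample(n_channels_range[1L]:n_channels_range[2L], 1L)
    if (nc < 2L) stop("each patient needs >= 2 channels")
    ch <- sprintf("P%02d-c%02d", p, seq_len(nc))
    rate <- 1 + stats::rexp(nc, rate = 1 / 3)
    target <- if (good) {
      if (stats::runif(1) < 0.5) 1 else stats::runif(1, 0.72, 1)
    } else {
      if (stats::runif(1) < 0.3) 0 else stats::runif(1, 0.02, 0.2)
    }
    k <- if (good) ceiling(target * nc) else floor(target * nc)
    ord <- order(-rate, ch)
    removed <- logical(nc)
    if (k > 0) removed[ord[seq_len(k)]] <- TRUE
    if (k < nc) {
      removed[ord[k + 1L]] <- FALSE
      if (k + 2L <= nc)
        removed[ord[(k + 2L):nc]] <- stats::runif(nc - k - 1L) < 0.5
    }
    designed <- k / nc
    engel <- if (designed >= 0.72) "I" else sample(c("II", "III", "IV"), 1L)
    rates <- rbind(rates, data.frame(patient = sprintf("P%02d", p),
                                     channel = ch, band = band,
                                     rate = rate, removed = removed))
    outcomes <- rbind(outcomes,
                      data.frame(patient = sprintf("P%02d", p),
                                 engel_class = engel,
                                 group = if (designed >= 0.72) "good" else "poor",
                                 designed_ratio = designed))
  }
  structure(list(rates = rates, outcomes = outcomes), class = "hfo_cohort")
}

#' Measured continuous resection ratios of a synthetic cohort
#'
#' Runs [rank_channels()] per patient and joins the outcome labels,
#' yielding the input table of [compare_outcomes()].
#'
#' @param cohort an `hfo_cohort` from [gen_cohort()].
#' @param ties tie-breaking mode passed to [rank_channels()].
#' @return data frame (patient, engel_class, ratio).
#' @export
cohort_ratios <- function(cohort, ties = "lexicographic") {
  out <- lapply(split(cohort$rates, cohort$rates$patient), function(d) {
    rk <- rank_channels(d[, c("channel", "band", "rate", "removed")],
                        ties = ties)
    data.frame(patient = d$patient[1L], ratio = rk$ratio)
  })
  res <- do.call(rbind, out)
  merge(res, cohort$outcomes[, c("patient", "engel_class")], by = "patient")
}

#' Standard validation conditions: 100 bursts and 100 transients
#'
#' Builds the pair of synthetic specs used to measure the package's
#' performance floors: a burst recording with 25 genuine 12-SD,
#' 8-cycle oscillations on each of four channels (two ripple channels
#' at 120/140 Hz, two fast-ripple channels at 250/300 Hz) plus one
#' insertion-free channel for false-positive checks, and a transient
#' recording with 25 sharp spikes on each of four channels.
#' Insertion times are evenly spread with a small seeded jitter so no
#' two events merge.
#'
#' @param seed integer seed controlling background noise and jitter.
#' @param dur duration per recording in seconds.
#' @param amp_sd burst amplitude in baseline-SD units.
#' @return list with elements `bursts` and `spikes`, each an
#'   `hfo_synth_spec`.
#' @export
validation_specs <- function(seed = 1L, dur = 90, amp_sd = 12) {
  seed <- as.integer(seed) %% 100000L
  set.seed(seed + 7L)
  times <- function() seq(3, dur - 3, length.out = 25) +
    stats::runif(25, -0.4, 0.4)
  bursts <- do.call(rbind, lapply(1:4, function(i) data.frame(
    channel = paste0("ch", i), time = times(),
    freq = c(120, 140, 250, 300)[i], n_cycles = 8L, amp_sd = amp_sd)))
  spikes <- do.call(rbind, lapply(1:4, function(i) data.frame(
    channel = paste0("ch", i), time = times(),
    width_ms = 20, amp_uv = 800)))
  list(bursts = synth_spec(5L, dur, bg_sd = 30, bursts = bursts,
                           seed = seed),
       spikes = synth_spec(4L, dur, bg_sd = 30, spikes = spikes,
                           seed = seed + 1000L))
}
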