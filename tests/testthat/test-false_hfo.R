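test_that("Morlet spectrum localizes tones and vanishes on silence", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  sp <- morlet_spectrum(sin(2 * pi * 120 * t), fs, freqs = 1:600)
  avg <- rowMeans(sp$power)
  expect_lte(abs(sp$freqs[which.max(avg)] - 120), 2)
  expect_true(all(morlet_spectrum(rep(0, fs), fs, 1:600)$power == 0))
  # two tones resolve into two local maxima at the FFT-verified places
  x2 <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  sp2 <- morlet_spectrum(x2, fs, 1:600)
  avg2 <- rowMeans(sp2$power)
  P_fft <- Mod(stats::fft(x2))^2
  f_fft <- (seq_along(x2) - 1) * fs / length(x2)
  half <- f_fft <= fs / 2
  tops <- sort(f_fft[half][order(-P_fft[half])][1:2])
  expect_equal(tops, c(100, 300), tolerance = 0.01)
  lo <- which.max(avg2[1:200]); hi <- 200 + which.max(avg2[201:600])
  expect_lte(abs(lo - 100), 2)
  expect_lte(abs(hi - 300), 2)
  expect_error(morlet_spectrum(rnorm(100), fs = 500, freqs = 1:600),
               "too low")
})

test_that("PSD slice takes the column nearest the event midpoint", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  burst <- exp(-((t - 0.5)^2) / (2 * 0.01^2)) * sin(2 * pi * 150 * t)
  sp <- morlet_spectrum(burst, fs, 1:600)
  sl <- psd_slice(sp, list(start = 0.45, end = 0.55))
  expect_lte(abs(which.max(sl$power) - 150), 3)
  # silence under the event -> zero slice
  z <- psd_slice(morlet_spectrum(rep(0, fs), fs, 1:600),
                 list(start = 0.4, end = 0.6))
  expect_true(all(z$power == 0))
  # a midpoint exactly between samples resolves to the earlier one:
  # times are 0, 0.1, ..., 0.9 and the event midpoint is 0.25
  sp3 <- morlet_spectrum(seq(0, 1, length.out = 10), fs = 10, freqs = 1:2)
  sl3 <- psd_slice(sp3, list(start = 0, end = 0.5))
  expect_equal(sl3$power, sp3$power[, 3L])
  expect_error(psd_slice(sp, list(start = 5, end = 6)), "outside")
})

test_that("accumulated offset power difference matches the double loop", {
  set.seed(10)
  mp <- rep(1, 600)
  p_r <- offset_params("ripple")
  # monotonically decreasing 1/f-like slice: every difference negative
  dec <- list(power = 1e4 / (1:600), freqs = 1:600)
  expect_identical(offset_power_difference(dec, mp, p_r), 0)
  # bump of height 10 at 120 Hz over a flat floor: equals brute force
  bump <- rep(5, 600); bump[115:125] <- bump[115:125] + 10
  sl <- list(power = bump, freqs = 1:600)
  S <- offset_power_difference(sl, mp, p_r)
  expect_gt(S, 0)
  expect_equal(S, oracle_offset_sum(bump, mp, 80, 200, 1, 200, 5))
  # baseline dominates: same bump under mean power 100 accumulates nothing
  expect_identical(offset_power_difference(sl, rep(100, 600), p_r), 0)
  # random slices, both bands, against the exhaustive oracle
  p_f <- offset_params("fast_ripple")
  for (k in 1:50) {
    P <- stats::rexp(600, rate = 1 / 50)
    m2 <- stats::runif(600, 0, 30)
    s2 <- list(power = P, freqs = 1:600)
    expect_equal(offset_power_difference(s2, m2, p_r),
                 oracle_offset_sum(P, m2, 80, 200, 1, 200, 5))
    expect_equal(offset_power_difference(s2, m2, p_f),
                 oracle_offset_sum(P, m2, 200, 500, 200, 600, 5))
  }
})

test_that("S scales linearly and respects the difference structure", {
  set.seed(11)
  P <- stats::rexp(600, 1 / 50)
  mp <- stats::runif(600, 0, 30)
  pr <- offset_params("ripple")
  s0 <- offset_power_difference(list(power = P, freqs = 1:600), mp, pr)
  # joint scaling is linear
  s3 <- offset_power_difference(list(power = 3 * P, freqs = 1:600),
                                3 * mp, pr)
  expect_equal(s3, 3 * s0)
  # adding a constant to both the slice and nothing else changes S only
  # through the baseline constraint; adding it to slice alone leaves
  # differences untouched
  s_shift <- offset_power_difference(list(power = P + 7, freqs = 1:600),
                                     mp, pr)
  expect_equal(s_shift, s0)
})

test_that("windowed bursts classify true, sharp transients false", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  params <- detection_params("ripple")
  # genuine oscillation: island in the time-frequency plane
  rb <- insert_burst(rec, "ch1", 15, 120, 8, 12, stats = st)
  fb <- bandpass(rb$rec$samples[1, ], "ripple", fs = q$fs)
  evb <- detect_hfos(fb, q$fs, q$base, params, channel = "ch1")
  expect_identical(nrow(evb), 1L)
  clb <- classify_event(evb[1, ], rb$rec$samples[1, ], q$fs, q$base)
  expect_identical(clb$verdict, "true_hfo")
  expect_gt(clb$accumulated_power, 0)
  # filtered sharp transient: mountain shape, no oscillation
  rs <- insert_spike(rec, "ch1", 15)
  fsig <- bandpass(rs$rec$samples[1, ], "ripple", fs = q$fs)
  evs <- detect_hfos(fsig, q$fs, q$base, params, channel = "ch1")
  expect_gte(nrow(evs), 1L)
  cls <- classify_event(evs[1, ], rs$rec$samples[1, ], q$fs, q$base)
  expect_identical(cls$verdict, "false_hfo")
  expect_identical(cls$accumulated_power, 0)
  # zero raw signal under the event: S = 0, false
  clz <- classify_event(evb[1, ], rep(0, length(q$x)), q$fs, q$base)
  expect_identical(clz$verdict, "false_hfo")
})

test_that("remove_false partitions events like a per-event loop", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  for (t0 in c(5, 10, 20)) rec <- insert_burst(rec, "ch1", t0, 120, 8, 12,
                                               stats = st)$rec
  for (t0 in c(15, 25)) rec <- insert_spike(rec, "ch1", t0)$rec
  filt <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  base <- estimate_baseline(filt, q$fs, "ripple", raw = rec$samples[1, ],
                            channel = "ch1")
  ev <- detect_hfos(filt, q$fs, base, detection_params("ripple"),
                    channel = "ch1")
  cls <- remove_false(ev, rec, list(ch1 = base))
  expect_identical(nrow(cls$true_events) + nrow(cls$false_events),
                   nrow(cls$events))
  # per-event oracle loop reproduces the partition
  for (i in seq_len(nrow(ev))) {
    ci <- classify_event(ev[i, ], rec$samples[1, ], q$fs, base)
    expect_identical(cls$events$verdict[i], ci$verdict)
  }
  expect_equal(cls$false_fraction[["ripple"]],
               100 * nrow(cls$false_events) / nrow(cls$events))
  # all-true partition gives a 0% false fraction
  cls_t <- remove_false(ev[cls$events$verdict == "true_hfo", ],
                        rec, list(ch1 = base))
  expect_equal(cls_t$false_fraction[["ripple"]], 0)
})

test_that("verdicts are deterministic for fixed inputs", {
  q <- quiet_channel()
  rec <- insert_spike(recording(q$x, q$fs), "ch1", 12)$rec
  filt <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  base <- estimate_baseline(filt, q$fs, "ripple", raw = rec$samples[1, ],
                            channel = "ch1")
  ev <- detect_hfos(filt, q$fs, base, detection_params("ripple"),
                    channel = "ch1")
  c1 <- classify_event(ev[1, ], rec$samples[1, ], q$fs, base)
  c2 <- classify_event(ev[1, ], rec$samples[1, ], q$fs, base)
  expect_identical(c1, c2)
})
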