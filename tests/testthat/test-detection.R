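test_that("rectified peak finding matches a brute-force scan", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  # 100 Hz tone: two rectified peaks per cycle
  pk <- find_peaks(sin(2 * pi * 100 * t), fs)
  expect_equal(nrow(pk), 200, tolerance = 0.01)
  expect_identical(nrow(find_peaks(rep(0, 1000), fs)), 0L)
  expect_identical(nrow(find_peaks(rep(3.2, 1000), fs)), 0L)
  # brute-force neighbour comparison on smooth random signal
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(5000), rep(1 / 20, 20), sides = 2))
  x[is.na(x)] <- 0
  pk2 <- find_peaks(x, fs)
  y <- abs(x)
  oracle <- which(vapply(2:(length(y) - 1), function(i)
    y[i] > y[i - 1] && y[i] > y[i + 1], TRUE)) + 1L
  expect_identical(pk2$index, oracle)
  expect_equal(pk2$amp, y[oracle])
  # plateau of equal samples reports its centre
  z <- c(0, 1, 5, 5, 5, 1, 0)
  expect_identical(find_peaks(z, 1)$index, 4L)
})

test_that("modal-peak baseline scales with amplitude and resists bursts", {
  q <- quiet_channel()
  base <- q$base
  expect_gt(base$mean_amp, 0)
  expect_true(all(base$segments$end - base$segments$start >= 0.2))
  # homogeneity: scaling the signal scales the model
  b2 <- estimate_baseline(2 * q$filt, q$fs, "ripple")
  expect_equal(b2$mean_amp, 2 * base$mean_amp, tolerance = 1e-6)
  expect_equal(b2$sd_amp, 2 * base$sd_amp, tolerance = 1e-6)
  # mean baseline amplitude close to the mean rectified-peak amplitude
  # of the event-free process (independent simulation oracle)
  set.seed(6)
  other <- gen_background(synth_spec(1, 30, bg_sd = 30, seed = 77))
  of <- bandpass(other$samples[1, ], "ripple", fs = 2000)
  oy <- abs(of)
  opk <- oy[which(vapply(2:(length(oy) - 1), function(i)
    oy[i] > oy[i - 1] && oy[i] > oy[i + 1], TRUE)) + 1L]
  # the modal-cutoff estimator trims the upper tail, so it sits at or
  # slightly below the raw mean peak amplitude of the process
  expect_equal(base$mean_amp, mean(opk), tolerance = 0.25)
  expect_lte(base$mean_amp, mean(opk))
  expect_error(estimate_baseline(q$filt[1:2000], q$fs, "ripple"),
               "at least 10 s")
})

test_that("baseline shifts < 10% when bursts occupy 5% of the time", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  # 10 bursts x ~0.15 s =~ 5% of 30 s, at 12 SD
  for (t0 in seq(2, 28, length.out = 10)) {
    out <- insert_burst(rec, "ch1", t0, 120, 18, 12,
                        stats = st)
    rec <- out$rec
  }
  fb <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  bb <- estimate_baseline(fb, q$fs, "ripple")
  expect_lt(abs(bb$mean_amp - q$base$mean_amp) / q$base$mean_amp, 0.10)
})

test_that("consecutive-peak detector finds seeded bursts and only them", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  params <- detection_params("ripple")
  # pure noise: nothing
  expect_identical(nrow(detect_hfos(q$filt, q$fs, q$base, params,
                                    channel = "ch1")), 0L)
  # one 12-SD burst, 8 cycles at 120 Hz -> exactly one event overlapping
  out <- insert_burst(rec, "ch1", 15, 120, 8, 12, stats = st)
  f1 <- bandpass(out$rec$samples[1, ], "ripple", fs = q$fs)
  ev <- detect_hfos(f1, q$fs, q$base, params, channel = "ch1")
  expect_identical(nrow(ev), 1L)
  expect_lt(ev$start, out$annotation$end)
  expect_gt(ev$end, out$annotation$start)
  expect_gte(ev$n_peaks, params$n_low)
  # a weak 5-cycle 4-SD burst never reaches the high threshold
  out2 <- insert_burst(recording(q$x, q$fs), "ch1", 15, 120, 5, 4,
                       stats = st)
  f2 <- bandpass(out2$rec$samples[1, ], "ripple", fs = q$fs)
  expect_identical(nrow(detect_hfos(f2, q$fs, q$base, params)), 0L)
})

test_that("detection is invariant to joint scaling and monotone in k_high", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  for (t0 in seq(3, 27, by = 3))
    rec <- insert_burst(rec, "ch1", t0, 120, 8, 10, stats = st)$rec
  filt <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  base <- estimate_baseline(filt, q$fs, "ripple")
  params <- detection_params("ripple")
  ev <- detect_hfos(filt, q$fs, base, params)
  # joint scaling of signal and baseline leaves events unchanged
  base3 <- base
  base3$mean_amp <- 3 * base$mean_amp; base3$sd_amp <- 3 * base$sd_amp
  ev3 <- detect_hfos(3 * filt, q$fs, base3, params)
  expect_equal(ev3$start, ev$start)
  expect_equal(ev3$end, ev$end)
  # raising k_high never increases the event count
  counts <- vapply(c(6, 8, 10, 12), function(k)
    nrow(detect_hfos(filt, q$fs, base,
                     detection_params("ripple", k_high = k))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("event matching agrees with exhaustive assignment", {
  a <- data.frame(start = c(1, 2, 3), end = c(1.5, 2.5, 3.5))
  expect_identical(match_events(a, a)$tp, 3L)
  b <- data.frame(start = c(10, 20), end = c(11, 21))
  m0 <- match_events(a, b)
  expect_identical(m0$tp, 0L)
  expect_identical(m0$fp, 3L)
  expect_identical(m0$fn, 2L)
  # 3 detected vs 2 visual with overlapping alternatives: enumerate all
  # one-to-one pairings and keep the one with maximal total overlap
  det <- data.frame(start = c(0.0, 0.4, 1.0), end = c(0.5, 0.9, 1.4))
  vis <- data.frame(start = c(0.3, 0.8), end = c(0.6, 1.2))
  ov <- function(i, j) max(0, min(det$end[i], vis$end[j]) -
                              max(det$start[i], vis$start[j]))
  best <- 0
  for (p in list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))) {
    tot <- ov(p[1], 1) + ov(p[2], 2)
    n <- sum(ov(p[1], 1) > 0, ov(p[2], 2) > 0)
    best <- max(best, n)
  }
  expect_identical(match_events(det, vis)$tp, as.integer(best))
})

test_that("sensitivity, specificity and Youden follow their formulas", {
  # counts reconstructed from the published false-ripple evaluation:
  # 699 visual marks, 568 detections, 537 true positives
  ev <- evaluate_detection(list(tp = 537L, fp = 31L, fn = 162L))
  expect_equal(round(100 * ev$sensitivity, 2), 76.82)
  expect_equal(round(100 * ev$specificity, 2), 94.54)
  # Youden index of the published ripple-detector operating point
  expect_equal(0.6684 + 0.7320 - 1, 0.4004, tolerance = 1e-12)
  perfect <- evaluate_detection(list(tp = 10L, fp = 0L, fn = 0L))
  expect_equal(perfect$youden, 1)
  expect_warning(und <- evaluate_detection(list(tp = 0L, fp = 2L, fn = 0L)),
                 "undefined")
  expect_true(is.nan(und$sensitivity))
})

test_that("self-evaluation of a detection gives sens = spec = 1", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  for (t0 in seq(4, 26, by = 4))
    rec <- insert_burst(rec, "ch1", t0, 130, 8, 12, stats = st)$rec
  filt <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  ev <- detect_hfos(filt, q$fs, q$base, detection_params("ripple"),
                    channel = "ch1")
  self <- evaluate_detection(match_events(ev, ev))
  expect_equal(self$sensitivity, 1)
  expect_equal(self$specificity, 1)
})

test_that("parameter traversal returns the feasible Youden optimum", {
  q <- quiet_channel()
  rec <- recording(q$x, q$fs)
  st <- band_baseline_stats(rec, "ripple")
  vis <- NULL
  for (t0 in seq(3, 27, by = 2)) {
    out <- insert_burst(rec, "ch1", t0, 120, 8, 12, stats = st)
    rec <- out$rec
    vis <- rbind(vis, out$annotation)
  }
  filt <- bandpass(rec$samples[1, ], "ripple", fs = q$fs)
  base <- estimate_baseline(filt, q$fs, "ripple", channel = "ch1")
  chs <- list(list(filtered = filt, fs = q$fs, baseline = base,
                   visual = vis))
  # single-point grid returns that point
  g1 <- data.frame(n_low = 8, n_high = 6, k_low = 3, k_high = 10)
  o1 <- optimize_parameters(chs, "ripple", g1)
  expect_identical(o1$params$n_low, 8L)
  expect_identical(o1$params$k_high, 10)
  # planted optimum: the defaults achieve sens = spec = 1 on this gold
  grid <- expand.grid(n_low = c(8, 10), n_high = 6, k_low = 3,
                      k_high = c(10, 20))
  opt <- optimize_parameters(chs, "ripple", grid)
  expect_equal(opt$evaluation$youden, 1)
  expect_gte(opt$evaluation$spec, opt$evaluation$sens)
  # brute-force re-evaluation of the whole grid (independent loop)
  for (g in seq_len(nrow(opt$table))) {
    p <- detection_params("ripple", n_low = opt$table$n_low[g],
                          k_low = opt$table$k_low[g],
                          n_high = opt$table$n_high[g],
                          k_high = opt$table$k_high[g])
    det <- detect_hfos(filt, q$fs, base, p, channel = "ch1")
    m <- match_events(det, vis)
    sens <- m$tp / (m$tp + m$fn)
    expect_equal(opt$table$sens[g], sens)
  }
})

test_that("Cohen's kappa matches its closed form and null behaviour", {
  expect_equal(cohen_kappa(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1)
  # constructed labeling with observed agreement 0.8, chance 0.5
  a <- rep(c("x", "y"), each = 10)
  b <- c(rep("x", 8), "y", "y", rep("y", 8), "x", "x")
  expect_equal(mean(a == b), 0.8)
  expect_equal(cohen_kappa(a, b), 0.6)
  # independent random labels: kappa near zero
  set.seed(8)
  r1 <- sample(c("a", "b"), 10000, replace = TRUE)
  r2 <- sample(c("a", "b"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(r1, r2)), 0.05)
  # disjoint constant labelings have zero chance-corrected agreement;
  # identical constant labelings sit on the p_e = 1 degenerate branch
  expect_equal(cohen_kappa(rep("a", 5), rep("b", 5)), 0)
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5)), 1)
})

test_that("Spearman correlation equals mid-rank Pearson on tied data", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_rank(x, x), 1)
  expect_equal(spearman_rank(x, -x), -1)
  set.seed(9)
  y <- sample(c(1, 2, 2, 3, 3, 3, 7, 8))
  expect_equal(spearman_rank(x, y),
               stats::cor(x, y, method = "spearman"))
  expect_warning(spearman_rank(rep(1, 5), 1:5), "constant")
})
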