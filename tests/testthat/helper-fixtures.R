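# Shared fixtures, generated once per session and cached.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# 1-channel pink-noise background, 30 s @ 2 kHz, with ripple-band
# filtering and a full baseline model (incl. mean Morlet power).
quiet_channel <- function() {
  memo("quiet", {
    rec <- gen_background(synth_spec(1, 30, bg_sd = 30, seed = 3))
    x <- rec$samples[1, ]
    filt <- bandpass(x, "ripple", fs = rec$fs)
    base <- estimate_baseline(filt, rec$fs, "ripple", raw = x,
                              channel = "ch1")
    list(rec = rec, x = x, filt = filt, base = base, fs = rec$fs)
  })
}

# Evenly spread insertion times with a deterministic jitter.
spread_times <- function(n, dur, margin = 3, jitter = 0.4, seed = 13) {
  set.seed(seed)
  seq(margin, dur - margin, length.out = n) + runif(n, -jitter, jitter)
}

# Event-free stretch finder: TRUE when no annotation within `gap` s.
in_quiet <- function(t, ann, gap = 5) {
  if (is.null(ann) || !nrow(ann)) return(rep(TRUE, length(t)))
  vapply(t, function(ti) all(ti < ann$start - gap | ti > ann$end + gap), TRUE)
}

# Brute-force accumulated offset power difference: plain double loop,
# independent of the vectorized implementation.
oracle_offset_sum <- function(P, mp, f_lo, f_hi, df_lo, df_hi, floor_hz) {
  S <- 0
  for (f in f_lo:f_hi) {
    for (df in df_lo:df_hi) {
      g <- f - df
      if (g < floor_hz) next
      D <- P[f] - P[g]
      if (D < 0) D <- 0
      if (D < mp[f]) D <- 0
      S <- S + D
    }
  }
  S
}

# Definitional continuous resection ratio: walk the descending order.
oracle_ratio <- function(rate, removed, channel) {
  ord <- order(-rate, as.character(channel))
  rem <- removed[ord]
  k <- 0L
  for (r in rem) {
    if (!r) break
    k <- k + 1L
  }
  k / length(rem)
}

# Exhaustive two-sided Mann-Whitney p via rank sums over all
# assignments (ties handled by mid-ranks).
oracle_mw_p <- function(x, y) {
  m <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(m)])
  idx <- utils::combn(length(pool), m)
  ws <- apply(idx, 2L, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
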