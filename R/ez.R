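#' Per-channel true-HFO rates with resection flags
#'
#' Computes events per minute for every channel/band from the true-event
#' table and drops channels at or below 1 event/min (strictly greater
#' than 1 is required for the resection-ratio analysis).
#'
#' @param true_events data frame of true events (columns `channel`,
#'   `band`).
#' @param duration_min analyzed duration in minutes.
#' @param resection_flags named logical vector (or data frame with
#'   columns `channel`, `removed`) covering every channel with events.
#' @return data frame with columns `channel`, `band`, `rate`
#'   (events/min), `removed`.
#' @export
channel_rates <- function(true_events, duration_min, resection_flags) {
  stopifnot(duration_min > 0)
  if (is.data.frame(resection_flags)) {
    flags <- resection_flags$removed
    names(flags) <- as.character(resection_flags$channel)
  } else flags <- resection_flags
  if (!nrow(true_events))
    return(data.frame(channel = character(0), band = character(0),
                      rate = numeric(0), removed = logical(0)))
  missing <- setdiff(unique(as.character(true_events$channel)), names(flags))
  if (length(missing))
    stop("no resection flag for channel(s): ", paste(missing, collapse = ", "))
  counts <- stats::aggregate(list(n = seq_len(nrow(true_events))),
                             by = list(channel = as.character(true_events$channel),
                                       band = as.character(true_events$band)),
                             FUN = length)
  counts$rate <- counts$n / duration_min
  counts <- counts[counts$rate > 1, , drop = FALSE]
  counts$removed <- as.logical(flags[counts$channel])
  rownames(counts) <- NULL
  counts[, c("channel", "band", "rate", "removed")]
}

#' Rank channels by HFO rate and compute the continuous resection ratio
#'
#' Channels are sorted in descending order of HFO rate; the ratio is the
#' number of channels continuously removed from the top of the ranking
#' (up to the first non-removed channel) divided by the total number of
#' ranked channels:
#' \deqn{ratio = \#ChannelConRem_{HFOs} / \#Channel_{HFOs}}
#'
#' @param rates data frame from [channel_rates()] for a single band
#'   (columns `channel`, `rate`, `removed`).
#' @param ties `"lexicographic"` (default, deterministic) or
#'   `"pessimistic"`, which places non-removed channels first within a
#'   rate tie to lower-bound the ratio.
#' @return object of class `hfo_ranking`: `ordered` (the ranked table),
#'   `n_channels`, `n_continuous_removed`, `first_kept_index` (rank of
#'   the first non-removed channel) and `ratio`.  An empty input yields
#'   a flagged result with `ratio = NA`.
#' @export
rank_channels <- function(rates, ties = c("lexicographic", "pessimistic")) {
  ties <- match.arg(ties)
  if (!nrow(rates)) {
    warning("no channels with rate > 1/min; ratio undefined")
    return(structure(list(ordered = rates, n_channels = 0L,
                          n_continuous_removed = NA_integer_,
                          first_kept_index = NA_integer_, ratio = NA_real_),
                     class = "hfo_ranking"))
  }
  ord <- if (ties == "lexicographic")
    order(-rates$rate, as.character(rates$channel))
  else
    order(-rates$rate, rates$removed, as.character(rates$channel))
  ordered <- rates[ord, , drop = FALSE]
  rownames(ordered) <- NULL
  kept <- which(!ordered$removed)
  first_kept <- if (length(kept)) kept[1L] else nrow(ordered) + 1L
  n_con <- first_kept - 1L
  structure(list(ordered = ordered, n_channels = nrow(ordered),
                 n_continuous_removed = n_con,
                 first_kept_index = first_kept,
                 ratio = n_con / nrow(ordered)),
            class = "hfo_ranking")
}

#' @export
print.hfo_ranking <- function(x, ...) {
  cat(sprintf(
    "<hfo_ranking> %d channel(s) > 1/min; %d continuously removed; ratio %.2f\n",
    x$n_channels, x$n_continuous_removed, x$ratio))
  invisible(x)
}

#' Delineate the epileptogenic zone from a ranking
#'
#' The EZ is the top ceiling(threshold * n) channels of the descending
#' HFO-rate ranking; a resection covers the EZ when its continuous
#' resection ratio reaches the threshold (at least 72% of channels
#' continuously removed from the top).
#'
#' @param ranking an `hfo_ranking`.
#' @param threshold fraction of top-ranked channels, default 0.72.
#' @return list with `ez_channels` (character vector), `covered`
#'   (logical: ratio >= threshold) and `threshold`.
#' @export
delineate_ez <- function(ranking, threshold = 0.72) {
  stopifnot(inherits(ranking, "hfo_ranking"))
  if (!ranking$n_channels)
    return(list(ez_channels = character(0), covered = NA, threshold = threshold))
  k <- ceiling(threshold * ranking$n_channels)
  k <- max(1L, min(k, ranking$n_channels))
  list(ez_channels = as.character(ranking$ordered$channel[seq_len(k)]),
       covered = ranking$ratio >= threshold, threshold = threshold)
}

#' Mann-Whitney U test (exact for small samples, ties allowed)
#'
#' Two-sided rank-sum test.  For combined sample sizes up to
#' `exact_max`, the permutation distribution of the U statistic is
#' enumerated exhaustively (correct in the presence of ties, where the
#' classical exact distribution does not apply); larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest combined size for exhaustive enumeration.
#' @return list with `U` (pairs where x > y, ties counted 1/2), `p`
#'   (two-sided) and `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 16L) {
  m <- length(x); n <- length(y)
  stopifnot(m > 0, n > 0)
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  U <- u_stat(x, y)
  if (m + n <= exact_max) {
    pool <- c(x, y)
    idx <- utils::combn(m + n, m)
    Us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  N <- m + n
  r <- rank(c(x, y))
  ties <- table(r)
  mu <- m * n / 2
  sigma2 <- m * n / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

engel_group <- function(engel_class) {
  cls <- as.character(engel_class)
  roman <- c(I = 1L, II = 2L, III = 3L, IV = 4L)
  num <- ifelse(cls %in% names(roman), roman[cls],
                suppressWarnings(as.integer(cls)))
  if (anyNA(num)) stop("unrecognized Engel class: ",
                       paste(cls[is.na(num)], collapse = ", "))
  ifelse(num == 1L, "good", "poor")
}

#' Compare resection ratios between surgical-outcome groups
#'
#' Splits patients into good (Engel class I) and poor (class >= II)
#' outcome groups and reports per-group median, quartile IQR, bootstrap
#' percentile 95% CI of the median (10,000 resamples) and the two-sided
#' Mann-Whitney p-value.  The lower CI bound of the good group is the
#' candidate quantitative threshold for delineating the EZ.
#'
#' @param records data frame with columns `patient`, `engel_class` and
#'   `ratio` (one band's continuous resection ratio; patients with an
#'   undefined ratio are excluded with a message).
#' @param n_boot bootstrap resamples for the median CI.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `hfo_outcome`: per-group statistics,
#'   `p_value`, and `candidate_threshold`.
#' @export
compare_outcomes <- function(records, n_boot = 10000L, seed = 1L) {
  drop <- is.na(records$ratio)
  if (any(drop)) {
    message("excluding ", sum(drop), " patient(s) with undefined ratio: ",
            paste(records$patient[drop], collapse = ", "))
    records <- records[!drop, , drop = FALSE]
  }
  grp <- engel_group(records$engel_class)
  good <- records$ratio[grp == "good"]
  poor <- records$ratio[grp == "poor"]
  if (!length(good) || !length(poor))
    stop("both outcome groups must be non-empty")
  boot_ci <- function(v) {
    if (length(v) < 2L) {
      warning("group of size < 2: CI suppressed")
      return(c(NA_real_, NA_real_))
    }
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(v, length(v), replace = TRUE)), 0)
    unname(stats::quantile(meds, c(0.025, 0.975)))
  }
  set.seed(seed)
  stats_of <- function(v) list(
    n = length(v), median = stats::median(v),
    iqr = unname(stats::quantile(v, c(0.25, 0.75))), ci = boot_ci(v))
  g <- stats_of(good); p <- stats_of(poor)
  mw <- mann_whitney(good, poor)
  structure(list(good = g, poor = p, p_value = mw$p, U = mw$U,
                 method = mw$method, candidate_threshold = g$ci[1L]),
            class = "hfo_outcome")
}

#' @export
print.hfo_outcome <- function(x, ...) {
  fmt <- function(s, nm) sprintf(
    "  %s (n=%d): median %.2f, IQR %.2f-%.2f, 95%% CI %.2f-%.2f\n",
    nm, s$n, s$median, s$iqr[1], s$iqr[2], s$ci[1], s$ci[2])
  cat("<hfo_outcome>\n", fmt(x$good, "good"), fmt(x$poor, "poor"),
      sprintf("  Mann-Whitney p = %.4g (%s)\n", x$p_value, x$method),
      sprintf("  candidate threshold (good lower CI) = %.2f\n",
              x$candidate_threshold), sep = "")
  invisible(x)
}
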