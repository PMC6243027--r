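#' Match detected events to visually marked events
#'
#' Greedy one-to-one matching by temporal overlap: all detected/visual
#' pairs with positive overlap are ranked by overlap length and assigned
#' largest first.  Unmatched detections are false positives, unmatched
#' visual marks false negatives.  Events are matched within channel and
#' band.
#'
#' @param detected,visual data frames with columns `start`, `end` (s)
#'   and optionally `channel`, `band`.
#' @return list of class `hfo_matching`: `tp`, `fp`, `fn`, `pairs`
#'   (data frame of matched index pairs with overlaps), `n_detected`,
#'   `n_visual`.
#' @export
match_events <- function(detected, visual) {
  # a field participates in the key only when both tables carry it
  has <- function(d, f) f %in% names(d) && nrow(d) > 0 && !all(is.na(d[[f]]))
  use_ch <- has(detected, "channel") && has(visual, "channel")
  use_bd <- has(detected, "band") && has(visual, "band")
  key <- function(d) {
    if (!nrow(d)) return(character(0))
    ch <- if (use_ch) as.character(d$channel) else rep("", nrow(d))
    bd <- if (use_bd) as.character(d$band) else rep("", nrow(d))
    paste(ch, bd, sep = "\r")
  }
  kd <- key(detected); kv <- key(visual)
  pairs <- list()
  if (nrow(detected) && nrow(visual)) {
    for (i in seq_len(nrow(detected))) {
      j <- which(kv == kd[i])
      if (!length(j)) next
      ov <- pmin(detected$end[i], visual$end[j]) -
        pmax(detected$start[i], visual$start[j])
      pos <- ov > 0
      if (any(pos))
        pairs[[length(pairs) + 1L]] <-
          data.frame(det = i, vis = j[pos], overlap = ov[pos])
    }
  }
  matched <- data.frame(det = integer(0), vis = integer(0),
                        overlap = numeric(0))
  if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(-cand$overlap), , drop = FALSE]
    used_d <- logical(nrow(detected)); used_v <- logical(nrow(visual))
    for (k in seq_len(nrow(cand))) {
      i <- cand$det[k]; j <- cand$vis[k]
      if (used_d[i] || used_v[j]) next
      used_d[i] <- TRUE; used_v[j] <- TRUE
      matched <- rbind(matched, cand[k, , drop = FALSE])
    }
  }
  tp <- nrow(matched)
  structure(list(tp = tp, fp = nrow(detected) - tp, fn = nrow(visual) - tp,
                 pairs = matched, n_detected = nrow(detected),
                 n_visual = nrow(visual)),
            class = "hfo_matching")
}

#' Sensitivity, specificity and Youden index of a detection
#'
#' Sensitivity = true positives / visual marks; specificity = 1 - false
#' positives / automated detections; Youden = sensitivity +
#' specificity - 1.
#'
#' @param x an `hfo_matching` from [match_events()], or a list/vector
#'   with elements `tp`, `fp`, `fn`.
#' @return list of class `hfo_evaluation` with `tp`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `youden`.  With zero visual marks the
#'   sensitivity is NaN and a warning is raised.
#' @export
evaluate_detection <- function(x) {
  tp <- x[["tp"]]; fp <- x[["fp"]]; fn <- x[["fn"]]
  if (tp + fn == 0) {
    warning("no visual marks: sensitivity undefined")
    sens <- NaN
  } else sens <- tp / (tp + fn)
  spec <- if (tp + fp == 0) NaN else 1 - fp / (tp + fp)
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 specificity = spec, youden = sens + spec - 1),
            class = "hfo_evaluation")
}

#' @export
print.hfo_evaluation <- function(x, ...) {
  cat(sprintf(
    "<hfo_evaluation> tp=%d fp=%d fn=%d | sens %.2f%%  spec %.2f%%  Youden %.4f\n",
    x$tp, x$fp, x$fn, 100 * x$sensitivity, 100 * x$specificity, x$youden))
  invisible(x)
}

#' Cohen's kappa for two event labelings
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) over two
#' equal-length categorical vectors (e.g. presence/absence of each
#' reviewer's mark on the union candidate list).  Kappa > 0.5 is the
#' concordance criterion used for visual marking.
#'
#' @param a,b equal-length vectors of categorical labels.
#' @return kappa (scalar).  When chance agreement is 1, returns 1 if the
#'   observed agreement is also 1, otherwise NaN with a warning.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- as.character(a); b <- as.character(b)
  po <- mean(a == b)
  lev <- union(a, b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), 0))
  if (1 - pe < .Machine$double.eps * 8) {
    if (po == 1) return(1)
    warning("chance agreement is 1; kappa undefined")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Spearman rank correlation of per-channel counts
#'
#' Pearson correlation of mid-ranks, as used to compare visual and
#' automated per-channel HFO counts.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return rho; NA with a warning for a constant vector.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Optimize detection parameters by traversal of the Youden index
#'
#' Exhaustively evaluates a parameter grid on gold-standard channels
#' (visually marked events, optionally negative baseline marks) and
#' returns the grid point with the highest Youden index among those with
#' specificity at least as high as sensitivity; ties are broken by higher
#' specificity, then smaller `n_low`.  If no grid point satisfies the
#' constraint, the unconstrained Youden argmax is returned with a
#' warning.
#'
#' @param channels list of gold channels, each a list with `filtered`
#'   (band-passed signal), `fs`, `baseline` (an `hfo_baseline`),
#'   `visual` (data frame of marked events with start/end) and
#'   optionally `negatives` (data frame of baseline marks).
#' @param band an `hfo_band` or band name.
#' @param grid data frame of candidate parameters with columns `n_low`,
#'   `k_low`, `n_high`, `k_high`; defaults to the traversal grid
#'   n_low 4--12, n_high 2--8, k_low {2, 2.5, 3, 3.5, 4},
#'   k_high 6--12 by 0.5 (infeasible combinations dropped).
#' @param fp_mode `"all"` counts every unmatched detection as a false
#'   positive; `"negatives"` counts only unmatched detections that
#'   overlap a negative baseline mark.
#' @param merge_gap merge gap passed to the detector.
#' @return list with `params` (an `hfo_params`), `evaluation` for the
#'   winning point, and `table` (grid with sens/spec/youden per point).
#' @export
optimize_parameters <- function(channels, band, grid = NULL,
                                fp_mode = c("all", "negatives"),
                                merge_gap = 0.01) {
  band <- as_band(band)
  fp_mode <- match.arg(fp_mode)
  if (is.null(grid))
    grid <- expand.grid(n_low = 4:12, n_high = 2:8,
                        k_low = c(2, 2.5, 3, 3.5, 4),
                        k_high = seq(6, 12, by = 0.5))
  grid <- grid[grid$n_high <= grid$n_low & grid$k_low < grid$k_high, ,
               drop = FALSE]
  if (!nrow(grid)) stop("empty parameter grid")
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- detection_params(band, n_low = grid$n_low[g], k_low = grid$k_low[g],
                          n_high = grid$n_high[g], k_high = grid$k_high[g],
                          merge_gap = merge_gap)
    tp <- fp <- fn <- 0L
    for (ch in channels) {
      det <- detect_hfos(ch$filtered, ch$fs, ch$baseline, p)
      m <- match_events(det, ch$visual)
      fp_ch <- m$fp
      if (fp_mode == "negatives" && !is.null(ch$negatives) && m$fp > 0) {
        unmatched <- setdiff(seq_len(nrow(det)), m$pairs$det)
        fp_ch <- sum(vapply(unmatched, function(i) {
          any(pmin(det$end[i], ch$negatives$end) -
                pmax(det$start[i], ch$negatives$start) > 0)
        }, TRUE))
      }
      tp <- tp + m$tp; fp <- fp + fp_ch; fn <- fn + m$fn
    }
    ev <- suppressWarnings(evaluate_detection(list(tp = tp, fp = fp, fn = fn)))
    c(sens = ev$sensitivity, spec = ev$specificity, youden = ev$youden)
  })
  tab <- cbind(grid, do.call(rbind, res))
  feasible <- which(tab$spec >= tab$sens & is.finite(tab$youden))
  pool <- if (length(feasible)) feasible else {
    warning("no grid point has specificity >= sensitivity; ",
            "returning the unconstrained Youden optimum")
    which(is.finite(tab$youden))
  }
  ord <- pool[order(-tab$youden[pool], -tab$spec[pool], tab$n_low[pool])]
  best <- ord[1L]
  list(params = detection_params(band, n_low = tab$n_low[best],
                                 k_low = tab$k_low[best],
                                 n_high = tab$n_high[best],
                                 k_high = tab$k_high[best],
                                 merge_gap = merge_gap),
       evaluation = tab[best, c("sens", "spec", "youden")],
       table = tab)
}
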