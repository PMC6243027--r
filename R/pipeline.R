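#' Default run configuration
#'
#' Bundles every tunable of the pipeline with its published default:
#' band edges, SEEG-optimized detection parameters per band, offset
#' parameters, the 0.72 resection-ratio threshold and the seeds.
#'
#' @param seed integer seed for the synthetic stage.
#' @param threshold EZ resection-ratio threshold.
#' @param synthetic list of overrides for [synth_spec()] fields.
#' @return a list of class `hfo_config`, YAML-serializable.
#' @export
run_config <- function(seed = 1L, threshold = 0.72, synthetic = list()) {
  structure(list(
    bands = list(ripple = c(80, 200), fast_ripple = c(200, 500)),
    detection = list(
      ripple = list(n_low = 8L, k_low = 3, n_high = 6L, k_high = 10),
      fast_ripple = list(n_low = 8L, k_low = 3, n_high = 6L, k_high = 9.5)),
    offset = list(ripple = list(df = c(1, 200)),
                  fast_ripple = list(df = c(200, 600))),
    merge_gap = 0.01,
    threshold = threshold,
    seed = as.integer(seed),
    synthetic = utils::modifyList(
      list(n_channels = 4L, dur = 60, fs = 2000, alpha = 1, bg_sd = 30),
      synthetic)),
    class = "hfo_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(utils::modifyList(unclass(run_config()), cfg),
            class = "hfo_config")
}

#' @rdname read_config
#' @param config an `hfo_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config, band) {
  d <- config$detection[[band]]
  detection_params(band, n_low = d$n_low, k_low = d$k_low,
                   n_high = d$n_high, k_high = d$k_high,
                   merge_gap = config$merge_gap)
}

#' Flatten an event table for delimited output
#'
#' Drops the list-columns (per-event peak times/amplitudes), keeping
#' channel, band, boundaries, peak count, maximum amplitude, verdict and
#' accumulated power.
#'
#' @param events event data frame.
#' @return plain data frame.
#' @export
events_table <- function(events) {
  keep <- setdiff(names(events), c("peak_times", "peak_amps"))
  out <- events[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline (simulate, detect, classify, rank, evaluate)
#'
#' Generates a synthetic recording from the configuration, detects HFOs
#' in both bands, removes false HFOs, computes channel rankings when
#' resection flags are supplied, evaluates detections against the
#' synthetic ground truth, and writes every stage table plus a manifest
#' into `out_dir`.  Re-running with the same configuration reproduces
#' all tables byte-identically.
#'
#' @param config an `hfo_config` (see [run_config()]).
#' @param out_dir output directory (created if missing).
#' @param resection optional data frame (channel, removed) enabling the
#'   ranking/EZ stage.
#' @param n_bursts,n_spikes how many bursts/spikes the simulated
#'   recording carries (placed deterministically from the seed).
#' @return (invisibly) a list with the stage outputs.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         resection = NULL, n_bursts = 20L, n_spikes = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- config$synthetic
  set.seed(config$seed)
  chans <- paste0("ch", seq_len(sy$n_channels))
  margin <- 2
  bursts <- data.frame(
    channel = sample(chans, n_bursts, replace = TRUE),
    time = sort(stats::runif(n_bursts, margin, sy$dur - margin)),
    freq = sample(c(120, 140, 250, 300), n_bursts, replace = TRUE),
    n_cycles = 8L, amp_sd = 12)
  spikes <- data.frame(
    channel = sample(chans, n_spikes, replace = TRUE),
    time = sort(stats::runif(n_spikes, margin, sy$dur - margin)),
    width_ms = 20, amp_uv = 25 * sy$bg_sd)
  spec <- synth_spec(n_channels = sy$n_channels, dur = sy$dur, fs = sy$fs,
                     alpha = sy$alpha, bg_sd = sy$bg_sd,
                     bursts = bursts, spikes = spikes, seed = config$seed)
  sim <- gen_recording(spec)
  write_matrix(sim$rec, file.path(out_dir, "recording.tsv"))
  write_tsv(sim$truth$events, file.path(out_dir, "truth_events.tsv"))
  write_tsv(sim$truth$transients, file.path(out_dir, "truth_transients.tsv"))

  all_events <- NULL; classified <- list(); rankings <- list()
  for (band in names(config$bands)) {
    det <- detect_recording(sim$rec, band, config_params(config, band))
    cls <- remove_false(det$events, sim$rec, det$baselines)
    classified[[band]] <- cls
    all_events <- rbind(all_events, events_table(cls$events))
  }
  write_tsv(all_events, file.path(out_dir, "events.tsv"))

  ez <- NULL
  if (!is.null(resection)) {
    true_ev <- all_events[all_events$verdict == "true_hfo", , drop = FALSE]
    rates <- channel_rates(true_ev, duration_min = sy$dur / 60, resection)
    for (band in unique(rates$band)) {
      rk <- rank_channels(rates[rates$band == band, , drop = FALSE])
      rankings[[band]] <- rk
      write_tsv(rk$ordered, file.path(out_dir, paste0("ranking_", band, ".tsv")))
    }
    if (!is.null(rankings$fast_ripple))
      ez <- delineate_ez(rankings$fast_ripple, config$threshold)
  }

  evaluation <- lapply(names(config$bands), function(band) {
    det_b <- all_events[all_events$band == band, , drop = FALSE]
    vis <- sim$truth$events
    vis_b <- if (is.null(vis)) empty_events() else
      vis[vis$band == band, , drop = FALSE]
    suppressWarnings(evaluate_detection(match_events(det_b, vis_b)))
  })
  names(evaluation) <- names(config$bands)

  manifest <- list(
    package = "hfotools",
    version = as.character(utils::packageVersion("hfotools")),
    seed = config$seed,
    config = unclass(config),
    false_fraction = lapply(classified, `[[`, "false_fraction"),
    evaluation = lapply(evaluation, function(e)
      list(tp = e$tp, fp = e$fp, fn = e$fn,
           sensitivity = e$sensitivity, specificity = e$specificity)),
    ez = if (!is.null(ez)) list(channels = ez$ez_channels,
                                covered = ez$covered,
                                threshold = ez$threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, events = all_events, classified = classified,
                 rankings = rankings, ez = ez, evaluation = evaluation,
                 manifest = manifest))
}
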