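#' Construct an iEEG recording object
#'
#' A recording holds a channel-by-time sample matrix in microvolts together
#' with its sampling rate, channel labels and montage state.  All analysis
#' functions in the package consume this container.
#'
#' @param samples numeric matrix, channels in rows, samples in columns,
#'   amplitudes in microvolts.  A vector is treated as a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @param montage `"monopolar"` or `"bipolar"`.
#' @param t0 start time of the segment in seconds (0-based).
#' @return an object of class `hfo_recording` with elements `samples`,
#'   `fs`, `labels`, `montage`, `t0`.
#' @export
recording <- function(samples, fs, labels = NULL,
                      montage = c("monopolar", "bipolar"), t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  montage <- match.arg(montage)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples))
    stop("length(labels) must equal the number of channels")
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels,
                 montage = montage, t0 = t0),
            class = "hfo_recording")
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf("<hfo_recording> %d channel(s), %.1f s @ %g Hz, %s montage\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs, x$montage))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `hfo_recording`.
#' @export
duration <- function(rec) ncol(rec$samples) / rec$fs

#' Read a recording from disk
#'
#' Supports European Data Format (EDF) and a delimited text matrix with a
#' YAML sidecar (`<path>.yaml` holding at least `fs`, optionally `unit`).
#' Samples are standardized to microvolts at read time: a file whose
#' physical dimension is millivolts is rescaled by 1000.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"matrix"`.
#' @param fs sampling rate in Hz, required for matrix input without a
#'   sidecar.
#' @return an `hfo_recording` with monopolar montage.
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix"),
                           fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  rec <- if (format == "edf") read_edf(path) else read_matrix(path, fs = fs)
  if (rec$fs < 1000)
    stop("sampling rate ", rec$fs,
         " Hz is below 1000 Hz; the fast-ripple band cannot be analyzed")
  rec
}

unit_scale <- function(unit) {
  u <- tolower(trimws(unit))
  if (u == "" || u == "uv" || u == "µv") return(1)
  switch(u,
         "mv" = 1000,
         "v"  = 1e6,
         stop("unsupported physical dimension: ", unit))
}

read_matrix <- function(path, fs = NULL) {
  sidecar <- paste0(path, ".yaml")
  unit <- "uV"
  labels <- NULL
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$fs)) fs <- meta$fs
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$labels)) labels <- meta$labels
  }
  if (is.null(fs))
    stop("sampling rate unavailable: pass `fs` or provide ", sidecar)
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(tab)) * unit_scale(unit)       # columns are channels
  recording(m, fs = fs, labels = labels %||% colnames(tab))
}

#' Write a recording as a delimited text matrix (+ YAML sidecar)
#' @param rec an `hfo_recording`.
#' @param path output path; `<path>.yaml` is written alongside.
#' @export
write_matrix <- function(rec, path) {
  tab <- as.data.frame(t(rec$samples))
  names(tab) <- rec$labels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs = rec$fs, unit = "uV", labels = rec$labels),
                   paste0(path, ".yaml"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF i/o -------------------------------------------------------
# EDF: 256-byte fixed ASCII header, 256 bytes per signal, then int16
# little-endian data records.  Continuous recordings with 1-s records.

pad <- function(x, n) formatC(as.character(x), width = -n)

#' Write a recording to an EDF file
#'
#' Minimal continuous-EDF writer (1-second data records, 16-bit samples).
#' The recording duration must be an integer number of seconds and the
#' sampling rate an integer.
#'
#' @param rec an `hfo_recording` (microvolts).
#' @param path output path.
#' @param unit physical dimension written to the header (`"uV"` or
#'   `"mV"`; samples are converted accordingly).
#' @export
write_edf <- function(rec, path, unit = "uV") {
  ns <- nrow(rec$samples)
  n  <- ncol(rec$samples)
  if (rec$fs != round(rec$fs)) stop("EDF writer requires integer fs")
  if (n %% rec$fs != 0)
    stop("EDF writer requires an integer number of seconds")
  nrec <- n / rec$fs
  x <- rec$samples / unit_scale(unit)
  pmax_ <- apply(abs(x), 1L, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- signif(pmax_ * 1.0001, 6)              # keep 8-char fields exact
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic patient", 80); wr("synthetic recording", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("", 44); wr(nrec, 8); wr("1", 8); wr(ns, 4)
  for (l in rec$labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)               # transducer
  for (i in seq_len(ns)) wr(unit, 8)
  for (i in seq_len(ns)) wr(format(-pmax_[i], scientific = FALSE), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i],  scientific = FALSE), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)               # prefilter
  for (i in seq_len(ns)) wr(rec$fs, 8)            # samples per record
  for (i in seq_len(ns)) wr("", 32)
  spr <- rec$fs
  for (r in seq_len(nrec)) {
    sel <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((x[i, sel] + pmax_[i]) / (2 * pmax_[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                           # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax  <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1L] / recdur
  out <- matrix(0, nrow = ns, ncol = nrec * spr[1L])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i])
      out[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  for (i in seq_len(ns)) out[i, ] <- out[i, ] * unit_scale(units[i])
  recording(out, fs = fs, labels = labels)
}

# ---- bipolar montage -------------------------------------------------------

#' Transform a monopolar recording to an adjacent-contact bipolar montage
#'
#' Each output channel is the difference of adjacent contacts (i minus
#' i+1) within an electrode shaft, labelled `"A1-A2"` style.  When
#' `shaft_map` is omitted, shafts are inferred from labels of the form
#' `<letters><number>` (e.g. `A1, A2, B1, ...`), ordered by contact
#' number within each shaft.
#'
#' @param rec a monopolar `hfo_recording`.
#' @param shaft_map optional named list mapping shaft name to its contact
#'   labels in anatomical order.
#' @return a bipolar `hfo_recording`.
#' @export
to_bipolar <- function(rec, shaft_map = NULL) {
  if (rec$montage != "monopolar")
    stop("to_bipolar requires a monopolar recording")
  if (is.null(shaft_map)) {
    prefix <- sub("([0-9]+)$", "", rec$labels)
    num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", rec$labels)))
    if (anyNA(num))
      stop("cannot infer shafts from labels; supply `shaft_map`")
    shaft_map <- lapply(split(seq_along(rec$labels), prefix),
                        function(i) rec$labels[i[order(num[i])]])
  }
  unknown <- setdiff(unlist(shaft_map), rec$labels)
  if (length(unknown))
    stop("shaft_map refers to unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  rows <- list(); labs <- character(0)
  for (shaft in names(shaft_map)) {
    contacts <- shaft_map[[shaft]]
    if (length(contacts) < 2L) {
      warning("shaft ", shaft, " has fewer than 2 contacts; skipped")
      next
    }
    for (k in seq_len(length(contacts) - 1L)) {
      rows[[length(rows) + 1L]] <-
        rec$samples[contacts[k], ] - rec$samples[contacts[k + 1L], ]
      labs <- c(labs, paste0(contacts[k], "-", contacts[k + 1L]))
    }
  }
  if (!length(rows)) stop("no bipolar pairs could be formed")
  recording(do.call(rbind, rows), fs = rec$fs, labels = labs,
            montage = "bipolar", t0 = rec$t0)
}
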