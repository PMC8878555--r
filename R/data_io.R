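#' Construct an EHG record
#'
#' An `ehg_record` holds one pregnancy recording: three derived bipolar
#' channels (CH1, CH2, CH3) in millivolts, the sampling rate, and gestational
#' metadata. The class label is *derived*, never stored independently: a
#' record is `preterm` if and only if delivery occurred before 37 completed
#' weeks of gestation.
#'
#' @param record_id Character identifier.
#' @param channels Named list of three equal-length numeric vectors
#'   (`CH1`, `CH2`, `CH3`), in millivolts.
#' @param fs Sampling rate in Hz (20 for TPEHG-style records).
#' @param gestation_week_recording Gestational age at recording, in weeks
#'   (fractional allowed); may be `NA`.
#' @param gestation_week_delivery Gestational age at delivery, in weeks.
#' @param prefiltered Logical: `TRUE` if the stored channels are already
#'   band-pass filtered (so the pipeline must not filter them again).
#' @return An object of class `ehg_record`.
#' @export
ehg_record <- function(record_id, channels, fs,
                       gestation_week_recording = NA_real_,
                       gestation_week_delivery,
                       prefiltered = FALSE) {
  if (!is.list(channels) || length(channels) != 3L)
    stop("channels must be a list of exactly 3 signals")
  names(channels) <- c("CH1", "CH2", "CH3")
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop("all three channels must have identical sample counts")
  if (!all(vapply(channels, function(ch) all(is.finite(ch)), logical(1))))
    stop("channel amplitudes must be finite")
  if (!(is.numeric(fs) && fs > 0)) stop("fs must be > 0")
  if (is.na(gestation_week_delivery))
    stop("metadata error: gestation_week_delivery is required to derive the label")
  structure(
    list(
      record_id = as.character(record_id),
      channels = lapply(channels, as.numeric),
      fs = fs,
      gestation_week_recording = as.numeric(gestation_week_recording),
      gestation_week_delivery = as.numeric(gestation_week_delivery),
      label = if (gestation_week_delivery < 37) "preterm" else "term",
      prefiltered = isTRUE(prefiltered)
    ),
    class = "ehg_record"
  )
}

#' @export
print.ehg_record <- function(x, ...) {
  cat(sprintf(
    "ehg_record '%s': 3 channels x %d samples @ %g Hz, delivery week %g (%s)\n",
    x$record_id, length(x$channels[[1]]), x$fs,
    x$gestation_week_delivery, x$label))
  invisible(x)
}

#' Channel-map configuration for record readers
#'
#' Selects which stored signals become CH1/CH2/CH3 and declares whether they
#' are raw (to be band-pass filtered by the pipeline, the default) or already
#' filtered. TPEHG-style WFDB records store a raw and several pre-filtered
#' variants per channel; the default map takes the first three stored signals
#' as raw CH1..CH3.
#'
#' @param indices Integer positions of the stored signals to use, in
#'   CH1, CH2, CH3 order.
#' @param prefiltered Logical; `TRUE` if the selected signals are already
#'   band-pass filtered.
#' @export
ehg_channel_map <- function(indices = 1:3, prefiltered = FALSE) {
  if (length(indices) != 3L) stop("channel_map must select exactly 3 signals")
  list(indices = as.integer(indices), prefiltered = isTRUE(prefiltered))
}

#' Read an EHG record from disk
#'
#' Reads a WFDB record (a `.hea` header with its companion signal file) or a
#' delimited-text record (CSV with one column per channel and a header row).
#' Gestational metadata is taken from WFDB header comment lines of the form
#' `# gestation_week_delivery 39.1`; when absent (always, for CSV), a sidecar
#' metadata table is consulted (see [read_metadata_table()]).
#'
#' @param path Path to a `.hea` header or a `.csv` file.
#' @param channel_map A [ehg_channel_map()] configuration.
#' @param metadata Optional data frame from [read_metadata_table()] used as
#'   fallback when the header carries no gestation metadata. If neither
#'   source provides the delivery week the call errors; a label is never
#'   silently defaulted.
#' @return An [ehg_record()].
#' @export
read_record <- function(path, channel_map = ehg_channel_map(), metadata = NULL) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot read '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "hea") {
    w <- read_wfdb(path)
    sig <- w$signals
    meta <- w$meta
    fs <- w$fs
    rid <- w$record_id
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    sig <- lapply(tab, as.numeric)
    meta <- list()
    fs <- attr(tab, "fs")
    if (is.null(fs)) fs <- 20
    rid <- tools::file_path_sans_ext(basename(path))
  }
  if (length(sig) < max(channel_map$indices))
    stop(sprintf("format error: '%s' stores %d signals but channel_map needs %d",
                 path, length(sig), max(channel_map$indices)))
  chans <- sig[channel_map$indices]

  gwr <- meta$gestation_week_recording
  gwd <- meta$gestation_week_delivery
  if (is.null(gwd) && !is.null(metadata)) {
    row <- metadata[metadata$record_id == rid, , drop = FALSE]
    if (nrow(row) == 1L) {
      gwr <- row$gestation_week_recording
      gwd <- row$gestation_week_delivery
    }
  }
  if (is.null(gwd) || is.na(gwd))
    stop(sprintf(
      "metadata error: no gestation_week_delivery for record '%s' (header or sidecar)",
      rid))
  if (is.null(gwr)) gwr <- NA_real_
  ehg_record(rid, chans, fs,
             gestation_week_recording = gwr,
             gestation_week_delivery = gwd,
             prefiltered = channel_map$prefiltered)
}

#' Write an EHG record as delimited text
#'
#' One column per channel, header row `CH1,CH2,CH3`. Metadata is *not*
#' embedded; write a sidecar table with [write_metadata_table()].
#'
#' @param record An [ehg_record()].
#' @param path Output `.csv` path.
#' @export
write_record_csv <- function(record, path) {
  df <- as.data.frame(record$channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the sidecar metadata table
#'
#' A delimited-text table with columns `record_id`,
#' `gestation_week_recording`, `gestation_week_delivery`, keyed by record id.
#'
#' @param path Path to the metadata CSV.
#' @return A data frame with the three columns.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "gestation_week_recording", "gestation_week_delivery")
  if (!all(need %in% names(tab)))
    stop("metadata table must have columns ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_metadata_table
#' @param table Data frame with the three metadata columns.
#' @export
write_metadata_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Remove filter transients from both ends of a signal
#'
#' Drops `trim_seconds` from the start and from the end. With the default
#' 180 s at 20 Hz this removes 3600 samples per side, turning a 30-min
#' record (36000 samples) into 28800 samples.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param trim_seconds Seconds to remove from each end (default 180).
#' @return The interior of `signal`.
#' @export
trim_transients <- function(signal, fs, trim_seconds = 180) {
  ntrim <- round(trim_seconds * fs)
  if (ntrim == 0L) return(signal)
  minlen <- 2 * ntrim + 1
  if (length(signal) < minlen)
    stop(sprintf(
      "length error: signal has %d samples; trimming %g s at %g Hz needs at least %d",
      length(signal), trim_seconds, fs, minlen))
  signal[(ntrim + 1):(length(signal) - ntrim)]
}

#' Cut a signal into consecutive non-overlapping windows
#'
#' Returns full windows of `window_seconds * fs` samples; a trailing partial
#' window is discarded. Windows carry their 0-based `start_index` into the
#' source signal, using half-open intervals `[start, start + len)`.
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_seconds Window length in seconds (default 60).
#' @return A list of `signal_window` objects, each with elements `samples`,
#'   `fs`, `start_index`.
#' @export
segment_windows <- function(signal, fs, window_seconds = 60) {
  wlen <- round(window_seconds * fs)
  if (length(signal) < wlen)
    stop(sprintf("length error: signal (%d samples) shorter than one window (%d)",
                 length(signal), wlen))
  nwin <- length(signal) %/% wlen
  lapply(seq_len(nwin) - 1L, function(i) {
    structure(
      list(samples = signal[(i * wlen + 1):((i + 1) * wlen)],
           fs = fs, start_index = i * wlen),
      class = "signal_window")
  })
}

#' Preprocess one channel of a record for feature extraction
#'
#' Applies the band-pass filter (unless the record is marked pre-filtered)
#' and removes the filter transients, returning the analysis-ready signal.
#'
#' @param record An [ehg_record()].
#' @param channel One of `"CH1"`, `"CH2"`, `"CH3"`.
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @param trim_seconds Transient trim, see [trim_transients()].
#' @param zero_phase Passed to [bandpass_filter()].
#' @return Numeric vector ready for [segment_windows()].
#' @export
preprocess_channel <- function(record, channel = "CH1",
                               low = 0.08, high = 4.0, order = 4L,
                               trim_seconds = 180, zero_phase = FALSE) {
  channel <- match.arg(channel, c("CH1", "CH2", "CH3"))
  x <- record$channels[[channel]]
  if (!record$prefiltered)
    x <- bandpass_filter(x, record$fs, low = low, high = high, order = order,
                         zero_phase = zero_phase)
  trim_transients(x, record$fs, trim_seconds)
}
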