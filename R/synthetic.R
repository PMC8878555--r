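#' Parameters for the synthetic EHG generator
#'
#' The generator encodes exactly the discriminative structure the analysis
#' method assumes — preterm records carry contraction bursts that are both
#' stronger and richer in higher frequencies than term records — on top of
#' 1/f background noise. It makes no claim of physiological realism beyond
#' that. Class defaults: term bursts 2.0 per 10 min, 0.05 mV, 0.2--0.6 Hz;
#' preterm bursts 3.5 per 10 min, 0.12 mV, 0.4--1.2 Hz; both ride on 0.02 mV
#' 1/f noise. Everything survives the 0.08--4 Hz band-pass.
#'
#' @param class_label `"term"` or `"preterm"`; selects the class defaults.
#' @param fs Sampling rate, Hz (default 20).
#' @param duration Record length in seconds (default 1800 = 30 min; must be
#'   at least 420 s so the 180 s trims leave one full window).
#' @param burst_rate Contractions per 10 minutes.
#' @param burst_amp Burst amplitude scale, mV.
#' @param burst_freq_band Length-2 Hz band the burst carrier is drawn from.
#' @param burst_duration_mean,burst_duration_sd Burst length, seconds.
#' @param noise_color_exponent alpha in the 1/f^alpha background.
#' @param noise_amp Background noise SD, mV.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(class_label = c("term", "preterm"),
                             fs = 20, duration = 1800,
                             burst_rate = NULL, burst_amp = NULL,
                             burst_freq_band = NULL,
                             burst_duration_mean = 45,
                             burst_duration_sd = 10,
                             noise_color_exponent = 1,
                             noise_amp = 0.02) {
  class_label <- match.arg(class_label)
  defaults <- if (class_label == "preterm")
    list(rate = 3.5, amp = 0.12, band = c(0.4, 1.2))
  else
    list(rate = 2.0, amp = 0.05, band = c(0.2, 0.6))
  p <- list(class_label = class_label, fs = fs, duration = duration,
            n_channels = 3L,
            burst_rate = burst_rate %||% defaults$rate,
            burst_amp = burst_amp %||% defaults$amp,
            burst_freq_band = burst_freq_band %||% defaults$band,
            burst_duration_mean = burst_duration_mean,
            burst_duration_sd = burst_duration_sd,
            noise_color_exponent = noise_color_exponent,
            noise_amp = noise_amp)
  if (p$duration < 2 * 180 + 60)
    stop("parameter error: duration must be >= 420 s (trims + one window)")
  if (!(p$burst_freq_band[1] > 0 && p$burst_freq_band[2] < fs / 2))
    stop("parameter error: burst_freq_band must lie within (0, fs/2)")
  if (p$burst_amp <= 0 || p$noise_amp <= 0)
    stop("parameter error: amplitudes must be > 0")
  structure(p, class = "generator_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1/f^alpha noise via FFT shaping, unit SD.
colored_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-12, seq_len(n - 1))  # DC guarded; symmetric bins share |f|
  f <- pmin(f, n - f)
  W <- W / f^(alpha / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EHG record
#'
#' Each channel is colored background noise plus Poisson-placed contraction
#' bursts: Hann-windowed sinusoidal packets whose carrier frequency is drawn
#' from the class's band and whose amplitude jitters around the class scale.
#' Burst *events* (times, durations, carriers) are shared across the three
#' channels — a contraction is visible on all electrodes — with per-channel
#' gain jitter and independent noise. Overlapping bursts are summed.
#' Delivery-week metadata is drawn consistently with the class (< 37 weeks
#' for preterm). Bit-for-bit reproducible from `seed`.
#'
#' @param class_label `"term"` or `"preterm"`.
#' @param params A [generator_params()]; defaults to the class defaults.
#' @param record_id Identifier for the record.
#' @param seed Integer seed.
#' @return An [ehg_record()].
#' @export
generate_record <- function(class_label = c("term", "preterm"),
                            params = generator_params(class_label),
                            record_id = "synth", seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(params$class_label == class_label)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  n <- round(params$duration * params$fs)
  t_all <- seq_len(n) / params$fs

  n_bursts <- stats::rpois(1, params$burst_rate * params$duration / 600)
  bursts <- lapply(seq_len(n_bursts), function(b) {
    list(center = stats::runif(1, 0, params$duration),
         dur = max(10, stats::rnorm(1, params$burst_duration_mean,
                                    params$burst_duration_sd)),
         freq = stats::runif(1, params$burst_freq_band[1],
                             params$burst_freq_band[2]),
         phase = stats::runif(1, 0, 2 * pi),
         amp = params$burst_amp * stats::runif(1, 0.8, 1.25))
  })

  channels <- lapply(seq_len(params$n_channels), function(ch) {
    x <- params$noise_amp * colored_noise(n, params$noise_color_exponent)
    gain <- stats::runif(1, 0.8, 1.2)
    for (b in bursts) {
      i0 <- max(1L, ceiling((b$center - b$dur / 2) * params$fs))
      i1 <- min(n, floor((b$center + b$dur / 2) * params$fs))
      if (i1 <= i0) next
      idx <- i0:i1
      hann <- 0.5 - 0.5 * cos(2 * pi * (idx - i0) / (i1 - i0))
      x[idx] <- x[idx] +
        gain * b$amp * hann * sin(2 * pi * b$freq * t_all[idx] + b$phase)
    }
    x
  })

  gwd <- if (class_label == "preterm") stats::runif(1, 29, 36.5)
         else stats::runif(1, 38, 41.5)
  gwr <- stats::runif(1, 22, 33)
  ehg_record(record_id, channels, params$fs,
             gestation_week_recording = round(gwr, 1),
             gestation_week_delivery = round(gwd, 1))
}

record_seed <- function(master_seed, i) {
  (as.numeric(master_seed) * 10007 + 7919 * i) %% 2147483647
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_term + n_preterm` records with per-record seeds derived
#' deterministically from `seed`. Defaults mirror the 262:38 term:preterm
#' imbalance of the reference database. Records can be returned in memory
#' or written to `dir` as WFDB or CSV files with a sidecar metadata table
#' (`metadata.csv`).
#'
#' @param n_term,n_preterm Class counts (defaults 262 and 38).
#' @param params_term,params_preterm [generator_params()] for each class.
#' @param seed Master seed.
#' @param dir Output directory; `NULL` (default) keeps records in memory.
#' @param format `"wfdb"` or `"csv"` when writing.
#' @return List with `records` (list of [ehg_record()], in memory mode),
#'   `metadata` (data frame), and `paths` (written files, if any).
#' @export
generate_dataset <- function(n_term = 262L, n_preterm = 38L,
                             params_term = generator_params("term"),
                             params_preterm = generator_params("preterm"),
                             seed = 1L, dir = NULL,
                             format = c("wfdb", "csv")) {
  format <- match.arg(format)
  if (n_term < 1 || n_preterm < 1) stop("counts must be >= 1")
  specs <- data.frame(
    record_id = sprintf("synth%03d", seq_len(n_term + n_preterm)),
    class_label = c(rep("term", n_term), rep("preterm", n_preterm)))
  records <- vector("list", nrow(specs))
  meta <- specs["record_id"]
  meta$gestation_week_recording <- NA_real_
  meta$gestation_week_delivery <- NA_real_
  for (i in seq_len(nrow(specs))) {
    cl <- specs$class_label[i]
    rec <- generate_record(cl,
                           params = if (cl == "term") params_term else params_preterm,
                           record_id = specs$record_id[i],
                           seed = record_seed(seed, i))
    records[[i]] <- rec
    meta$gestation_week_recording[i] <- rec$gestation_week_recording
    meta$gestation_week_delivery[i] <- rec$gestation_week_delivery
  }
  paths <- character(0)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (rec in records) {
      paths <- c(paths, if (format == "wfdb") write_wfdb(rec, dir)
                 else write_record_csv(rec, file.path(dir, paste0(rec$record_id, ".csv"))))
    }
    write_metadata_table(meta, file.path(dir, "metadata.csv"))
  }
  list(records = records, metadata = meta, paths = paths)
}
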