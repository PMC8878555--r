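#' Minimal WFDB format-16 record I/O
#'
#' Reads and writes the subset of the WFDB standard used by TPEHG-style
#' records: one `.hea` header plus one interleaved 16-bit little-endian
#' `.dat` signal file shared by all signals. Gestational metadata travels in
#' `#` comment lines (`# gestation_week_delivery 39.1`). Digital-to-physical
#' conversion is `(adu - baseline) / gain` with gain in adu/mV; 16-bit
#' resolution over \eqn{\pm}2.5 mV corresponds to gain 13107.2 adu/mV.
#'
#' @param hea_path Path to the `.hea` header file.
#' @return For `read_wfdb`: a list with `record_id`, `fs`, `signals` (list of
#'   numeric vectors in mV, named by their header descriptions when present)
#'   and `meta` (named list parsed from comment lines).
#' @name wfdb
NULL

parse_gain <- function(tok) {
  # gain token may look like "13107.2", "13107.2(0)", or "13107.2(0)/mV"
  tok <- sub("/.*$", "", tok)
  base <- 0
  if (grepl("\\(", tok)) {
    base <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", tok))
    tok <- sub("\\(.*$", "", tok)
  }
  g <- as.numeric(tok)
  if (!is.finite(g) || g == 0) g <- 200 # WFDB default gain
  c(gain = g, baseline = base)
}

#' @rdname wfdb
#' @export
read_wfdb <- function(hea_path) {
  if (!file.exists(hea_path))
    stop(sprintf("I/O error: cannot read '%s'", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- grep("^\\s*#", lines, value = TRUE)
  lines <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  record_id <- hdr[1]
  nsig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(hdr[3]) else 250
  nsamp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  if (length(lines) < 1 + nsig)
    stop(sprintf("format error: header '%s' declares %d signals but lists %d",
                 hea_path, nsig, length(lines) - 1L))

  spec <- lapply(lines[2:(1 + nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat_file <- vapply(spec, `[`, character(1), 1)
  if (length(unique(dat_file)) != 1L)
    stop("format error: only single-.dat records are supported")
  fmt <- vapply(spec, `[`, character(1), 2)
  if (!all(sub("x.*$", "", fmt) == "16"))
    stop("format error: only WFDB format 16 is supported")
  gb <- t(vapply(spec, function(s) parse_gain(if (length(s) >= 3) s[3] else "200"),
                 numeric(2)))
  desc <- vapply(spec, function(s) {
    if (length(s) >= 9) paste(s[9:length(s)], collapse = " ") else ""
  }, character(1))

  dat_path <- file.path(dirname(hea_path), dat_file[1])
  if (!file.exists(dat_path))
    stop(sprintf("I/O error: signal file '%s' missing", dat_path))
  raw <- readBin(dat_path, "integer", n = file.size(dat_path) / 2,
                 size = 2, signed = TRUE, endian = "little")
  if (length(raw) %% nsig != 0)
    stop("format error: .dat length is not a multiple of the signal count")
  m <- matrix(raw, nrow = nsig)
  if (!is.na(nsamp) && ncol(m) != nsamp)
    stop(sprintf("format error: header declares %d samples, .dat holds %d",
                 nsamp, ncol(m)))
  signals <- lapply(seq_len(nsig), function(i) (m[i, ] - gb[i, 2]) / gb[i, 1])
  names(signals) <- ifelse(nzchar(desc), desc, paste0("sig", seq_len(nsig)))

  meta <- list()
  for (cm in comments) {
    toks <- strsplit(trimws(sub("^\\s*#\\s*", "", cm)), "\\s+")[[1]]
    if (length(toks) == 2 && !is.na(suppressWarnings(as.numeric(toks[2]))))
      meta[[toks[1]]] <- as.numeric(toks[2])
  }
  list(record_id = record_id, fs = fs, signals = signals, meta = meta)
}

wfdb_checksum <- function(adu) {
  s <- sum(as.numeric(adu)) %% 65536
  if (s >= 32768) s <- s - 65536
  as.integer(s)
}

#' @rdname wfdb
#' @param record An [ehg_record()] to write.
#' @param dir Output directory (created if needed).
#' @param gain adu/mV conversion gain; the default 13107.2 mirrors 16-bit
#'   resolution over \eqn{\pm}2.5 mV.
#' @return For `write_wfdb`: the header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 13107.2) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rid <- record$record_id
  nsamp <- length(record$channels[[1]])
  adu <- lapply(record$channels, function(x) {
    v <- round(x * gain)
    as.integer(pmin(pmax(v, -32768), 32767))
  })
  m <- do.call(rbind, adu)
  dat_name <- paste0(rid, ".dat")
  writeBin(as.integer(m), file.path(dir, dat_name), size = 2, endian = "little")

  sig_lines <- vapply(seq_along(adu), function(i) {
    sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 CH%d",
            dat_name, gain, adu[[i]][1], wfdb_checksum(adu[[i]]), i)
  }, character(1))
  meta_lines <- c(
    sprintf("# gestation_week_recording %g", record$gestation_week_recording),
    sprintf("# gestation_week_delivery %g", record$gestation_week_delivery))
  meta_lines <- meta_lines[!grepl("NA$", meta_lines)]
  hea_path <- file.path(dir, paste0(rid, ".hea"))
  writeLines(c(sprintf("%s 3 %g %d", rid, record$fs, nsamp),
               sig_lines, meta_lines), hea_path)
  invisible(hea_path)
}
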