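#' Root mean square of a window
#'
#' \eqn{RMS = \sqrt{\frac{1}{N}\sum_n x(n)^2}}. Higher-amplitude uterine
#' contractions raise the RMS of the high-frequency IMFs.
#'
#' @param window Numeric vector, non-empty and finite.
#' @return Non-negative scalar.
#' @export
rms <- function(window) {
  if (length(window) == 0) stop("length error: empty window")
  sqrt(mean(window^2))
}

# Names of the 6 per-channel features, frozen so saved matrices are stable.
feature_names <- function() {
  c("RMS_IMF1", "RMS_IMF2", "SampEn_IMF1", "SampEn_IMF2",
    "MTKE_IMF1", "MTKE_IMF2")
}

#' Sample entropy
#'
#' \eqn{SampEn(m, r, n) = -\ln(A/B)} where `B` counts pairs of length-`m`
#' templates and `A` pairs of length-`m+1` templates agreeing within
#' tolerance under the Chebyshev (max-norm) distance, self-matches excluded.
#' Template starts are restricted to `1..n-m` so every counted template has
#' an `m+1`-length extension. With the default `r_mode = "sd"` the tolerance
#' is \code{r * sd(window)} (the convention of the entropy literature for
#' physiological series), which makes SampEn exactly scale-invariant; an
#' absolute tolerance in signal units is available with `r_mode =
#' "absolute"`.
#'
#' When no template pair matches (`A == 0` or `B == 0`) the entropy is
#' undefined; a condition of class `sampen_undefined` carrying the partial
#' counts is signalled so the caller can drop the window rather than invent
#' a value. A zero-variance window under SD-relative tolerance returns 0
#' (all templates match).
#'
#' @param window Numeric vector, length > m + 1.
#' @param m Embedding dimension (default 3).
#' @param r Tolerance factor (default 0.15).
#' @param r_mode `"sd"` (tolerance \code{r * sd(window)}) or `"absolute"`.
#' @return Non-negative scalar, or a `sampen_undefined` error condition.
#' @export
sample_entropy <- function(window, m = 3L, r = 0.15, r_mode = c("sd", "absolute")) {
  r_mode <- match.arg(r_mode)
  n <- length(window)
  if (n <= m + 1) stop("length error: window must have more than m + 1 samples")
  tol <- if (r_mode == "sd") {
    s <- stats::sd(window)
    if (s == 0) return(0)
    r * s
  } else r
  cnt <- .sampen_counts_cpp(as.numeric(window), as.integer(m), tol)
  A <- cnt[1]; B <- cnt[2]
  if (A == 0 || B == 0)
    stop(structure(
      class = c("sampen_undefined", "error", "condition"),
      list(message = sprintf("sample entropy undefined (A=%g, B=%g)", A, B),
           call = NULL, A = A, B = B)))
  -log(A / B)
}

#' Mean Teager--Kaiser energy
#'
#' Mean over the interior samples of the discrete Teager--Kaiser operator
#' \eqn{x(n)^2 - x(n-1)\,x(n+1)}, which tracks instantaneous energy as a
#' joint function of amplitude and frequency — for a sampled sinusoid
#' \eqn{A\sin(\omega n)} it is the constant \eqn{A^2 \sin^2 \omega}.
#'
#' @param window Numeric vector, length >= 3.
#' @return Scalar (can be negative for broadband noise windows).
#' @export
mtke <- function(window) {
  n <- length(window)
  if (n < 3) stop("length error: window must have at least 3 samples")
  mean(window[2:(n - 1)]^2 - window[1:(n - 2)] * window[3:n])
}

window_features <- function(w, emd_config, sampen_m, sampen_r, sampen_r_mode) {
  dec <- do.call(decompose, c(list(signal = w, n_imfs = 2L), emd_config))
  if (dec$n_imfs < 2L) return(NULL)
  vals <- numeric(6)
  for (i in 1:2) {
    imf <- dec$imfs[[i]]
    vals[i] <- rms(imf)
    se <- tryCatch(
      sample_entropy(imf, m = sampen_m, r = sampen_r, r_mode = sampen_r_mode),
      sampen_undefined = function(e) NA_real_)
    if (is.na(se)) return(NULL)
    vals[2 + i] <- se
    vals[4 + i] <- mtke(imf)
  }
  vals
}

#' Extract the 6-feature vector for one record and channel
#'
#' Preprocesses the selected channel (band-pass + transient trim, unless the
#' record is marked pre-filtered), cuts it into non-overlapping windows,
#' decomposes each window into two IMFs, computes RMS, sample entropy and
#' mean Teager--Kaiser energy on each IMF, and averages each of the 6
#' per-window values over all usable windows. Windows whose decomposition
#' yields fewer than two IMFs, or whose sample entropy is undefined, are
#' skipped and counted in `n_windows_skipped`.
#'
#' @param record An [ehg_record()].
#' @param channel `"CH1"`, `"CH2"` or `"CH3"`.
#' @param emd_config Named list of overrides for [decompose()]
#'   (`sd_threshold`, `criterion`, `spline_method`, `max_iterations`).
#' @param window_seconds Window length (default 60).
#' @param sampen_m,sampen_r,sampen_r_mode Sample-entropy parameters
#'   (defaults m = 3, r = 0.15, SD-relative).
#' @param low,high,order,trim_seconds Preprocessing, see
#'   [preprocess_channel()].
#' @return An object of class `feature_vector`: list with `record_id`,
#'   `channel`, `label`, `values` (named length-6 numeric in the frozen
#'   order RMS_IMF1, RMS_IMF2, SampEn_IMF1, SampEn_IMF2, MTKE_IMF1,
#'   MTKE_IMF2), `n_windows_averaged`, `n_windows_skipped`.
#' @export
extract_record_features <- function(record, channel = "CH1",
                                    emd_config = list(),
                                    window_seconds = 60,
                                    sampen_m = 3L, sampen_r = 0.15,
                                    sampen_r_mode = "sd",
                                    low = 0.08, high = 4.0, order = 4L,
                                    trim_seconds = 180) {
  x <- preprocess_channel(record, channel, low = low, high = high,
                          order = order, trim_seconds = trim_seconds)
  wins <- segment_windows(x, record$fs, window_seconds)
  acc <- matrix(NA_real_, nrow = length(wins), ncol = 6)
  for (i in seq_along(wins)) {
    v <- window_features(wins[[i]]$samples, emd_config,
                         sampen_m, sampen_r, sampen_r_mode)
    if (!is.null(v)) acc[i, ] <- v
  }
  ok <- stats::complete.cases(acc)
  if (!any(ok))
    stop(sprintf(
      "feature error: record '%s' channel %s has no usable windows (%d skipped)",
      record$record_id, channel, length(wins)))
  structure(
    list(record_id = record$record_id, channel = channel, label = record$label,
         values = stats::setNames(colMeans(acc[ok, , drop = FALSE]),
                                  feature_names()),
         n_windows_averaged = sum(ok),
         n_windows_skipped = sum(!ok)),
    class = "feature_vector")
}

#' Assemble a feature matrix from many records
#'
#' Runs [extract_record_features()] over a list of records for one channel
#' and stacks the results. Per-record failures are collected; the call only
#' fails if every record fails.
#'
#' @param records List of [ehg_record()] objects.
#' @param channel Channel id.
#' @param ... Passed to [extract_record_features()].
#' @param verbose Print per-record progress.
#' @return A `feature_matrix`: data frame with columns `record_id`,
#'   `channel`, `label`, the 6 feature columns, `n_windows_averaged`, with
#'   attributes `normalized` (FALSE), and later `column_means`/`column_sds`
#'   once normalized.
#' @export
extract_dataset_features <- function(records, channel = "CH1", ...,
                                     verbose = FALSE) {
  rows <- list()
  fails <- character(0)
  for (rec in records) {
    fv <- tryCatch(extract_record_features(rec, channel, ...),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      fails <- c(fails, sprintf("%s: %s", rec$record_id, conditionMessage(fv)))
      next
    }
    if (verbose)
      message(sprintf("[features] %s %s: %d windows (%d skipped)",
                      fv$record_id, channel, fv$n_windows_averaged,
                      fv$n_windows_skipped))
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = fv$record_id, channel = fv$channel, label = fv$label,
      as.list(fv$values), n_windows_averaged = fv$n_windows_averaged,
      check.names = FALSE)
  }
  if (length(rows) == 0)
    stop("feature error: all records failed:\n", paste(fails, collapse = "\n"))
  if (length(fails) > 0)
    warning(sprintf("%d record(s) failed feature extraction", length(fails)))
  fm <- do.call(rbind, rows)
  rownames(fm) <- NULL
  attr(fm, "normalized") <- FALSE
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Z-normalize feature columns
#'
#' Subtracts each feature column's mean and divides by its sample standard
#' deviation. `mode = "global"` (the default) uses all rows — the
#' whole-dataset normalization described for this pipeline, which leaks test
#' statistics into training and is therefore flagged on results.
#' `mode = "train_only"` computes the statistics on `train_idx` rows only
#' and applies them to all rows (leakage-safe).
#'
#' @param matrix A `feature_matrix` from [extract_dataset_features()].
#' @param mode `"global"` or `"train_only"`.
#' @param train_idx Row indices of the training subset (required for
#'   `"train_only"`).
#' @return The matrix with normalized feature columns and attributes
#'   `normalized = TRUE`, `normalization_mode`, `column_means`, `column_sds`.
#' @export
normalize_features <- function(matrix, mode = c("global", "train_only"),
                               train_idx = NULL) {
  mode <- match.arg(mode)
  if (nrow(matrix) < 2) stop("need at least 2 rows to normalize")
  fcols <- feature_names()
  ref <- if (mode == "global") seq_len(nrow(matrix)) else {
    if (is.null(train_idx)) stop("train_only mode requires train_idx")
    train_idx
  }
  mu <- vapply(fcols, function(cn) mean(matrix[[cn]][ref]), numeric(1))
  sds <- vapply(fcols, function(cn) stats::sd(matrix[[cn]][ref]), numeric(1))
  if (any(sds == 0))
    stop(sprintf("degenerate-feature error: zero-variance column(s): %s",
                 paste(fcols[sds == 0], collapse = ", ")))
  for (cn in fcols) matrix[[cn]] <- (matrix[[cn]] - mu[cn]) / sds[cn]
  attr(matrix, "normalized") <- TRUE
  attr(matrix, "normalization_mode") <- mode
  attr(matrix, "column_means") <- mu
  attr(matrix, "column_sds") <- sds
  matrix
}

#' Write / read a feature table as delimited text
#'
#' @param matrix A `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_table <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path))
  fm <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("record_id", "channel", "label", feature_names())
  if (!all(need %in% names(fm)))
    stop("feature table is missing required columns")
  attr(fm, "normalized") <- FALSE
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
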