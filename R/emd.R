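#' Locate interior local extrema
#'
#' Finds interior local maxima and minima by neighbour comparison. A plateau
#' of equal values contributes a single extremum at its midpoint index
#' (rounded down for even-length plateaus). By construction the returned
#' index vectors are strictly increasing and maxima/minima interleave.
#'
#' @param signal Numeric vector, length >= 3.
#' @return An object of class `extrema_set`: a list with integer vectors
#'   `maxima_indices` and `minima_indices` (1-based sample indices). Either
#'   may be empty (e.g. for a monotone signal).
#' @export
find_extrema <- function(signal) {
  n <- length(signal)
  if (n < 3) stop("signal must have at least 3 samples")
  d <- diff(signal)
  nz <- which(d != 0)
  empty <- structure(list(maxima_indices = integer(0),
                          minima_indices = integer(0)),
                     class = "extrema_set")
  if (length(nz) < 2) return(empty)
  s <- sign(d[nz])
  chg <- which(s[-length(s)] != s[-1])
  if (length(chg) == 0) return(empty)
  # a sign change at run j means an extremum spanning samples
  # nz[j]+1 .. nz[j+1] (a single sample when there is no plateau)
  left <- nz[chg] + 1L
  right <- nz[chg + 1L]
  idx <- (left + right) %/% 2L
  is_max <- s[chg] > 0
  structure(list(maxima_indices = idx[is_max],
                 minima_indices = idx[!is_max]),
            class = "extrema_set")
}

# Condition signalled when a signal has too few extrema to continue sifting;
# the caller treats the remaining signal as the residue.
emd_termination <- function(msg) {
  structure(class = c("emd_termination", "error", "condition"),
            list(message = msg, call = NULL))
}

mirror_knots <- function(idx, val, n, n_mirror = 2L) {
  k <- min(n_mirror, length(idx))
  left <- 2L - idx[seq_len(k)]               # reflect across sample 1
  right <- 2L * n - idx[length(idx) - seq_len(k) + 1L]  # across sample n
  list(x = c(rev(left), idx, rev(right)),
       y = c(val[seq_len(k)], val, val[length(val) - seq_len(k) + 1L]))
}

#' Upper and lower cubic-spline envelopes
#'
#' Interpolates the local maxima (upper) and minima (lower) with cubic
#' splines evaluated at every sample. End effects are mitigated by mirroring
#' the two nearest extrema across each end of the signal; additionally the
#' signal's endpoint values are pinned as envelope knots when they exceed
#' (upper) or undercut (lower) the adjacent extremum, so the envelope never
#' ignores an endpoint that is itself extremal. `upper >= lower` pointwise is
#' not guaranteed and not asserted.
#'
#' @param signal Numeric vector.
#' @param extrema An `extrema_set` from [find_extrema()].
#' @param spline_method `"fmm"` (default; Forsythe--Malcolm--Moler end
#'   conditions, base R's analogue of not-a-knot) or `"natural"`.
#' @return List with numeric vectors `upper` and `lower`, same length as
#'   `signal`. Signals with fewer than 2 maxima or 2 minima raise an
#'   `emd_termination` condition.
#' @export
envelopes <- function(signal, extrema, spline_method = c("fmm", "natural")) {
  spline_method <- match.arg(spline_method)
  n <- length(signal)
  mx <- extrema$maxima_indices
  mn <- extrema$minima_indices
  if (length(mx) < 2 || length(mn) < 2)
    stop(emd_termination(sprintf(
      "too few extrema to build envelopes (%d maxima, %d minima)",
      length(mx), length(mn))))
  one_env <- function(idx, val, upper) {
    if (upper) {
      if (signal[1] >= val[1]) { idx <- c(1L, idx); val <- c(signal[1], val) }
      if (signal[n] >= val[length(val)]) { idx <- c(idx, n); val <- c(val, signal[n]) }
    } else {
      if (signal[1] <= val[1]) { idx <- c(1L, idx); val <- c(signal[1], val) }
      if (signal[n] <= val[length(val)]) { idx <- c(idx, n); val <- c(val, signal[n]) }
    }
    kn <- mirror_knots(idx, val, n)
    keep <- !duplicated(kn$x)
    ord <- order(kn$x[keep])
    f <- stats::splinefun(kn$x[keep][ord], kn$y[keep][ord], method = spline_method)
    f(seq_len(n))
  }
  list(upper = one_env(mx, signal[mx], upper = TRUE),
       lower = one_env(mn, signal[mn], upper = FALSE))
}

#' One round of sifting: extract a single IMF candidate
#'
#' Repeatedly subtracts the local mean (the average of the upper and lower
#' envelopes) from the working signal until the stopping criterion fires or
#' `max_iterations` is reached. Two criteria are available:
#' \describe{
#'   \item{`"sd"` (default)}{Huang's normalized squared difference between
#'     consecutive candidates, \eqn{SD = \sum (h_{k-1}-h_k)^2 / \sum
#'     h_{k-1}^2}; stop when \eqn{SD <} `sd_threshold`.}
#'   \item{`"envelope_mean"`}{the literal reading of a 0.2 envelope-mean
#'     threshold: stop when `mean(|m|) / mean(|(upper-lower)/2|) <`
#'     `sd_threshold`.}
#' }
#'
#' @param signal Numeric vector with enough extrema for envelopes.
#' @param sd_threshold Stopping threshold (default 0.2).
#' @param max_iterations Hard iteration cap (default 100; guarantees
#'   termination, hitting it is recorded by the caller).
#' @param criterion `"sd"` or `"envelope_mean"`.
#' @param spline_method Passed to [envelopes()].
#' @return List with `imf` (numeric vector) and `iterations` (count used).
#' @export
sift <- function(signal, sd_threshold = 0.2, max_iterations = 100L,
                 criterion = c("sd", "envelope_mean"),
                 spline_method = "fmm") {
  criterion <- match.arg(criterion)
  h <- signal
  it <- 0L
  repeat {
    it <- it + 1L
    ext <- find_extrema(h)
    env <- envelopes(h, ext, spline_method = spline_method)
    m <- (env$upper + env$lower) / 2
    h_new <- h - m
    crit_ok <- if (criterion == "sd") {
      denom <- sum(h^2)
      denom == 0 || sum(m^2) / denom < sd_threshold
    } else {
      amp <- mean(abs((env$upper - env$lower) / 2))
      amp == 0 || mean(abs(m)) / amp < sd_threshold
    }
    # the candidate must also satisfy the counting condition of an IMF:
    # extrema and zero-crossings equal or differing by one
    cnt_ok <- FALSE
    if (crit_ok) {
      e2 <- find_extrema(h_new)
      n_ext <- length(e2$maxima_indices) + length(e2$minima_indices)
      cnt_ok <- abs(n_ext - count_zero_crossings(h_new)) <= 1
    }
    h <- h_new
    if ((crit_ok && cnt_ok) || it >= max_iterations) break
  }
  list(imf = h, iterations = it)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into up to `n_imfs` intrinsic mode functions by
#' iterated sifting on successive residues, following
#' \eqn{x(n) = \sum_j IMF_j + r_m(n)}. When the residue has too few extrema
#' to continue, decomposition stops early and the remaining content stays in
#' the residue, so the reconstruction identity holds exactly regardless. The
#' procedure is deterministic: identical inputs give identical outputs.
#'
#' @param signal Numeric vector, length >= 10, all finite.
#' @param n_imfs Maximum number of IMFs to extract (default 2: for EHG the
#'   two highest-frequency components carry the contraction energy).
#' @param sd_threshold,max_iterations,criterion,spline_method Passed to
#'   [sift()].
#' @return An object of class `imf_decomposition`: list with `imfs` (list of
#'   numeric vectors, possibly shorter than `n_imfs`), `residue`,
#'   `sift_counts` (iterations used per IMF), and `n_imfs` (count actually
#'   extracted).
#' @export
decompose <- function(signal, n_imfs = 2L, sd_threshold = 0.2,
                      max_iterations = 100L, criterion = "sd",
                      spline_method = "fmm") {
  if (length(signal) < 10) stop("signal must have at least 10 samples")
  if (!all(is.finite(signal))) stop("input error: non-finite samples")
  res <- as.numeric(signal)
  imfs <- list()
  counts <- integer(0)
  for (j in seq_len(n_imfs)) {
    s <- tryCatch(
      sift(res, sd_threshold = sd_threshold, max_iterations = max_iterations,
           criterion = criterion, spline_method = spline_method),
      emd_termination = function(e) NULL)
    if (is.null(s)) break
    imfs[[j]] <- s$imf
    counts[j] <- s$iterations
    res <- res - s$imf
  }
  structure(list(imfs = imfs, residue = res, sift_counts = counts,
                 n_imfs = length(imfs)),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("imf_decomposition: %d IMF(s) (+ residue), sift counts: %s\n",
              x$n_imfs, paste(x$sift_counts, collapse = ", ")))
  invisible(x)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Test the intrinsic-mode-function conditions
#'
#' `TRUE` iff (a) the counts of extrema and zero-crossings differ by at most
#' one, and (b) the envelope-mean ratio
#' `mean(|m|) / mean(|(upper-lower)/2|)` is below `tolerance`. Candidates
#' with too few extrema for envelopes return `FALSE`.
#'
#' @param candidate Numeric vector, length >= 3.
#' @param tolerance Envelope-mean threshold (default 0.2).
#' @param spline_method Passed to [envelopes()].
#' @export
is_imf <- function(candidate, tolerance = 0.2, spline_method = "fmm") {
  ext <- find_extrema(candidate)
  n_ext <- length(ext$maxima_indices) + length(ext$minima_indices)
  if (abs(n_ext - count_zero_crossings(candidate)) > 1) return(FALSE)
  env <- tryCatch(envelopes(candidate, ext, spline_method = spline_method),
                  emd_termination = function(e) NULL)
  if (is.null(env)) return(FALSE)
  m <- (env$upper + env$lower) / 2
  amp <- mean(abs((env$upper - env$lower) / 2))
  if (amp == 0) return(TRUE)
  mean(abs(m)) / amp < tolerance
}

#' Dump a window's decomposition as delimited text
#'
#' Debug helper: writes sample index, each IMF and the residue as CSV.
#'
#' @param decomposition An `imf_decomposition`.
#' @param path Output path.
#' @export
write_imf_csv <- function(decomposition, path) {
  cols <- c(list(sample = seq_along(decomposition$residue) - 1L),
            stats::setNames(decomposition$imfs,
                            paste0("IMF", seq_along(decomposition$imfs))),
            list(residue = decomposition$residue))
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}
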