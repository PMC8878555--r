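#' Design a digital Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass filter (so `2 * order` poles
#' in the digital filter) by the classical route: analog low-pass prototype,
#' low-pass-to-band-pass transformation with pre-warped edge frequencies, and
#' bilinear transform. The result is returned as cascaded second-order
#' sections (biquads), which stay numerically well-conditioned even for the
#' very low 0.08 Hz edge used for uterine EMG at 20 Hz, where a single
#' direct-form polynomial of degree 8 would not.
#'
#' @param order Prototype filter order (number of analog low-pass poles).
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `butter_bandpass` with elements `sos`
#'   (an `order` x 6 matrix of `b0 b1 b2 a0 a1 a2` rows), `gain` (scalar
#'   applied once), and the design parameters.
#' @seealso [bandpass_filter()]
#' @export
butter_bandpass <- function(order, low, high, fs) {
  if (!(is.numeric(low) && is.numeric(high) && is.numeric(fs)))
    stop("filter parameters must be numeric")
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist constraint)")
  N <- as.integer(order)
  if (N < 1) stop("order must be >= 1")

  k <- seq_len(N)
  p <- exp(1i * pi * (2 * k + N - 1) / (2 * N)) # LHP Butterworth poles

  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)   # pre-warped edges (rad/s)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass: each prototype pole splits into a pair
  pb <- p * bw / 2
  pa <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  za <- rep(0 + 0i, N)             # N analog zeros at the origin
  ka <- bw^N

  # bilinear transform of the zpk representation
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))

  # pair conjugate poles into biquads; each section takes one zero at z = +1
  # and one at z = -1, i.e. numerator (1, 0, -1)
  pp <- pd[Im(pd) >= 0]
  pp <- pp[order(-abs(pp))]
  sos <- matrix(0, nrow = N, ncol = 6,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(N)) {
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(pp[i]), Mod(pp[i])^2)
  }
  structure(
    list(sos = sos, gain = kd, order = N, low = low, high = high, fs = fs),
    class = "butter_bandpass"
  )
}

# Apply one biquad causally (direct form via FIR + recursive AR pass).
apply_biquad <- function(b, a, x) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

#' Band-pass filter a signal
#'
#' Filters a single channel with a Butterworth band-pass. The default pass
#' band 0.08--4 Hz with a 4th-order design is the standard preprocessing for
#' 20 Hz electrohysterogram recordings. The default is a single causal
#' forward pass; start-up transients are expected to be handled downstream by
#' trimming (see [trim_transients()]), not by zero-phase filtering. A
#' forward-backward zero-phase pass is available via `zero_phase = TRUE`.
#'
#' @param signal Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 0.08 and 4).
#' @param order Prototype order (default 4).
#' @param zero_phase If `TRUE`, filter forward then backward (squared
#'   magnitude response, zero phase). Default `FALSE`.
#' @return Filtered signal, same length as the input.
#' @export
bandpass_filter <- function(signal, fs, low = 0.08, high = 4.0, order = 4L,
                            zero_phase = FALSE) {
  if (!is.numeric(signal) || length(signal) == 0)
    stop("signal must be a non-empty numeric vector")
  if (length(signal) <= 3 * order)
    stop("signal too short for the requested filter order")
  des <- butter_bandpass(order, low, high, fs)
  run <- function(x) {
    y <- x * des$gain
    for (i in seq_len(nrow(des$sos)))
      y <- apply_biquad(des$sos[i, 1:3], des$sos[i, 4:6], y)
    y
  }
  y <- run(as.numeric(signal))
  if (zero_phase) y <- rev(run(rev(y)))
  y
}
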