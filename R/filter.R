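#' FFT brick-wall band-pass filter
#'
#' Filters the whole trace in the frequency domain: the forward DFT is
#' taken, every bin whose (folded) frequency lies outside
#' `[low_hz, high_hz]` is set to zero on both conjugate-symmetric halves,
#' and the inverse DFT is returned. This is the classic "FFT filter" of
#' acquisition software: zero-phase and exact in-band, at the price of
#' edge ringing near sharp transients. Traces are filtered whole, never
#' per window.
#'
#' With `low_hz = 0` the DC bin is kept, so `[0, 80]` is the slow-wave
#' low-pass and `[120, 400]` the ripple band-pass used for sharp
#' wave-ripple analysis.
#'
#' @param trace An [lfp_trace()].
#' @param band A [band_spec()] or numeric `c(low, high)`; `high` must not
#'   exceed Nyquist (`fs_hz / 2`).
#' @return A filtered [lfp_trace()] of the same length, rate and metadata.
#' @export
#' @examples
#' tr <- lfp_trace(sin(2 * pi * 50 * (0:9999) / 1000), fs_hz = 1000)
#' lp <- fft_bandpass(tr, c(0, 80))   # passes the 50 Hz tone untouched
fft_bandpass <- function(trace, band) {
  stopifnot(inherits(trace, "lfp_trace"))
  band <- as_band(band, trace$fs_hz)
  x <- trace$samples
  n <- length(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * trace$fs_hz / n
  X <- stats::fft(x)
  X[f < band$low_hz | f > band$high_hz] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  out <- trace
  out$samples <- y
  out
}
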