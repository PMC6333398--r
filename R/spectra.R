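#' Welch power spectral density
#'
#' Averaged modified periodograms: the trace is cut into segments of
#' `nfft` samples with the given overlap, each segment is Hann-windowed,
#' and the one-sided density-scaled periodograms are averaged. With the
#' 10 kHz sampling rate of the target recordings and the default
#' `nfft = 8192` the bin spacing is 10000/8192 = 1.2207 Hz.
#'
#' Density scaling means `sum(power) * df_hz` approximates the variance of
#' a zero-mean input (Parseval, up to windowing loss), so areas under the
#' spectrum carry physical units of mV^2.
#'
#' @param trace An [lfp_trace()] (typically one 30-s analysis window).
#' @param nfft Segment and transform length in samples.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return An object of class `lfp_psd`: list with `freqs_hz`, `power`
#'   (mV^2/Hz), `df_hz`, `nfft`, `fs_hz`, `n_segments`.
#' @export
welch_psd <- function(trace, nfft = 8192L, overlap = 0.5) {
  stopifnot(inherits(trace, "lfp_trace"))
  nfft <- as.integer(nfft)
  x <- trace$samples
  n <- length(x)
  if (n < nfft) {
    stop("trace length (", n, ") shorter than nfft (", nfft, ")",
         call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq.int(1L, n - nfft + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / nfft))  # periodic Hann
  u <- sum(w^2)
  nhalf <- nfft %/% 2L
  acc <- numeric(nhalf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    X <- stats::fft(seg)
    p <- (Mod(X[seq_len(nhalf + 1L)])^2) / (trace$fs_hz * u)
    p[2:nhalf] <- 2 * p[2:nhalf]  # fold negative frequencies, keep DC/Nyquist
    acc <- acc + p
  }
  power <- acc / length(starts)
  structure(
    list(freqs_hz = (0:nhalf) * trace$fs_hz / nfft,
         power = power,
         df_hz = trace$fs_hz / nfft,
         nfft = nfft,
         fs_hz = trace$fs_hz,
         n_segments = length(starts)),
    class = "lfp_psd"
  )
}

#' Normalized autocorrelation of a trace
#'
#' Biased (divide-by-n) autocovariance of the demeaned signal, computed by
#' FFT and normalized so that `r(0) = 1`. Lags run from 0 to `max_lag_ms`
#' at the sampling step. The biased estimator guarantees `|r| <= 1` and a
#' positive-semidefinite sequence, which the exponential-envelope TAU fit
#' assumes.
#'
#' @param trace An [lfp_trace()].
#' @param max_lag_ms Largest lag, in ms; must be shorter than the trace.
#' @return An object of class `lfp_acorr`: list with `lags_ms` and `r`.
#' @export
autocorrelation <- function(trace, max_lag_ms) {
  stopifnot(inherits(trace, "lfp_trace"))
  n <- length(trace$samples)
  max_lag <- as.integer(round(max_lag_ms / 1000 * trace$fs_hz))
  if (max_lag >= n) {
    stop("max_lag_ms (", max_lag_ms, ") must be shorter than the window",
         call. = FALSE)
  }
  x <- trace$samples - mean(trace$samples)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  ac <- ac[seq_len(max_lag + 1L)] / n
  if (ac[1] <= 0) stop("zero-variance window: autocorrelation undefined",
                       call. = FALSE)
  structure(
    list(lags_ms = (0:max_lag) / trace$fs_hz * 1000, r = ac / ac[1],
         n = n, fs_hz = trace$fs_hz),
    class = "lfp_acorr"
  )
}

#' Morlet wavelet spectrogram
#'
#' Time-frequency power via the analytic Morlet wavelet (centre frequency
#' `omega0 = 6`), evaluated at `n_freqs` log-spaced frequencies between
#' `fmin_hz` and `fmax_hz`. Convolution is done in the frequency domain
#' per row. Intended for visualizing ripple-band structure of single
#' events; rows are ordered low to high frequency.
#'
#' @param trace An [lfp_trace()].
#' @param fmin_hz,fmax_hz Frequency range; `0 < fmin < fmax <= Nyquist`.
#' @param n_freqs Number of log-spaced frequency rows.
#' @param omega0 Morlet centre frequency (non-dimensional).
#' @return List of class `lfp_spectrogram` with `power` (`n_freqs` x
#'   `n_samples` matrix), `freqs_hz`, `times_s`.
#' @export
spectrogram <- function(trace, fmin_hz, fmax_hz, n_freqs = 64L,
                        omega0 = 6) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (fmin_hz <= 0 || fmin_hz >= fmax_hz || fmax_hz > trace$fs_hz / 2) {
    stop("need 0 < fmin_hz < fmax_hz <= Nyquist", call. = FALSE)
  }
  x <- trace$samples
  n <- length(x)
  freqs <- exp(seq(log(fmin_hz), log(fmax_hz), length.out = n_freqs))
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) * trace$fs_hz / n
  power <- matrix(0, n_freqs, n)
  for (i in seq_len(n_freqs)) {
    s <- omega0 / (2 * pi * freqs[i])
    psi <- ifelse(omega > 0, exp(-0.5 * (s * omega - omega0)^2), 0)
    w <- stats::fft(X * psi, inverse = TRUE) / n
    power[i, ] <- Mod(w)^2
  }
  structure(
    list(power = power, freqs_hz = freqs,
         times_s = trace$t0_s + (seq_len(n) - 1) / trace$fs_hz),
    class = "lfp_spectrogram"
  )
}
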