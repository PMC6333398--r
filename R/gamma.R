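#' Gamma analysis windowing scheme
#'
#' The trailing `analysis_span_s` of a recording (default the last
#' 5 minutes) is partitioned into consecutive non-overlapping windows of
#' `window_s` seconds (default 30 s, i.e. 10 windows per 5 min), each
#' band-pass filtered to `band` (default 5-200 Hz) before spectral
#' analysis. Partial trailing windows are dropped.
#'
#' @param analysis_span_s Portion analyzed, seconds (default 300).
#' @param window_s Window length, seconds (default 30).
#' @param band Pre-filter [band_spec()] (default 5-200 Hz).
#' @return A validated list of class `gamma_windowing`.
#' @export
gamma_windowing <- function(analysis_span_s = 300, window_s = 30,
                            band = band_spec(5, 200)) {
  if (window_s <= 0) stop("'window_s' must be > 0", call. = FALSE)
  if (analysis_span_s < window_s) {
    stop("'analysis_span_s' must be >= 'window_s'", call. = FALSE)
  }
  structure(list(analysis_span_s = analysis_span_s, window_s = window_s,
                 band = as_band(band)),
            class = "gamma_windowing")
}

#' Cut a recording into filtered analysis windows
#'
#' @param trace An [lfp_trace()] at least one window long.
#' @param windowing A [gamma_windowing()].
#' @return List of band-pass filtered [lfp_trace()] windows, earliest
#'   first, covering the trailing end of the analyzed span.
#' @export
segment_windows <- function(trace, windowing = gamma_windowing()) {
  stopifnot(inherits(trace, "lfp_trace"))
  fs <- trace$fs_hz
  dur <- trace_duration_s(trace)
  if (dur < windowing$window_s) {
    stop("trace (", round(dur, 3), " s) shorter than one window (",
         windowing$window_s, " s)", call. = FALSE)
  }
  span <- min(windowing$analysis_span_s, dur)
  k <- floor(span / windowing$window_s)
  wn <- as.integer(round(windowing$window_s * fs))
  n <- length(trace$samples)
  # windows tile backwards from the end so the latest data is analyzed
  lapply(seq_len(k), function(j) {
    i1 <- n - (k - j) * wn
    i0 <- i1 - wn + 1L
    w <- lfp_trace(trace$samples[i0:i1], fs,
                   t0_s = trace$t0_s + (i0 - 1) / fs, meta = trace$meta)
    fft_bandpass(w, windowing$band)
  })
}

#' Spectral peak metrics of a power spectrum
#'
#' Finds the power maximum within `search_band` and characterizes its
#' peak: `f_hz` the bin-centre frequency of the maximum, `ppsd` the peak
#' power density, the peak region as the maximal contiguous run of bins
#' containing the peak with power at or above half maximum, `fwhm_hz` the
#' width of that region with linear interpolation at the half-power
#' crossings (floored at one bin), and `auc` the trapezoidal integral of
#' power over the region (`ppsd * df` for a single-bin region).
#'
#' @param psd An `lfp_psd` from [welch_psd()].
#' @param search_band [band_spec()] to search (default 25-100 Hz, the
#'   gamma range above the 25 Hz acceptance edge).
#' @return List with `f_hz`, `ppsd`, `auc`, `fwhm_hz`, `edge_peak`
#'   (TRUE when the maximum sits on a search-band edge bin).
#' @export
gamma_spectrum_metrics <- function(psd, search_band = band_spec(25, 100)) {
  stopifnot(inherits(psd, "lfp_psd"))
  search_band <- as_band(search_band, psd$fs_hz)
  in_band <- which(psd$freqs_hz >= search_band$low_hz &
                     psd$freqs_hz <= search_band$high_hz)
  if (!length(in_band)) stop("empty search band for this PSD", call. = FALSE)
  g <- in_band[which.max(psd$power[in_band])]
  ppsd <- psd$power[g]
  half <- ppsd / 2
  p <- psd$power
  nb <- length(p)
  l <- g
  while (l > 1L && p[l - 1L] >= half) l <- l - 1L
  r <- g
  while (r < nb && p[r + 1L] >= half) r <- r + 1L
  df <- psd$df_hz
  left_x <- if (l == 1L) psd$freqs_hz[1L] else {
    psd$freqs_hz[l] - df * (p[l] - half) / (p[l] - p[l - 1L])
  }
  right_x <- if (r == nb) psd$freqs_hz[nb] else {
    psd$freqs_hz[r] + df * (p[r] - half) / (p[r] - p[r + 1L])
  }
  fwhm <- max(right_x - left_x, df)
  auc <- if (r == l) ppsd * df else {
    sum((p[l:(r - 1L)] + p[(l + 1L):r]) / 2) * df
  }
  list(f_hz = psd$freqs_hz[g], ppsd = ppsd, auc = auc, fwhm_hz = fwhm,
       edge_peak = g == in_band[1L] || g == in_band[length(in_band)])
}

#' Inner-coherence time constant from an autocorrelogram
#'
#' Collects the autocorrelation local maxima near integer multiples of
#' the oscillation period (lag windows `k/f +- 1/(2f)`, `k >= 1`; the
#' zero-lag point is excluded) and fits `A * exp(-lag / tau)` to the
#' positive peaks by least squares on the log-transformed peak values.
#'
#' Two numerical choices make the estimate stable on single recordings:
#' the biased autocorrelation's triangular taper (factor `1 - lag/T` for
#' a window of length `T`) is divided out before fitting, since for
#' coherence times comparable to the window it masquerades as genuine
#' decay; and the log-fit is weighted by the squared peak value, which is
#' the correct relative weighting for log-transformed data and keeps
#' noise-floor peaks at long lags from flattening the fit.
#'
#' @param acorr An `lfp_acorr` from [autocorrelation()]; must span at
#'   least 5 oscillation periods.
#' @param f_hz Oscillation frequency locating the expected peaks.
#' @param taper_correct Divide out the biased estimator's triangular
#'   taper (default TRUE; only possible when `acorr` carries the window
#'   length).
#' @return List with `tau_ms` (`NA` with a `reason` when fewer than 3
#'   usable peaks exist; `Inf` with reason `"non_decaying"` for an
#'   undamped oscillation), `a` (fitted amplitude), `n_peaks`, `reason`
#'   (`"ok"` on success) and `peaks` (lag/value pairs used).
#' @export
fit_tau <- function(acorr, f_hz, taper_correct = TRUE) {
  stopifnot(inherits(acorr, "lfp_acorr"))
  period_ms <- 1000 / f_hz
  max_lag <- max(acorr$lags_ms)
  if (max_lag < 5 * period_ms) {
    stop("autocorrelogram must span >= 5 periods of f_hz", call. = FALSE)
  }
  r <- acorr$r
  if (taper_correct && !is.null(acorr$n)) {
    lag_frac <- (acorr$lags_ms / 1000 * acorr$fs_hz) / acorr$n
    r <- r / (1 - lag_frac)
  }
  peak_lag <- numeric(0)
  peak_val <- numeric(0)
  k <- 1L
  while ((k + 0.5) * period_ms <= max_lag) {
    lo <- (k - 0.5) * period_ms
    hi <- (k + 0.5) * period_ms
    idx <- which(acorr$lags_ms > lo & acorr$lags_ms <= hi)
    if (length(idx) >= 3L) {
      seg <- r[idx]
      lm_idx <- local_maxima(seg)
      # the expected peak sits at lag k/f: take the local maximum nearest
      # to it (picking the largest would bias small peaks upward)
      j <- if (length(lm_idx)) {
        lm_idx[which.min(abs(acorr$lags_ms[idx[lm_idx]] - k * period_ms))]
      } else which.max(seg)
      peak_lag <- c(peak_lag, acorr$lags_ms[idx[j]])
      peak_val <- c(peak_val, seg[j])
    }
    k <- k + 1L
  }
  # once the envelope estimate reaches the noise floor the peaks hover
  # around zero; truncate the sequence at the first non-positive peak
  first_bad <- which(peak_val <= 0)
  usable <- rep(TRUE, length(peak_val))
  if (length(first_bad)) usable[first_bad[1]:length(usable)] <- FALSE
  if (sum(usable) < 3L) {
    return(list(tau_ms = NA_real_, a = NA_real_, n_peaks = sum(usable),
                reason = "insufficient_peaks",
                peaks = data.frame(lag_ms = peak_lag, r = peak_val)))
  }
  x <- peak_lag[usable]
  y <- log(peak_val[usable])
  fit <- stats::lm.wfit(cbind(1, x), y, w = peak_val[usable]^2)
  slope <- unname(fit$coefficients[2])
  a <- exp(unname(fit$coefficients[1]))
  if (!is.finite(slope) || slope >= 0) {
    return(list(tau_ms = Inf, a = a, n_peaks = sum(usable),
                reason = "non_decaying",
                peaks = data.frame(lag_ms = peak_lag, r = peak_val)))
  }
  list(tau_ms = -1 / slope, a = a, n_peaks = sum(usable), reason = "ok",
       peaks = data.frame(lag_ms = peak_lag, r = peak_val))
}

#' Windowed gamma metrics with median summary and acceptance rule
#'
#' Computes the Welch spectrum and spectral peak metrics plus the
#' autocorrelation TAU for every window, then reports the median of each
#' metric across windows. A recording is accepted when the median peak
#' frequency strictly exceeds 25 Hz.
#'
#' @param windows List of filtered windows from [segment_windows()].
#' @param nfft Welch transform size (default 8192).
#' @param search_band Spectral peak search [band_spec()].
#' @param tau_max_lag_ms Autocorrelation span for the TAU fit, ms.
#' @return An object of class `gamma_metrics`: list with the medians
#'   `f_hz`, `ppsd`, `auc`, `fwhm_hz`, `tau_ms`, the flag `accepted`,
#'   `n_windows`, `tau_note` (set when TAU failed in every window) and
#'   `per_window` (one row per window).
#' @export
summarize_gamma <- function(windows, nfft = 8192L,
                            search_band = band_spec(25, 100),
                            tau_max_lag_ms = 1000) {
  if (!length(windows)) stop("need at least one window", call. = FALSE)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    psd <- welch_psd(w, nfft = nfft)
    m <- gamma_spectrum_metrics(psd, search_band)
    ac <- autocorrelation(w, tau_max_lag_ms)
    tf <- fit_tau(ac, m$f_hz)
    data.frame(window_index = i, f_hz = m$f_hz, ppsd = m$ppsd,
               auc = m$auc, fwhm_hz = m$fwhm_hz, tau_ms = tf$tau_ms,
               tau_reason = tf$reason, edge_peak = m$edge_peak)
  })
  per_window <- do.call(rbind, rows)
  tau_vals <- per_window$tau_ms[!is.na(per_window$tau_ms)]
  med_f <- stats::median(per_window$f_hz)
  structure(
    list(f_hz = med_f,
         ppsd = stats::median(per_window$ppsd),
         auc = stats::median(per_window$auc),
         fwhm_hz = stats::median(per_window$fwhm_hz),
         tau_ms = if (length(tau_vals)) stats::median(tau_vals) else NA_real_,
         accepted = med_f > 25,
         n_windows = nrow(per_window),
         tau_note = if (!length(tau_vals)) "tau undefined in all windows" else NULL,
         per_window = per_window),
    class = "gamma_metrics")
}

#' @export
print.gamma_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<gamma_metrics> %d windows: f=%.2f Hz, pPSD=%.3g mV^2/Hz, ",
           "AUC=%.3g mV^2, FWHM=%.2f Hz, TAU=%.1f ms [%s]\n"),
    x$n_windows, x$f_hz, x$ppsd, x$auc, x$fwhm_hz, x$tau_ms,
    if (x$accepted) "accepted" else "rejected: peak <= 25 Hz"))
  invisible(x)
}

#' Full gamma pipeline on one recording
#'
#' @param trace An [lfp_trace()].
#' @param windowing A [gamma_windowing()].
#' @param ... Passed to [summarize_gamma()].
#' @return A `gamma_metrics` object.
#' @export
analyze_gamma <- function(trace, windowing = gamma_windowing(), ...) {
  summarize_gamma(segment_windows(trace, windowing), ...)
}
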