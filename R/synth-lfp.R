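#' Parameters for the synthetic sharp wave-ripple generator
#'
#' Defaults describe a typical interface-chamber CA3 recording: events at
#' 2 per second riding on 1/f background noise, 0.1 mV sharp waves of
#' ~10 ms Gaussian half-width with a 180 Hz ripple at half the sharp-wave
#' amplitude, and a 250 ms refractory interval between events.
#'
#' @param duration_s Trace duration in seconds.
#' @param fs_hz Sampling rate (default 10000, the digitization rate of the
#'   target recordings).
#' @param event_rate_hz Mean SPW-R event rate in events/s. Must satisfy
#'   `event_rate_hz < 1000 / refractory_ms` so the refractory interval can
#'   be honoured at the requested mean rate.
#' @param sw_amplitude_mv Peak slow-wave deflection in mV.
#' @param sw_sigma_ms Gaussian half-width (SD) of the slow deflection, ms.
#' @param ripple_freq_hz Ripple frequency in Hz, within `[120, 400]`.
#' @param ripple_rel_amp Ripple amplitude as a fraction of
#'   `sw_amplitude_mv`.
#' @param noise_sd_mv Background noise SD in mV.
#' @param noise_exponent Spectral slope of the background noise
#'   (0 = white, 1 = pink).
#' @param refractory_ms Minimum inter-event interval in ms.
#' @param seed Integer RNG seed.
#' @return A validated list of class `spwr_gen_params`.
#' @export
spwr_gen_params <- function(duration_s, fs_hz = 10000, event_rate_hz = 2,
                            sw_amplitude_mv = 0.1, sw_sigma_ms = 10,
                            ripple_freq_hz = 180, ripple_rel_amp = 0.5,
                            noise_sd_mv = 0.01, noise_exponent = 1,
                            refractory_ms = 250, seed = 1L) {
  p <- list(duration_s = duration_s, fs_hz = fs_hz,
            event_rate_hz = event_rate_hz, sw_amplitude_mv = sw_amplitude_mv,
            sw_sigma_ms = sw_sigma_ms, ripple_freq_hz = ripple_freq_hz,
            ripple_rel_amp = ripple_rel_amp, noise_sd_mv = noise_sd_mv,
            noise_exponent = noise_exponent, refractory_ms = refractory_ms,
            seed = as.integer(seed))
  check_num <- function(field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- p[[field]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (strict_lo) v > lo else v >= lo) && v <= hi
    if (!ok) stop("invalid '", field, "'", call. = FALSE)
  }
  check_num("duration_s", 0, strict_lo = TRUE)
  check_num("fs_hz", 0, strict_lo = TRUE)
  check_num("event_rate_hz", 0)
  check_num("ripple_freq_hz", 120, 400)
  check_num("refractory_ms", 0, strict_lo = TRUE)
  check_num("sw_amplitude_mv", 0)
  check_num("sw_sigma_ms", 0, strict_lo = TRUE)
  check_num("ripple_rel_amp", 0)
  check_num("noise_sd_mv", 0)
  if (p$event_rate_hz >= 1000 / p$refractory_ms) {
    stop("invalid 'event_rate_hz': must be below 1000/refractory_ms",
         call. = FALSE)
  }
  structure(p, class = "spwr_gen_params")
}

# 1/f^exponent Gaussian background: white noise shaped in the frequency
# domain by f^(-exponent/2), DC removed, rescaled to the requested SD.
shaped_noise <- function(n, fs_hz, sd_mv, exponent) {
  if (sd_mv == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(w * sd_mv)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs_hz / n
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x * sd_mv / stats::sd(x)
}

# Rate-preserving Poisson process with dead time: inter-event intervals are
# refractory + Exp(mean = 1/rate - refractory), so the mean rate is exactly
# `rate` while no two events fall closer than the refractory interval.
dead_time_poisson <- function(duration_s, rate_hz, refractory_s) {
  if (rate_hz <= 0) return(numeric(0))
  mean_gap <- 1 / rate_hz
  exp_mean <- mean_gap - refractory_s
  n_draw <- max(16L, ceiling(duration_s * rate_hz * 2 + 10))
  gaps <- refractory_s + stats::rexp(n_draw, rate = 1 / exp_mean)
  # first event: uniform phase within one mean interval keeps the process
  # stationary-ish at the trace start
  times <- cumsum(c(stats::runif(1, 0, mean_gap), gaps))
  while (times[length(times)] < duration_s) {
    extra <- refractory_s + stats::rexp(n_draw, rate = 1 / exp_mean)
    times <- c(times, times[length(times)] + cumsum(extra))
  }
  times[times < duration_s]
}

# Count of ripple local maxima exceeding k*SD of the clean ripple component
# -- the generator's own brute-force oracle for truth$ripple_cycles.
count_clean_ripple_cycles <- function(ripple_clean, windows, k_sd = 3) {
  thr <- k_sd * stats::sd(ripple_clean)
  vapply(windows, function(w) {
    seg <- ripple_clean[w[1]:w[2]]
    if (length(seg) < 3L) return(0L)
    mid <- 2:(length(seg) - 1L)
    peaks <- seg[mid] > seg[mid - 1L] & seg[mid] >= seg[mid + 1L] &
      seg[mid] > thr
    sum(peaks)
  }, integer(1))
}

#' Generate a synthetic sharp wave-ripple trace with ground truth
#'
#' Events are placed by a rate-preserving Poisson process with a hard
#' refractory interval. Each event is a Gaussian-windowed slow deflection
#' with a ripple-band sinusoid under the same envelope, added to
#' spectrally shaped (1/f by default) Gaussian background noise. The same
#' seed reproduces the trace bit for bit.
#'
#' @param params An [spwr_gen_params()].
#' @return List with `trace` (an [lfp_trace()]) and `truth` (class
#'   `synth_truth`): `event_times_s`, `event_amplitudes_mv`,
#'   `ripple_cycles` (supra-threshold ripple peaks per event, counted on
#'   the noise-free ripple component at the 3 SD rule), `params`.
#' @export
generate_spwr_trace <- function(params) {
  stopifnot(inherits(params, "spwr_gen_params"))
  set.seed(params$seed)
  n <- as.integer(round(params$duration_s * params$fs_hz))
  t <- (seq_len(n) - 1) / params$fs_hz
  times <- dead_time_poisson(params$duration_s, params$event_rate_hz,
                             params$refractory_ms / 1000)
  sigma_s <- params$sw_sigma_ms / 1000
  slow <- numeric(n)
  ripple <- numeric(n)
  windows <- vector("list", length(times))
  half_w <- ceiling(4 * sigma_s * params$fs_hz)
  for (i in seq_along(times)) {
    tc <- times[i]
    ic <- as.integer(round(tc * params$fs_hz)) + 1L
    i0 <- max(1L, ic - half_w); i1 <- min(n, ic + half_w)
    idx <- i0:i1
    g <- exp(-((t[idx] - tc)^2) / (2 * sigma_s^2))
    slow[idx] <- slow[idx] + params$sw_amplitude_mv * g
    ripple[idx] <- ripple[idx] + params$ripple_rel_amp *
      params$sw_amplitude_mv * g *
      sin(2 * pi * params$ripple_freq_hz * (t[idx] - tc))
    windows[[i]] <- c(i0, i1)
  }
  noise <- shaped_noise(n, params$fs_hz, params$noise_sd_mv,
                        params$noise_exponent)
  trace <- lfp_trace(slow + ripple + noise, params$fs_hz,
                     meta = list(condition = "spontaneous",
                                 synthetic = TRUE))
  ripple_cycles <- if (length(times)) {
    count_clean_ripple_cycles(ripple, windows)
  } else integer(0)
  truth <- structure(
    list(event_times_s = times,
         event_amplitudes_mv = rep(params$sw_amplitude_mv, length(times)),
         ripple_cycles = ripple_cycles,
         params = unclass(params)),
    class = "synth_truth")
  list(trace = trace, truth = truth)
}

#' Parameters for the synthetic gamma-oscillation generator
#'
#' @param duration_s Trace duration in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @param osc_freq_hz Carrier frequency in Hz (carbachol gamma peaks near
#'   40 Hz in the target preparations).
#' @param osc_amp_mv Carrier amplitude in mV.
#' @param phase_diffusion Phase-noise intensity in rad^2/s. The carrier
#'   phase performs a Wiener walk with this variance rate, which gives the
#'   oscillation an exponentially decaying autocorrelation envelope with
#'   expected time constant `2000 / phase_diffusion` ms.
#' @param noise_sd_mv Additive white-noise SD in mV.
#' @param seed Integer RNG seed.
#' @return A validated list of class `gamma_gen_params`.
#' @export
gamma_gen_params <- function(duration_s, fs_hz = 10000, osc_freq_hz = 40,
                             osc_amp_mv = 0.05, phase_diffusion = 10,
                             noise_sd_mv = 0.01, seed = 1L) {
  p <- list(duration_s = duration_s, fs_hz = fs_hz,
            osc_freq_hz = osc_freq_hz, osc_amp_mv = osc_amp_mv,
            phase_diffusion = phase_diffusion, noise_sd_mv = noise_sd_mv,
            seed = as.integer(seed))
  if (!is.numeric(p$duration_s) || p$duration_s <= 0) {
    stop("invalid 'duration_s'", call. = FALSE)
  }
  if (!is.numeric(p$osc_freq_hz) || p$osc_freq_hz <= 0) {
    stop("invalid 'osc_freq_hz'", call. = FALSE)
  }
  if (!is.numeric(p$phase_diffusion) || p$phase_diffusion < 0) {
    stop("invalid 'phase_diffusion'", call. = FALSE)
  }
  if (!is.numeric(p$noise_sd_mv) || p$noise_sd_mv < 0) {
    stop("invalid 'noise_sd_mv'", call. = FALSE)
  }
  structure(p, class = "gamma_gen_params")
}

# Direct-lag coherence oracle: correlations of the clean oscillation with
# itself at integer-period lags, log-linear fit of the decay. Independent
# of the analysis-path autocorrelation/fit machinery.
clean_coherence_tau_ms <- function(clean, fs_hz, f_hz, duration_s) {
  span_s <- min(duration_s / 4, 1)
  ks <- seq_len(max(1L, floor(span_s * f_hz)))
  lags <- unique(as.integer(round(ks * fs_hz / f_hz)))
  lags <- lags[lags > 0 & lags < length(clean)]
  r <- vapply(lags, function(l) {
    stats::cor(clean[seq_len(length(clean) - l)],
               clean[(l + 1L):length(clean)])
  }, numeric(1))
  # the envelope estimate is meaningless once it reaches the noise floor:
  # truncate at the first non-positive correlation
  first_bad <- which(!is.finite(r) | r <= 0)
  if (length(first_bad)) {
    keep_n <- first_bad[1] - 1L
    lags <- lags[seq_len(keep_n)]
    r <- r[seq_len(keep_n)]
  }
  if (length(r) < 3L) return(NA_real_)
  lag_ms <- lags / fs_hz * 1000
  # weight by r^2: correct relative weighting for the log transform,
  # keeps realization noise at small correlations from flattening the fit
  fit <- stats::lm.wfit(cbind(1, lag_ms), log(r), w = r^2)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= -1e-12) return(Inf)
  -1 / slope
}

#' Generate a synthetic gamma-oscillation trace with ground truth
#'
#' The trace is `osc_amp_mv * cos(2*pi*osc_freq_hz*t + W(t))` plus white
#' noise, where `W` is a Wiener phase walk with variance rate
#' `phase_diffusion` (rad^2/s). The truth records the carrier frequency
#' and an empirical coherence time constant computed by the generator's
#' own direct-lag oracle on the noise-free oscillation.
#'
#' @param params A [gamma_gen_params()].
#' @return List with `trace` and `truth` (fields `osc_freq_hz`,
#'   `coherence_tau_ms`, `params`); `coherence_tau_ms` is `Inf` for a
#'   fully coherent (zero-diffusion) oscillation.
#' @export
generate_gamma_trace <- function(params) {
  stopifnot(inherits(params, "gamma_gen_params"))
  set.seed(params$seed)
  n <- as.integer(round(params$duration_s * params$fs_hz))
  dt <- 1 / params$fs_hz
  t <- (seq_len(n) - 1) * dt
  w <- if (params$phase_diffusion > 0) {
    cumsum(stats::rnorm(n, 0, sqrt(params$phase_diffusion * dt)))
  } else numeric(n)
  clean <- params$osc_amp_mv * cos(2 * pi * params$osc_freq_hz * t + w)
  noise <- if (params$noise_sd_mv > 0) {
    stats::rnorm(n, 0, params$noise_sd_mv)
  } else numeric(n)
  trace <- lfp_trace(clean + noise, params$fs_hz,
                     meta = list(condition = "carbachol", synthetic = TRUE))
  tau <- if (params$phase_diffusion == 0) {
    Inf
  } else {
    clean_coherence_tau_ms(clean, params$fs_hz, params$osc_freq_hz,
                           params$duration_s)
  }
  truth <- structure(
    list(osc_freq_hz = params$osc_freq_hz, coherence_tau_ms = tau,
         params = unclass(params)),
    class = "synth_truth")
  list(trace = trace, truth = truth)
}
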