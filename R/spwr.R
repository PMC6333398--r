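#' Sharp wave-ripple detection parameters
#'
#' The slow (wave) component is obtained by a 0-80 Hz FFT low-pass and
#' used for event detection; the ripple component by a 120-400 Hz FFT
#' band-pass. Ripples are counted at 3 SD of the band-passed signal, the
#' convention the analysis reproduces; the slow-component detection
#' threshold mirrors that convention at 3 SD since slice work rarely
#' reports it explicitly. Detection is polarity-agnostic (|deviation|
#' from baseline) because the sharp-wave polarity in slice LFPs depends
#' on electrode depth.
#'
#' @param slow_band [band_spec()] for the slow component (default 0-80 Hz).
#' @param ripple_band [band_spec()] for ripples (default 120-400 Hz).
#' @param detect_k_sd Peak detection threshold in SDs of the slow
#'   component (default 3).
#' @param ripple_k_sd Ripple counting threshold in SDs of the ripple
#'   component (default 3).
#' @param merge_ms Peaks closer than this merge into one event, keeping
#'   the larger (default 50 ms).
#' @param boundary_k_sd Event start/end at the nearest crossings of this
#'   many SDs flanking the peak (default 1).
#' @return A validated list of class `spwr_detect_params`.
#' @export
spwr_detect_params <- function(slow_band = band_spec(0, 80),
                               ripple_band = band_spec(120, 400),
                               detect_k_sd = 3, ripple_k_sd = 3,
                               merge_ms = 50, boundary_k_sd = 1) {
  if (detect_k_sd <= 0 || ripple_k_sd <= 0 || boundary_k_sd <= 0) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  if (merge_ms < 0) stop("'merge_ms' must be >= 0", call. = FALSE)
  structure(list(slow_band = as_band(slow_band),
                 ripple_band = as_band(ripple_band),
                 detect_k_sd = detect_k_sd, ripple_k_sd = ripple_k_sd,
                 merge_ms = merge_ms, boundary_k_sd = boundary_k_sd),
            class = "spwr_detect_params")
}

# Local maxima indices of x: strictly greater than the left neighbour,
# at least the right neighbour (plateaus count once).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  mid <- 2:(n - 1L)
  which(x[mid] > x[mid - 1L] & x[mid] >= x[mid + 1L]) + 1L
}

#' Detect sharp wave-ripple events
#'
#' The trace is low-pass filtered to its slow component; samples whose
#' absolute deviation from baseline (the median of the slow component)
#' exceeds `detect_k_sd` SDs of the slow component form candidate
#' regions, one peak per region at the extremum. Peaks closer than
#' `merge_ms` merge, keeping the larger. Event boundaries sit at the
#' nearest `boundary_k_sd`-SD crossings flanking each peak; overlapping
#' neighbours are trimmed at the midpoint so events are disjoint and
#' ordered.
#'
#' @param trace An [lfp_trace()]; at least 10 s is recommended so the SD
#'   estimate is stable, and at least 1 s is required.
#' @param params An [spwr_detect_params()].
#' @return A data.frame of events with columns `t_peak_s`, `t_start_s`,
#'   `t_end_s` (plus internal sample indices `i_peak`, `i_start`,
#'   `i_end`), sorted by peak time. Metric columns are added by
#'   [event_metrics()].
#' @export
detect_events <- function(trace, params = spwr_detect_params()) {
  stopifnot(inherits(trace, "lfp_trace"))
  n <- length(trace$samples)
  fs <- trace$fs_hz
  if (n < fs) stop("trace too short for SD estimation (< 1 s)", call. = FALSE)
  if (fs < 2 * params$ripple_band$high_hz) {
    stop("sampling rate below twice the ripple band upper edge",
         call. = FALSE)
  }
  slow <- fft_bandpass(trace, params$slow_band)$samples
  baseline <- stats::median(slow)
  dev <- slow - baseline
  sdv <- stats::sd(slow)
  if (sdv == 0) {
    return(empty_events())
  }
  above <- abs(dev) > params$detect_k_sd * sdv
  if (!any(above)) return(empty_events())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- which(runs$values)
  peaks <- vapply(sel, function(j) {
    idx <- starts[j]:ends[j]
    idx[which.max(abs(dev[idx]))]
  }, integer(1))
  peaks <- sort(peaks)
  # merge close peaks, keeping the larger deviation
  if (length(peaks) > 1L && params$merge_ms > 0) {
    merge_n <- params$merge_ms / 1000 * fs
    repeat {
      gaps <- diff(peaks)
      j <- which(gaps < merge_n)
      if (!length(j)) break
      j <- j[1]
      drop <- if (abs(dev[peaks[j]]) >= abs(dev[peaks[j + 1L]])) j + 1L else j
      peaks <- peaks[-drop]
    }
  }
  b_thr <- params$boundary_k_sd * sdv
  below <- abs(dev) <= b_thr
  i_start <- integer(length(peaks))
  i_end <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    left <- p
    while (left > 1L && !below[left]) left <- left - 1L
    right <- p
    while (right < n && !below[right]) right <- right + 1L
    i_start[k] <- left
    i_end[k] <- right
  }
  # enforce disjoint events: trim overlaps at the inter-peak midpoint
  if (length(peaks) > 1L) {
    for (k in seq_len(length(peaks) - 1L)) {
      if (i_end[k] >= i_start[k + 1L]) {
        mid <- (peaks[k] + peaks[k + 1L]) %/% 2L
        i_end[k] <- mid
        i_start[k + 1L] <- mid + 1L
      }
    }
  }
  data.frame(
    t_peak_s = trace$t0_s + (peaks - 1) / fs,
    t_start_s = trace$t0_s + (i_start - 1) / fs,
    t_end_s = trace$t0_s + (i_end - 1) / fs,
    i_peak = peaks, i_start = i_start, i_end = i_end)
}

empty_events <- function() {
  data.frame(t_peak_s = numeric(0), t_start_s = numeric(0),
             t_end_s = numeric(0), i_peak = integer(0),
             i_start = integer(0), i_end = integer(0))
}

#' Per-event sharp wave-ripple metrics
#'
#' Populates each detected event with: amplitude (absolute slow-component
#' deviation from baseline at the peak, mV), duration
#' (boundary-to-boundary, ms), ripple count (local maxima of the
#' ripple-band component within the event window exceeding `ripple_k_sd`
#' SDs of the whole-trace ripple component), ripple frequency (reciprocal
#' of the median inter-peak interval of those maxima; 0 when fewer than
#' 2), and AUC (integral of the rectified slow deviation over the event
#' window, mV*ms).
#'
#' @param trace The same [lfp_trace()] passed to [detect_events()].
#' @param events The data.frame returned by [detect_events()].
#' @param params The same [spwr_detect_params()].
#' @return The events data.frame with columns `amplitude_mv`,
#'   `duration_ms`, `ripple_count`, `ripple_freq_hz`, `auc_mv_ms` added.
#' @export
event_metrics <- function(trace, events, params = spwr_detect_params()) {
  stopifnot(inherits(trace, "lfp_trace"), is.data.frame(events))
  n <- length(trace$samples)
  fs <- trace$fs_hz
  if (nrow(events) == 0L) {
    events$amplitude_mv <- numeric(0)
    events$duration_ms <- numeric(0)
    events$ripple_count <- integer(0)
    events$ripple_freq_hz <- numeric(0)
    events$auc_mv_ms <- numeric(0)
    return(events)
  }
  if (any(events$i_start < 1L) || any(events$i_end > n)) {
    stop("event window outside trace bounds", call. = FALSE)
  }
  slow <- fft_bandpass(trace, params$slow_band)$samples
  baseline <- stats::median(slow)
  dev <- slow - baseline
  ripple <- fft_bandpass(trace, params$ripple_band)$samples
  rip_thr <- params$ripple_k_sd * stats::sd(ripple)
  amplitude <- abs(dev[events$i_peak])
  duration <- (events$i_end - events$i_start) / fs * 1000
  ripple_count <- integer(nrow(events))
  ripple_freq <- numeric(nrow(events))
  auc <- numeric(nrow(events))
  for (k in seq_len(nrow(events))) {
    idx <- events$i_start[k]:events$i_end[k]
    seg <- ripple[idx]
    pk <- local_maxima(seg)
    pk <- pk[seg[pk] > rip_thr]
    ripple_count[k] <- length(pk)
    if (length(pk) >= 2L) {
      ipi_ms <- stats::median(diff(pk)) / fs * 1000
      ripple_freq[k] <- 1000 / ipi_ms
    }
    auc[k] <- sum(abs(dev[idx])) / fs * 1000
  }
  events$amplitude_mv <- amplitude
  events$duration_ms <- duration
  events$ripple_count <- ripple_count
  events$ripple_freq_hz <- ripple_freq
  events$auc_mv_ms <- auc
  events
}

#' Per-slice sharp wave-ripple summary with inclusion rule
#'
#' Medians of the per-event metrics plus incidence, and the slice
#' acceptance rule: a slice is accepted only when its events average more
#' than 0.04 mV in amplitude and occur at a rate of at least 1 Hz
#' (60/min).
#'
#' @param events Fully populated events from [event_metrics()].
#' @param recording_duration_s Recording duration in seconds.
#' @param min_amplitude_mv Acceptance threshold on the mean event
#'   amplitude (default 0.04 mV).
#' @param min_incidence_per_min Acceptance threshold on the event rate
#'   (default 60/min, i.e. 1 Hz).
#' @return An object of class `spwr_summary`: list with
#'   `incidence_per_min`, `median_amplitude_mv`, `median_duration_ms`,
#'   `median_ripple_freq_hz`, `median_ripples_per_event`,
#'   `median_auc_mv_ms`, `n_events`, `accepted`, `rejection_reason`
#'   (one of "none", "amplitude", "incidence", "both").
#' @export
summarize_slice <- function(events, recording_duration_s,
                            min_amplitude_mv = 0.04,
                            min_incidence_per_min = 60) {
  if (recording_duration_s <= 0) stop("duration must be > 0", call. = FALSE)
  n <- nrow(events)
  incidence <- n / (recording_duration_s / 60)
  med <- function(col) {
    if (n == 0L) NA_real_ else stats::median(events[[col]])
  }
  mean_amp <- if (n == 0L) 0 else mean(events$amplitude_mv)
  amp_ok <- mean_amp > min_amplitude_mv
  inc_ok <- incidence >= min_incidence_per_min
  reason <- if (amp_ok && inc_ok) "none"
  else if (!amp_ok && !inc_ok) "both"
  else if (!amp_ok) "amplitude"
  else "incidence"
  structure(
    list(incidence_per_min = incidence,
         median_amplitude_mv = med("amplitude_mv"),
         median_duration_ms = med("duration_ms"),
         median_ripple_freq_hz = med("ripple_freq_hz"),
         median_ripples_per_event = med("ripple_count"),
         median_auc_mv_ms = med("auc_mv_ms"),
         n_events = n,
         accepted = amp_ok && inc_ok,
         rejection_reason = reason),
    class = "spwr_summary")
}

#' @export
print.spwr_summary <- function(x, ...) {
  cat(sprintf(
    "<spwr_summary> %d events, %.1f/min, median amplitude %.3f mV [%s]\n",
    x$n_events, x$incidence_per_min, x$median_amplitude_mv,
    if (x$accepted) "accepted" else paste0("rejected: ", x$rejection_reason)))
  invisible(x)
}

#' Run detection, metrics and summary in one call
#'
#' @param trace An [lfp_trace()].
#' @param params An [spwr_detect_params()].
#' @return List with `events` (populated data.frame) and `summary`
#'   (an `spwr_summary`).
#' @export
analyze_spwr <- function(trace, params = spwr_detect_params()) {
  ev <- detect_events(trace, params)
  ev <- event_metrics(trace, ev, params)
  list(events = ev, summary = summarize_slice(ev, trace_duration_s(trace)))
}
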