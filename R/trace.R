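#' LFP trace container
#'
#' A uniformly sampled extracellular voltage series with its sampling rate
#' and recording metadata. All analysis functions in the package take and
#' return this container.
#'
#' @param samples Numeric vector of voltages in mV. Must be finite and of
#'   length at least 2.
#' @param fs_hz Sampling rate in samples per second (10000 for the
#'   interface-chamber recordings this package targets).
#' @param t0_s Start time of the first sample in seconds.
#' @param meta Named list of recording metadata. Recognised keys:
#'   `region` ("CA3"/"CA1"), `genotype` ("WT"/"TG"), `animal_id`,
#'   `slice_id`, `condition` ("spontaneous"/"carbachol"). Extra keys are
#'   carried along untouched.
#'
#' @return An object of class `lfp_trace`: a list with elements `samples`,
#'   `fs_hz`, `t0_s` and `meta`.
#' @export
lfp_trace <- function(samples, fs_hz, t0_s = 0, meta = list()) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("'samples' must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) ||
      fs_hz <= 0) {
    stop("'fs_hz' must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), meta = as.list(meta)),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  dur <- length(x$samples) / x$fs_hz
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs_hz, dur))
  m <- x$meta[!vapply(x$meta, is.null, logical(1))]
  if (length(m)) {
    cat("  meta:", paste(names(m), unlist(m, use.names = FALSE),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trace duration in seconds
#' @param trace An [lfp_trace()].
#' @return Duration in seconds (`n / fs_hz`).
#' @export
trace_duration_s <- function(trace) {
  stopifnot(inherits(trace, "lfp_trace"))
  length(trace$samples) / trace$fs_hz
}

#' Frequency band specification
#'
#' A half-open filtering band `[low_hz, high_hz]` used by [fft_bandpass()]
#' and the spectral peak search. The upper edge is validated against the
#' Nyquist frequency at application time, not here.
#'
#' @param low_hz Lower band edge in Hz (0 allowed; 0 keeps the DC bin).
#' @param high_hz Upper band edge in Hz; must exceed `low_hz`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      length(low_hz) != 1L || length(high_hz) != 1L ||
      !is.finite(low_hz) || !is.finite(high_hz)) {
    stop("band edges must be single finite numbers", call. = FALSE)
  }
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("band must satisfy 0 <= low_hz < high_hz", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

# Coerce c(low, high) shorthand; validate against Nyquist.
as_band <- function(band, fs_hz = NULL) {
  if (!inherits(band, "band_spec")) {
    if (is.numeric(band) && length(band) == 2L) {
      band <- band_spec(band[1], band[2])
    } else {
      stop("'band' must be a band_spec or numeric length-2 vector",
           call. = FALSE)
    }
  }
  if (!is.null(fs_hz) && band$high_hz > fs_hz / 2 + 1e-9) {
    stop(sprintf("band edge %g Hz exceeds Nyquist (%g Hz)",
                 band$high_hz, fs_hz / 2), call. = FALSE)
  }
  band
}
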