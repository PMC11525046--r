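# Regularly sampled signals (LFP, EMG) and the filtering primitives shared
# by the detectors and the sleep scorer.

#' Construct a sampled signal
#'
#' @param samples numeric vector (microvolts or a.u.).
#' @param rate_hz sampling rate, > 0.
#' @param t0_s time of the first sample on the session clock; sample `i`
#'   (0-based) occurs at `t0_s + i / rate_hz`.
#' @param label channel label, e.g. `"CA1-lfp"`, `"RSC-lfp"`, `"EMG"`.
#' @return a `sampled_signal` object.
#' @export
sampled_signal <- function(samples, rate_hz, t0_s = 0, label = "signal") {
  stopifnot(rate_hz > 0, length(samples) >= 1)
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 t0_s = t0_s, label = label),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal '%s' %d samples @ %g Hz, t0=%.3f s (%.1f s)>\n",
              x$label, length(x$samples), x$rate_hz, x$t0_s,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Sample times of a signal
#' @param sig a [sampled_signal()].
#' @return numeric vector of times (s), 0-based indexing.
#' @export
signal_times <- function(sig) {
  sig$t0_s + (seq_along(sig$samples) - 1) / sig$rate_hz
}

signal_end_s <- function(sig) sig$t0_s + length(sig$samples) / sig$rate_hz

#' Zero-phase Butterworth band filter
#'
#' 3rd-order Butterworth applied forward and backward
#' ([signal::filtfilt()]) so detected event times are not phase-delayed.
#' A `band[1]` of 0 gives a low-pass filter.
#'
#' @param sig a [sampled_signal()].
#' @param band numeric length-2 `(low_hz, high_hz)`.
#' @param order filter order (default 3).
#' @return a `sampled_signal` with filtered samples.
#' @export
bandpass <- function(sig, band, order = 3) {
  ny <- sig$rate_hz / 2
  if (band[2] >= ny)
    stop(sprintf("bandpass: upper edge %.1f Hz at/above Nyquist %.1f Hz",
                 band[2], ny))
  if (band[1] <= 0) {
    flt <- signal::butter(order, band[2] / ny, type = "low")
  } else {
    flt <- signal::butter(order, band / ny, type = "pass")
  }
  if (length(sig$samples) < 3 * (order * 3 + 1))
    stop("bandpass: signal shorter than filter warm-up")
  y <- signal::filtfilt(flt, sig$samples)
  sampled_signal(y, sig$rate_hz, sig$t0_s, paste0(sig$label, "-bp"))
}

# Band-filter, square, Gaussian-smooth, z-score: the normalised power trace
# every envelope detector thresholds.  smooth_sd_s = 0 skips smoothing.
normalized_band_power <- function(sig, band, smooth_sd_s = 0.004) {
  f <- bandpass(sig, band)
  p <- f$samples^2
  if (smooth_sd_s > 0) p <- gaussian_smooth(p, smooth_sd_s * sig$rate_hz)
  sampled_signal(zscore(p), sig$rate_hz, sig$t0_s, paste0(sig$label, "-nbp"))
}

# --- on-disk format: <label>.f32 raw little-endian float32 + JSON sidecar ---

#' Write a signal as raw float32 plus JSON sidecar
#'
#' @param sig a [sampled_signal()].
#' @param dir_path directory; files are `<label>.f32` and `<label>.json`.
#' @return invisibly, the `.f32` path.
#' @export
write_signal <- function(sig, dir_path) {
  base <- file.path(dir_path, sig$label)
  con <- file(paste0(base, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(sig$samples), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(rate_hz = sig$rate_hz, t0_s = sig$t0_s, units = "uV",
         label = sig$label),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".f32"))
}

#' Read a raw float32 signal with its JSON sidecar
#'
#' @param f32_path path to a `.f32` file; `<same>.json` must exist.
#' @return a [sampled_signal()].
#' @export
read_signal <- function(f32_path) {
  side <- sub("\\.f32$", ".json", f32_path)
  if (!file.exists(side))
    stop("read_signal: missing JSON sidecar for ", f32_path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- file.info(f32_path)$size / 4
  con <- file(f32_path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  sampled_signal(x, meta$rate_hz, meta$t0_s %||% 0,
                 meta$label %||% sub("\\.f32$", "", basename(f32_path)))
}
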