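# Spectrograms (STFT / Morlet), peri-event z-scored spectrograms, Welch
# PSDs, band-power ratios and wavelet power coherence.

#' Welch power spectral density
#'
#' Hann-windowed segments with 50% overlap; power normalised so the
#' integral over frequency approximates the signal variance.
#'
#' @param sig a [sampled_signal()].
#' @param window_s segment length (s), default 1.
#' @return list `(freq_hz, power)` (one-sided density, unit^2/Hz).
#' @export
welch_psd <- function(sig, window_s = 1) {
  x <- sig$samples - mean(sig$samples)
  n <- round(window_s * sig$rate_hz)
  if (n > length(x)) stop("welch_psd: window longer than signal")
  step <- floor(n / 2)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  starts <- seq(1, length(x) - n + 1, by = step)
  acc <- numeric(floor(n / 2) + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + n - 1)] * w
    p <- Mod(fft(seg))^2 / (sum(w^2) * sig$rate_hz)
    acc <- acc + p[seq_len(length(acc))]
  }
  p1 <- acc / length(starts)
  p1[2:(length(p1) - 1)] <- 2 * p1[2:(length(p1) - 1)]
  list(freq_hz = (seq_along(p1) - 1) * sig$rate_hz / n, power = p1)
}

morlet_transform <- function(sig, freqs_hz, n_cycles = 7) {
  x <- sig$samples - mean(sig$samples)
  n <- length(x)
  nf <- nextn(2 * n, 2)
  xf <- fft(c(x, rep(0, nf - n)))
  fs <- sig$rate_hz
  t_half <- (nf / 2)
  tt <- c(0:(t_half - 1), -(t_half):-1) / fs
  W <- matrix(0 + 0i, length(freqs_hz), n)
  for (k in seq_along(freqs_hz)) {
    f <- freqs_hz[k]
    sdt <- n_cycles / (2 * pi * f)
    wav <- exp(-tt^2 / (2 * sdt^2)) * exp(2i * pi * f * tt)
    wav <- wav / sqrt(sum(Mod(wav)^2))
    wf <- fft(wav)
    conv <- fft(xf * Conj(wf), inverse = TRUE) / nf
    W[k, ] <- conv[seq_len(n)]
  }
  W
}

#' Time-frequency power map
#'
#' STFT: Hann-windowed short-time Fourier power with unit-window
#' normalisation (total power matches time-domain variance).  Morlet:
#' wavelet scalogram with `n_cycles` cycles per frequency.
#'
#' @param sig a [sampled_signal()].
#' @param method `"stft"` or `"morlet"`.
#' @param window_s STFT window (s), default 0.5.
#' @param step_s STFT hop (s), default `window_s / 4`.
#' @param freqs_hz Morlet frequency grid.
#' @param n_cycles Morlet width, default 7.
#' @return a `tf_map`: list `(times_s, freqs_hz, power)` with power
#'   rows = frequencies.
#' @export
spectrogram <- function(sig, method = c("stft", "morlet"), window_s = 0.5,
                        step_s = NULL, freqs_hz = NULL, n_cycles = 7) {
  method <- match.arg(method)
  ny <- sig$rate_hz / 2
  if (!is.null(freqs_hz) && max(freqs_hz) >= ny)
    stop("spectrogram: requested frequency at/above Nyquist")
  if (method == "stft") {
    n <- round(window_s * sig$rate_hz)
    step <- round((step_s %||% (window_s / 4)) * sig$rate_hz)
    x <- sig$samples
    if (n > length(x)) stop("spectrogram: window longer than signal")
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    starts <- seq(1, length(x) - n + 1, by = step)
    n_keep <- floor(n / 2) + 1
    pow <- vapply(starts, function(s0) {
      seg <- x[s0:(s0 + n - 1)]
      p <- Mod(fft((seg - mean(seg)) * w))^2 / (n * sum(w^2) / n)
      p <- p[seq_len(n_keep)]
      p[2:(n_keep - 1)] <- 2 * p[2:(n_keep - 1)]
      p / n
    }, numeric(n_keep))
    freqs <- (seq_len(n_keep) - 1) * sig$rate_hz / n
    times <- sig$t0_s + (starts - 1 + n / 2) / sig$rate_hz
    sel <- if (is.null(freqs_hz)) seq_along(freqs) else
      which(freqs >= min(freqs_hz) & freqs <= max(freqs_hz))
    structure(list(times_s = times, freqs_hz = freqs[sel],
                   power = pow[sel, , drop = FALSE], method = "stft"),
              class = "tf_map")
  } else {
    if (is.null(freqs_hz)) freqs_hz <- exp(seq(log(2), log(ny * 0.8),
                                               length.out = 40))
    W <- morlet_transform(sig, freqs_hz, n_cycles)
    structure(list(times_s = signal_times(sig), freqs_hz = freqs_hz,
                   power = Mod(W)^2, method = "morlet"),
              class = "tf_map")
  }
}

#' Peri-event z-scored spectrogram
#'
#' Morlet power snippets around each anchor are z-scored per frequency
#' against the anchor's own baseline window, then averaged across anchors;
#' baseline rows therefore average to about zero.
#'
#' @param sig a [sampled_signal()].
#' @param anchors event times (s); anchors whose window leaves the signal
#'   are dropped.
#' @param window_s lag window, default `c(-1, 1)`.
#' @param baseline_s baseline lag window, default `c(-1, -0.5)`.
#' @param freqs_hz frequency grid (default 20 log-spaced up to 250 Hz).
#' @param n_cycles Morlet width.
#' @return a `tf_map` with lag times and the anchor-averaged z map.
#' @export
peri_event_spectrogram <- function(sig, anchors, window_s = c(-1, 1),
                                   baseline_s = c(-1, -0.5),
                                   freqs_hz = NULL, n_cycles = 7) {
  fs <- sig$rate_hz
  if (is.null(freqs_hz))
    freqs_hz <- exp(seq(log(2), log(min(250, fs / 2 * 0.9)),
                        length.out = 30))
  t_end <- signal_end_s(sig)
  anchors <- anchors[anchors + window_s[1] >= sig$t0_s &
                       anchors + window_s[2] < t_end]
  if (!length(anchors)) stop("peri_event_spectrogram: no valid anchors")
  P <- spectrogram(sig, "morlet", freqs_hz = freqs_hz, n_cycles = n_cycles)
  lag_idx <- round(window_s[1] * fs):round(window_s[2] * fs)
  lags_s <- lag_idx / fs
  bl <- lags_s >= baseline_s[1] & lags_s < baseline_s[2]
  acc <- matrix(0, length(freqs_hz), length(lag_idx))
  for (a in anchors) {
    c0 <- round((a - sig$t0_s) * fs) + 1L
    snip <- P$power[, c0 + lag_idx, drop = FALSE]
    mu <- rowMeans(snip[, bl, drop = FALSE])
    sdv <- apply(snip[, bl, drop = FALSE], 1, sd)
    sdv[sdv == 0] <- 1
    acc <- acc + (snip - mu) / sdv
  }
  structure(list(times_s = lags_s, freqs_hz = freqs_hz,
                 power = acc / length(anchors), method = "morlet-z",
                 baseline_s = baseline_s, n_events = length(anchors)),
            class = "tf_map")
}

#' Band-power ratio between two PSDs
#'
#' Integrated (trapezoidal) power of `psd_a` over `psd_b` per band; the
#' PSDs must share a frequency grid covering every band.
#'
#' @param psd_a,psd_b lists `(freq_hz, power)` (e.g. [welch_psd()]).
#' @param bands named list of `c(lo, hi)` (Hz); defaults to the delta,
#'   theta, spindle and ripple bands.
#' @return named numeric vector of ratios.
#' @export
band_power_ratio <- function(psd_a, psd_b,
                             bands = list(delta = c(1, 4), theta = c(6, 10),
                                          spindle = c(10, 20),
                                          ripple = c(140, 250))) {
  if (!isTRUE(all.equal(psd_a$freq_hz, psd_b$freq_hz)))
    stop("band_power_ratio: PSDs must share a frequency grid")
  f <- psd_a$freq_hz
  trapz_band <- function(p, band) {
    sel <- which(f >= band[1] & f <= band[2])
    if (length(sel) < 2) stop("band_power_ratio: band outside PSD grid")
    sum(diff(f[sel]) * (p[sel][-1] + p[sel][-length(sel)]) / 2)
  }
  vapply(bands, function(b) trapz_band(psd_a$power, b) /
           trapz_band(psd_b$power, b), numeric(1))
}

#' Wavelet magnitude-squared power coherence
#'
#' Morlet cross- and auto-spectra smoothed over time (Gaussian,
#' `smooth_cycles` cycles at each frequency) give
#' `|S(Wa conj(Wb))|^2 / (S|Wa|^2 S|Wb|^2)` in `[0, 1]`; coherence of a
#' signal with itself is 1 everywhere.
#'
#' @param sig_a,sig_b equal-rate [sampled_signal()]s.
#' @param freqs_hz frequency grid.
#' @param n_cycles Morlet width; `smooth_cycles` smoothing width.
#' @return a `tf_map` whose `power` holds coherence values.
#' @export
wavelet_coherence <- function(sig_a, sig_b, freqs_hz, n_cycles = 7,
                              smooth_cycles = 5) {
  if (sig_a$rate_hz != sig_b$rate_hz)
    stop("wavelet_coherence: sampling rates differ")
  Wa <- morlet_transform(sig_a, freqs_hz, n_cycles)
  Wb <- morlet_transform(sig_b, freqs_hz, n_cycles)
  fs <- sig_a$rate_hz
  coh <- matrix(0, length(freqs_hz), ncol(Wa))
  for (k in seq_along(freqs_hz)) {
    sdt <- smooth_cycles / freqs_hz[k] * fs
    sm <- function(v) gaussian_smooth(v, sdt)
    sxy_re <- sm(Re(Wa[k, ] * Conj(Wb[k, ])))
    sxy_im <- sm(Im(Wa[k, ] * Conj(Wb[k, ])))
    sxx <- sm(Mod(Wa[k, ])^2)
    syy <- sm(Mod(Wb[k, ])^2)
    coh[k, ] <- (sxy_re^2 + sxy_im^2) / pmax(sxx * syy, 1e-300)
  }
  structure(list(times_s = signal_times(sig_a), freqs_hz = freqs_hz,
                 power = pmin(coh, 1), method = "wavelet-coherence"),
            class = "tf_map")
}
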