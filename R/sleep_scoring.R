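# Vigilance-state scoring from hippocampal LFP and EMG.
#
# Wake is flagged where the z-scored EMG envelope passes a threshold;
# among immobile periods, REM is a high theta/delta ratio (>= 2) and NREM a
# low one (< 2).  Stages shorter than 30 s and 5-s windows around stage
# changes are relabelled "other" (transition).

#' z-scored EMG envelope
#'
#' Band-pass 20-150 Hz, rectified, Gaussian-smoothed (50 ms SD), z-scored
#' over the whole signal.
#'
#' @param emg a [sampled_signal()].
#' @param smooth_sd_s envelope smoothing SD (s), default 0.05.
#' @return a `sampled_signal` named `"EMG_z"` on the same grid.
#' @export
compute_emg_z <- function(emg, smooth_sd_s = 0.05) {
  if (sd(emg$samples) == 0)
    return(sampled_signal(rep(0, length(emg$samples)), emg$rate_hz,
                          emg$t0_s, "EMG_z"))
  hi <- min(150, emg$rate_hz / 2 - 1)
  f <- bandpass(emg, c(20, hi))
  env <- gaussian_smooth(abs(f$samples), smooth_sd_s * emg$rate_hz)
  sampled_signal(zscore(env), emg$rate_hz, emg$t0_s, "EMG_z")
}

# Band power in one short window: Hann-tapered, zero-padded periodogram
# (a 256-sample window at 1250 Hz has a raw resolution of ~4.9 Hz, so the
# 1-4 Hz band needs interpolated bins; the Hann taper keeps theta
# sidelobes out of the delta band).
window_band_power <- function(x, rate_hz, band, nfft = 2048) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- (x - mean(x)) * w
  nfft <- max(nfft, n)
  sp <- Mod(fft(c(xw, rep(0, nfft - n))))^2 / sum(w^2)
  freqs <- (0:(nfft - 1)) * rate_hz / nfft
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(sp[sel])
}

#' Theta/delta band-power ratio trace
#'
#' Ratio of 6-10 Hz to 1-4 Hz power computed in non-overlapping
#' 256-sample windows on the ratio-rate trace (the LFP is anti-alias
#' filtered and decimated to `ratio_rate_hz` first: 256 samples at 125 Hz
#' is a 2.05-s window, the shortest that resolves the 1-4 Hz band), then
#' Gaussian-smoothed on the window grid.
#'
#' @param lfp hippocampal [sampled_signal()], nominally at 1250 Hz.
#' @param window_samples window length in samples (default 256).
#' @param ratio_rate_hz working rate for the ratio (default 125); set to
#'   `lfp$rate_hz` to disable decimation.
#' @param smooth_sd_s smoothing SD in seconds applied on the window grid
#'   (default 5 s: stage continuity; a 50-ms kernel is inert on a 2-s
#'   window grid).
#' @return a `sampled_signal` on the window grid (one value per window,
#'   centred), rate `ratio_rate_hz / window_samples`.
#' @export
theta_delta_ratio <- function(lfp, window_samples = 256,
                              ratio_rate_hz = 125, smooth_sd_s = 5) {
  if (ratio_rate_hz < lfp$rate_hz) {
    dec <- round(lfp$rate_hz / ratio_rate_hz)
    aa <- signal::butter(4, 0.8 / dec, type = "low")
    y <- signal::filtfilt(aa, lfp$samples)
    lfp <- sampled_signal(y[seq(1, length(y), by = dec)],
                          lfp$rate_hz / dec, lfp$t0_s, lfp$label)
  }
  x <- lfp$samples
  if (length(x) < window_samples)
    stop("theta_delta_ratio: window longer than signal")
  n_win <- floor(length(x) / window_samples)
  idx <- matrix(seq_len(n_win * window_samples), nrow = window_samples)
  theta <- apply(idx, 2, function(i)
    window_band_power(x[i], lfp$rate_hz, c(6, 10)))
  delta <- apply(idx, 2, function(i)
    window_band_power(x[i], lfp$rate_hz, c(1, 4)))
  eps <- 1e-12
  ratio <- (theta + eps) / (delta + eps)
  win_rate <- lfp$rate_hz / window_samples
  ratio <- gaussian_smooth(ratio, smooth_sd_s * win_rate)
  sampled_signal(pmax(ratio, eps), win_rate,
                 lfp$t0_s + window_samples / (2 * lfp$rate_hz),
                 "theta_delta_ratio")
}

#' Score wake/NREM/REM/other states
#'
#' Per ratio-window: wake where `emg_z >= wake_threshold`; otherwise NREM
#' where the theta/delta ratio is below `ratio_threshold` and REM where it
#' is at or above it.  Stages shorter than `min_dur_s` become `"other"`,
#' and a `gap_s` window straddling each boundary between two different
#' remaining stages is also `"other"`.
#'
#' @param ratio theta/delta ratio trace ([theta_delta_ratio()]).
#' @param emg_z EMG envelope trace ([compute_emg_z()]); resampled onto the
#'   ratio grid by window averaging.
#' @param wake_threshold EMG_z wake threshold (SD units, default 0.5).
#' @param ratio_threshold REM/NREM split (default 2).
#' @param min_dur_s minimum stage duration (default 30 s).
#' @param gap_s transition window at stage changes (default 5 s).
#' @return hypnogram [interval_set()] (kind `"hypnogram"`, `state` column
#'   in `wake/nrem/rem/other`) tiling the scored span.
#' @export
score_states <- function(ratio, emg_z, wake_threshold = 0.5,
                         ratio_threshold = 2, min_dur_s = 30, gap_s = 5) {
  r <- ratio$samples
  if (all(is.na(r))) stop("score_states: all-NaN ratio")
  # mean EMG_z per ratio window
  step <- emg_z$rate_hz / ratio$rate_hz
  n <- length(r)
  t_win <- signal_times(ratio)
  e <- vapply(seq_len(n), function(i) {
    j0 <- max(1L, floor((i - 1) * step) + 1L)
    j1 <- min(length(emg_z$samples), floor(i * step))
    mean(emg_z$samples[j0:j1])
  }, numeric(1))

  lab <- ifelse(e >= wake_threshold, "wake",
                ifelse(r < ratio_threshold, "nrem", "rem"))
  rl <- rle(lab)
  dt <- 1 / ratio$rate_hz
  # stages shorter than min_dur_s -> other
  rl$values[rl$lengths * dt < min_dur_s] <- "other"
  rl <- rle(inverse.rle(rl))
  lab <- inverse.rle(rl)
  # transition windows at boundaries between two differing (non-other) stages
  ends <- cumsum(rl$lengths)
  half <- round(gap_s / 2 / dt)
  if (length(rl$values) > 1 && half > 0) {
    for (k in seq_len(length(rl$values) - 1)) {
      a <- rl$values[k]; b <- rl$values[k + 1]
      if (a != b && a != "other" && b != "other") {
        i0 <- max(1L, ends[k] - half + 1L)
        i1 <- min(length(lab), ends[k] + half)
        lab[i0:i1] <- "other"
      }
    }
  }
  rl <- rle(lab)
  en <- cumsum(rl$lengths)
  st <- c(0, en[-length(en)])
  t0 <- t_win[1] - dt / 2
  interval_set(t0 + st * dt, t0 + en * dt, "hypnogram", state = rl$values)
}

#' Intervals of one state from a hypnogram
#' @param hyp hypnogram [interval_set()] with a `state` column.
#' @param state state name (`"wake"`, `"nrem"`, `"rem"`, `"other"`).
#' @return [interval_set()] of that state's intervals.
#' @export
state_intervals <- function(hyp, state) {
  sel <- hyp$state == state
  if (!any(sel)) return(empty_intervals(if (state %in% INTERVAL_KINDS) state else "other"))
  interval_set(hyp$start_s[sel], hyp$end_s[sel],
               if (state %in% INTERVAL_KINDS) state else "other")
}

#' State firing-rate contrast
#'
#' `(FR_a - FR_b) / (FR_a + FR_b)` with firing rates measured inside the
#' hypnogram's `a` and `b` states; positive values mean the unit fires
#' faster in state `a`.  The NREM/wake ratio of the sleep analyses is
#' `state_rate_ratio(train, hyp, "nrem", "wake")`.
#'
#' @param train a [spike_train()].
#' @param hypnogram hypnogram [interval_set()].
#' @param a,b state names (default `"nrem"` vs `"wake"`).
#' @return a number in `[-1, 1]`, or `NA` when both rates are zero.
#' @export
state_rate_ratio <- function(train, hypnogram, a = "nrem", b = "wake") {
  iva <- state_intervals(hypnogram, a)
  ivb <- state_intervals(hypnogram, b)
  da <- interval_duration(iva); db <- interval_duration(ivb)
  if (da <= 0 || db <= 0)
    stop("state_rate_ratio: both states must be present with nonzero duration")
  fa <- length(restrict(train, iva)$times_s) / da
  fb <- length(restrict(train, ivb)$times_s) / db
  if (fa + fb == 0) return(NA_real_)
  (fa - fb) / (fa + fb)
}
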