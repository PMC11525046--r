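# Offline detection of ripples, sharp waves, SWRs, delta waves, spindles,
# SWR-cortical pairs, SWR size classes, OFF periods and ripple features.
#
# Envelope detectors share one normalisation: band-pass, square, smooth
# with a short Gaussian, z-score ("normalised band power").  Thresholds are
# in SD units of that trace.

# Contiguous runs where cond is TRUE -> (start index, end index) pairs.
true_runs <- function(cond) {
  r <- rle(cond)
  en <- cumsum(r$lengths)
  st <- c(1L, head(en, -1) + 1L)
  cbind(start = st[r$values], end = en[r$values])
}

# Segment an already-normalised power trace by envelope threshold, merge
# nearby segments, then apply duration and peak criteria.
threshold_events <- function(z_sig, thr_env, thr_peak, dur_s, merge_gap_s,
                             kind, max_merged_s = Inf) {
  z <- z_sig$samples; fs <- z_sig$rate_hz; t0 <- z_sig$t0_s
  runs <- true_runs(z > thr_env)
  if (nrow(runs) == 0) return(empty_intervals(kind))
  st <- t0 + (runs[, 1] - 1) / fs
  en <- t0 + runs[, 2] / fs
  pk_idx <- vapply(seq_len(nrow(runs)), function(i) {
    j <- runs[i, 1]:runs[i, 2]; j[which.max(z[j])]
  }, numeric(1))
  ev <- interval_set(st, en, kind, peak_s = t0 + (pk_idx - 1) / fs,
                     peak_score = z[pk_idx])
  ev <- merge_intervals(ev, merge_gap_s)
  dur <- ev$end_s - ev$start_s
  keep <- dur >= dur_s[1] & dur <= dur_s[2] & ev$peak_score > thr_peak &
    dur <= max_merged_s
  interval_set(ev$start_s[keep], ev$end_s[keep], kind,
               peak_s = ev$peak_s[keep], peak_score = ev$peak_score[keep])
}

#' Detect hippocampal ripples (or cortical ripple-like events)
#'
#' The band-passed LFP is squared, lightly smoothed and z-scored, yielding
#' R(t).  Events where R(t) stays above `thr_env` for 15-200 ms and peaks
#' above `thr_peak` are kept; events separated by less than `merge_gap` s
#' are merged before the duration test.
#'
#' @param lfp a [sampled_signal()] (CA1 for ripples, RSC for ripple-likes).
#' @param band frequency band, default `c(140, 250)` Hz.
#' @param thr_env sustained envelope threshold (SD), default 1.
#' @param thr_peak peak threshold (SD), default 4.
#' @param dur allowed duration range (s), default `c(0.015, 0.200)`.
#' @param merge_gap merge gap (s), default 0.020.
#' @param smooth_sd_s envelope smoothing SD (s), default 0.0125.
#' @return [interval_set()] of kind `"ripple"` with peak times and scores.
#' @export
detect_ripples <- function(lfp, band = c(140, 250), thr_env = 1, thr_peak = 4,
                           dur = c(0.015, 0.200), merge_gap = 0.020,
                           smooth_sd_s = 0.0125) {
  z <- normalized_band_power(lfp, band, smooth_sd_s)
  threshold_events(z, thr_env, thr_peak, dur, merge_gap, "ripple")
}

#' Detect sharp waves
#'
#' The 5-40 Hz filtered, z-scored CA1 LFP (averaged across channels when
#' several are given) is scanned for single-polarity excursions exceeding
#' `thr` SD for 20-400 ms.  The default polarity is negative (the radiatum
#' sharp-wave deflection); `polarity = "abs"` thresholds the absolute
#' excursion instead.
#'
#' @param lfp_channels one [sampled_signal()] or a list of them.
#' @param band filter band (Hz), default `c(5, 40)`.
#' @param thr excursion threshold (SD), default 2.5.
#' @param dur duration range (s), default `c(0.020, 0.400)`.
#' @param merge_gap optional gap (s) under which successive excursions are
#'   treated as one candidate; default 0 (no merging).
#' @param polarity deflection sign to threshold (`"negative"` default).
#' @return [interval_set()] of kind `"sharp_wave"`.
#' @export
detect_sharp_waves <- function(lfp_channels, band = c(5, 40), thr = 2.5,
                               dur = c(0.020, 0.400), merge_gap = 0,
                               polarity = c("negative", "positive", "abs")) {
  polarity <- match.arg(polarity)
  if (inherits(lfp_channels, "sampled_signal")) lfp_channels <- list(lfp_channels)
  avg <- Reduce(`+`, lapply(lfp_channels, `[[`, "samples")) / length(lfp_channels)
  sig <- sampled_signal(avg, lfp_channels[[1]]$rate_hz,
                        lfp_channels[[1]]$t0_s, "CA1-mean")
  z <- zscore(bandpass(sig, band)$samples)
  z <- switch(polarity, negative = -z, positive = z, abs = abs(z))
  z_sig <- sampled_signal(z, sig$rate_hz, sig$t0_s, "sw-z")
  threshold_events(z_sig, thr, thr, dur, merge_gap, "sharp_wave")
}

#' Pair ripples with sharp waves into SWRs
#'
#' A ripple becomes an SWR only if it temporally overlaps a sharp wave and
#' lies inside `valid_states` (NREM in sleep, immobility in task).  The
#' SWR keeps the ripple's onset, peak and score.
#'
#' @param ripples,sharp_waves [interval_set()]s from the same session.
#' @param valid_states [interval_set()] of eligible states; `NULL` skips
#'   the state gate.
#' @return [interval_set()] of kind `"swr"`.
#' @export
pair_swr <- function(ripples, sharp_waves, valid_states = NULL) {
  if (nrow(ripples) == 0) return(empty_intervals("swr"))
  overlaps <- vapply(seq_len(nrow(ripples)), function(i) {
    any(sharp_waves$start_s < ripples$end_s[i] &
          sharp_waves$end_s > ripples$start_s[i])
  }, logical(1))
  keep <- overlaps
  if (!is.null(valid_states) && nrow(ripples))
    keep <- keep & in_intervals(ripples$peak_s, valid_states)
  interval_set(ripples$start_s[keep], ripples$end_s[keep], "swr",
               peak_s = ripples$peak_s[keep],
               peak_score = ripples$peak_score[keep])
}

#' Detect cortical delta waves
#'
#' The RSC LFP is low-passed below 4 Hz and z-scored, giving D(t).
#' Candidate waves are positive lobes between upward and downward
#' zero-crossings; the wave's end is the following trough.  A candidate is
#' kept when it lasts 150-450 ms and satisfies either amplitude clause:
#' `D(peak) > 2` with `D(end) <= 0`, or `D(peak) > 1` with
#' `D(end) < -1.5`.
#'
#' @param lfp_rsc RSC [sampled_signal()].
#' @param band low-pass band, default `c(0, 4)` Hz.
#' @param dur duration range onset-to-trough (s), default `c(0.150, 0.450)`.
#' @param thr_peak,thr_peak2,thr_end2 clause thresholds (SD), defaults
#'   2, 1 and -1.5.
#' @return [interval_set()] of kind `"delta"`; `peak_s`/`peak_score` give
#'   the positive peak.
#' @export
detect_delta <- function(lfp_rsc, band = c(0, 4), dur = c(0.150, 0.450),
                         thr_peak = 2, thr_peak2 = 1, thr_end2 = -1.5) {
  f <- bandpass(lfp_rsc, band)
  d <- zscore(f$samples)
  fs <- lfp_rsc$rate_hz; t0 <- lfp_rsc$t0_s
  pos <- true_runs(d > 0)
  if (nrow(pos) == 0) return(empty_intervals("delta"))
  st <- en <- pk <- sc <- numeric(0)
  for (i in seq_len(nrow(pos))) {
    a <- pos[i, 1]; b <- pos[i, 2]
    if (b >= length(d)) next                      # no following trough
    j <- a:b
    ipk <- j[which.max(d[j])]
    # end = trough of the following negative lobe
    b2 <- if (i < nrow(pos)) pos[i + 1, 1] - 1L else length(d)
    j2 <- (b + 1L):b2
    iend <- j2[which.min(d[j2])]
    dur_i <- (iend - a) / fs
    ok1 <- d[ipk] > thr_peak && d[iend] <= 0
    ok2 <- d[ipk] > thr_peak2 && d[iend] < thr_end2
    if (dur_i >= dur[1] && dur_i <= dur[2] && (ok1 || ok2)) {
      st <- c(st, t0 + (a - 1) / fs)
      en <- c(en, t0 + iend / fs)
      pk <- c(pk, t0 + (ipk - 1) / fs)
      sc <- c(sc, d[ipk])
    }
  }
  interval_set(st, en, "delta", peak_s = pk, peak_score = sc)
}

#' Detect sleep spindles
#'
#' The 10-20 Hz filtered RSC LFP is squared, smoothed and z-scored
#' (S(t)).  Segments where S(t) exceeds `thr_env` are merged when closer
#' than `merge_gap` s; merged events must last more than `min_dur` s, peak
#' above `thr_peak`, and merged events longer than `max_merged` s are
#' discarded.
#'
#' @param lfp_rsc RSC [sampled_signal()].
#' @param band spindle band (Hz), default `c(10, 20)`.
#' @param thr_env sustained threshold (SD), default 2.5.
#' @param min_dur minimum duration (s), default 0.5.
#' @param thr_peak peak threshold (SD), default 5.
#' @param merge_gap merge gap (s), default 0.4.
#' @param max_merged maximum merged duration (s), default 3.
#' @param smooth_sd_s envelope smoothing SD (s), default 0.025.
#' @return [interval_set()] of kind `"spindle"`.
#' @export
detect_spindles <- function(lfp_rsc, band = c(10, 20), thr_env = 2.5,
                            min_dur = 0.5, thr_peak = 5, merge_gap = 0.4,
                            max_merged = 3, smooth_sd_s = 0.025) {
  z <- normalized_band_power(lfp_rsc, band, smooth_sd_s)
  ev <- threshold_events(z, thr_env, thr_peak, c(min_dur, Inf), merge_gap,
                         "spindle", max_merged_s = max_merged)
  ev
}

#' Pair SWRs with following cortical events
#'
#' Keeps (SWR, cortical) pairs whose cortical peak falls 0-250 ms after
#' the SWR peak; each cortical event is assigned to its nearest preceding
#' qualifying SWR only.
#'
#' @param swrs SWR [interval_set()] (with `peak_s`).
#' @param cortical delta or spindle [interval_set()] (with `peak_s`).
#' @param window lag window (s), default `c(0, 0.250)`; the pairing rule is
#'   `0 < lag <= window[2]`.
#' @return data.frame `(swr_idx, cortical_idx, swr_peak_s, cortical_peak_s,
#'   lag_s)`.
#' @export
pair_sequences <- function(swrs, cortical, window = c(0, 0.250)) {
  out <- data.frame(swr_idx = integer(0), cortical_idx = integer(0),
                    swr_peak_s = numeric(0), cortical_peak_s = numeric(0),
                    lag_s = numeric(0))
  if (nrow(swrs) == 0 || nrow(cortical) == 0) return(out)
  sp <- swrs$peak_s
  for (j in seq_len(nrow(cortical))) {
    cp <- cortical$peak_s[j]
    prev <- which(sp < cp)
    if (!length(prev)) next
    i <- prev[which.max(sp[prev])]
    lag <- cp - sp[i]
    if (lag > window[1] && lag <= window[2])
      out <- rbind(out, data.frame(swr_idx = i, cortical_idx = j,
                                   swr_peak_s = sp[i], cortical_peak_s = cp,
                                   lag_s = lag))
  }
  out
}

#' Stratify SWRs by ripple peak amplitude
#'
#' @param swrs SWR [interval_set()] with `peak_score`.
#' @param thr size thresholds (SD), ascending, default `c(4, 6, 10)`:
#'   large > 10, medium > 6, small > 4.
#' @return character vector (`"small"`, `"medium"`, `"large"`, or `NA` for
#'   events at/below the small threshold) aligned with `swrs` rows.
#' @export
classify_swr_size <- function(swrs, thr = c(4, 6, 10)) {
  stopifnot(all(diff(thr) > 0))
  if (is.null(swrs$peak_score)) stop("classify_swr_size: peak_score missing")
  p <- swrs$peak_score
  out <- rep(NA_character_, length(p))
  out[p > thr[1]] <- "small"
  out[p > thr[2]] <- "medium"
  out[p > thr[3]] <- "large"
  out
}

#' Detect cortical OFF periods
#'
#' Maximal intervals with zero spikes pooled across RSC units, longer than
#' `min_gap` s; OFF periods separated by less than `merge_gap` s are
#' merged.  Sessions with fewer than `min_units` RSC units are skipped.
#'
#' @param rsc_trains list of RSC [spike_train()]s.
#' @param min_units minimum RSC unit count, default 5.
#' @param min_gap minimum silence (s), default 0.100.
#' @param merge_gap merge gap (s), default 0.005.
#' @param span optional `c(t0, t1)` analysis span; defaults to the pooled
#'   spike range.
#' @return [interval_set()] of kind `"off_period"`, or `NULL` (with a
#'   logged reason) when too few units are available.
#' @export
detect_off_periods <- function(rsc_trains, min_units = 5, min_gap = 0.100,
                               merge_gap = 0.005, span = NULL) {
  if (length(rsc_trains) < min_units) {
    swr_log(sprintf("detect_off_periods: only %d RSC units (< %d), skipped",
                    length(rsc_trains), min_units))
    return(NULL)
  }
  pooled <- sort(unlist(lapply(rsc_trains, `[[`, "times_s")))
  if (!is.null(span)) pooled <- c(span[1], pooled[pooled >= span[1] & pooled <= span[2]], span[2])
  if (length(pooled) < 2) return(empty_intervals("off_period"))
  gaps <- diff(pooled)
  sel <- which(gaps > min_gap)
  ivs <- interval_set(pooled[sel], pooled[sel + 1], "off_period")
  if (nrow(ivs) > 1) ivs <- merge_intervals(ivs, merge_gap)
  ivs
}

#' Per-event ripple features
#'
#' @param ripples ripple/SWR [interval_set()].
#' @param analyzed_s analysed NREM duration in seconds (for the rate).
#' @return list with `table` (duration_s, peak_norm_power per event),
#'   `rate_per_min`, and `n`.
#' @export
ripple_features <- function(ripples, analyzed_s) {
  tab <- data.frame(duration_s = ripples$end_s - ripples$start_s,
                    peak_norm_power = ripples$peak_score %||%
                      rep(NA_real_, nrow(ripples)))
  list(table = tab, rate_per_min = nrow(ripples) / (analyzed_s / 60),
       n = nrow(ripples))
}
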