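# Synthetic session generator with full ground truth.
#
# Sleep sessions: state-switching LFP (1/f background plus state-dependent
# oscillations and inserted ripple/sharp-wave/delta/spindle events with
# known times and amplitudes in detector SD units), EMG with wake bursts,
# and spike trains from an inhomogeneous Poisson process whose rate is
# baseline x state factor x peri-SWR kernel x coupling/assembly terms.
# Task sessions: figure-eight maze trajectories with place/trial-type/speed
# tuning and a cross-region co-firing assembly expressed during running.

#' Default sleep-session generator configuration
#'
#' All values are generator assumptions (no recorded-data estimates):
#' amplitudes are in detector SD units, rates in Hz, durations in seconds.
#'
#' @param ... overrides merged into the defaults by name.
#' @return a named list.
#' @export
sleep_config <- function(...) {
  cfg <- list(
    duration_s = 600,
    rate_hz = 1250,
    emg_rate_hz = 1250,
    # state dwell ranges (s); sequence cycles wake -> nrem -> rem
    state_plan = "cycle",
    wake_dwell = c(60, 90), nrem_dwell = c(150, 240), rem_dwell = c(40, 70),
    # LFP background
    bg_alpha = 1,
    theta_hz = 7.5, rem_theta_amp = 2.0, wake_theta_amp = 0.8,
    nrem_slow_amp = 1.5,
    emg_wake_gain = 4, emg_burst_gain = 8, emg_burst_rate = 0.2,
    # inserted events: counts are per 10 min of NREM
    n_ripples = 60, ripple_hz = 180, ripple_amp_sd = 6,
    ripple_dur = c(0.040, 0.100), ripple_min_sep = 0.8,
    sharp_wave_amp_sd = 4.5, sharp_wave_dur = c(0.060, 0.150),
    n_delta = 80, delta_amp_sd = 5.5, delta_pos_dur = c(0.14, 0.22),
    delta_neg_dur = c(0.10, 0.18), delta_min_sep = 1.0,
    n_spindles = 30, spindle_hz = 13, spindle_amp_sd = 6,
    spindle_dur = c(0.85, 0.95), spindle_min_sep = 3.0,
    # spike trains
    n_ca1 = 12, n_rsc = 12,
    ca1_rate = c(1, 4), rsc_rate = c(1.5, 5),
    state_factor = c(wake = 1.1, nrem = 1.0, rem = 0.9, other = 1.0),
    # peri-SWR modulation kernels (multiplicative Gaussian bumps in lag)
    ca1_kernel = list(center = 0.030, sd = 0.030, gain = 3),
    rsc_kernel = list(center = -0.050, sd = 0.020, gain = 2),
    # per-SWR latent excitability (gamma, mean 1) and directional coupling
    event_gain_shape = 2,
    coupling = list(direction = "none", strength = 0),
    # cross-region assembly reactivated at SWRs
    assembly = list(n_pairs = 0, strength = 0, window_s = 0.05),
    # OFF periods carved into RSC trains (0 = none)
    n_off = 0, off_dur = c(0.12, 0.30), off_lag_s = NULL,
    make_lfp = TRUE,
    seed_margin_s = 1.6)
  modifyList(cfg, list(...))
}

runif_range <- function(n, r) runif(n, r[1], r[2])

# Place n event times inside the interval union, >= margin from interval
# edges and >= min_sep apart; rejection sampling.
place_event_times <- function(n, ivs, min_sep, margin) {
  st <- ivs$start_s + margin; en <- ivs$end_s - margin
  keep <- en > st
  st <- st[keep]; en <- en[keep]
  if (!length(st) || n == 0) return(numeric(0))
  w <- en - st
  out <- numeric(0)
  for (tries in seq_len(200 * n)) {
    if (length(out) >= n) break
    seg <- sample.int(length(w), 1, prob = w)
    t <- runif(1, st[seg], en[seg])
    if (!length(out) || min(abs(out - t)) >= min_sep) out <- c(out, t)
  }
  if (length(out) < n)
    warning(sprintf("place_event_times: placed %d of %d events", length(out), n))
  sort(out)
}

# Add a windowed waveform to x (in place semantics via return).
add_waveform <- function(x, fs, t_start, wf) {
  i0 <- round(t_start * fs) + 1L
  idx <- i0:(i0 + length(wf) - 1L)
  ok <- idx >= 1 & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + wf[ok]
  x
}

ripple_waveform <- function(fs, dur, hz) {
  t <- seq(0, dur, by = 1 / fs)
  sin(2 * pi * hz * t) * exp(-0.5 * ((t - dur / 2) / (dur / 5))^2)
}

# Half-sine deflection pre-shaped by the detection band-pass so the
# inserted pulse (rebound lobes included) is what the detector's filter
# returns; padded so filtfilt start-up transients stay inside the window.
sharp_wave_waveform <- function(fs, dur) {
  pad <- round(0.3 * fs)
  t <- seq(0, dur, by = 1 / fs)
  w <- c(numeric(pad), -sin(pi * t / dur), numeric(pad))
  flt <- signal::butter(3, c(5, 40) / (fs / 2), "pass")
  wf <- signal::filtfilt(flt, w)
  wf / max(abs(wf))
}

# Down-up-down delta wave: a small leading trough pins the onset
# zero-crossing to the wave itself, then the positive peak and the
# following trough carry the detection clauses.
delta_waveform <- function(fs, d_pos, d_neg, neg_frac = 0.6,
                           lead_dur = 0.09, lead_frac = 0.35) {
  t0 <- seq(0, lead_dur, by = 1 / fs)
  t1 <- seq(1 / fs, d_pos, by = 1 / fs)
  t2 <- seq(1 / fs, d_neg, by = 1 / fs)
  c(-lead_frac * sin(pi * t0 / lead_dur),
    sin(pi * t1 / d_pos), -neg_frac * sin(pi * t2 / d_neg))
}

# Waxing-waning spindle; the square-root half-sine envelope rises fast
# and stays near its crest, so the sustained-power criterion is met
# without the event dominating the band's variance budget.
spindle_waveform <- function(fs, dur, hz) {
  t <- seq(0, dur, by = 1 / fs)
  sin(2 * pi * hz * t) * sqrt(sin(pi * t / dur))
}

# Measure achieved detector-SD amplitude at given times on a transform
# trace and return per-event z.
measured_z <- function(z_sig, t_peaks, halfwin_s = 0.05) {
  fs <- z_sig$rate_hz
  vapply(t_peaks, function(tp) {
    i <- round((tp - z_sig$t0_s) * fs) + 1L
    j <- max(1L, i - round(halfwin_s * fs)):min(length(z_sig$samples),
                                                i + round(halfwin_s * fs))
    max(abs(z_sig$samples[j]))
  }, numeric(1))
}

build_state_sequence <- function(cfg) {
  if (is.data.frame(cfg$state_plan)) {
    df <- cfg$state_plan
  } else {
    states <- c("wake", "nrem", "rem")
    dwells <- list(wake = cfg$wake_dwell, nrem = cfg$nrem_dwell,
                   rem = cfg$rem_dwell)
    st <- character(0); du <- numeric(0); tot <- 0; k <- 1
    while (tot < cfg$duration_s) {
      s <- states[(k - 1) %% 3 + 1]
      d <- runif_range(1, dwells[[s]])
      d <- min(d, cfg$duration_s - tot)
      st <- c(st, s); du <- c(du, d); tot <- tot + d; k <- k + 1
    }
    df <- data.frame(state = st, dur_s = du)
  }
  en <- cumsum(df$dur_s)
  interval_set(c(0, head(en, -1)), en, "hypnogram", state = df$state)
}

#' Simulate a sleep session with ground truth
#'
#' @param cfg a [sleep_config()].  With `make_lfp = FALSE` the LFP/EMG
#'   composition and amplitude calibration are skipped (event times,
#'   states and spike trains only), which is much faster for analyses
#'   that never read the signals.
#' @param seed integer seed; same seed, same output.
#' @return list with `session` (a [session()]) and `truth` (state
#'   sequence, true event intervals with calibrated detector-SD peaks,
#'   per-unit parameters, per-SWR latent gains, assembly spec).
#' @export
simulate_sleep_session <- function(cfg = sleep_config(), seed = 1) {
  set.seed(child_seed(seed, "sleep"))
  fs <- cfg$rate_hz
  n <- round(cfg$duration_s * fs)
  hyp <- build_state_sequence(cfg)
  nrem <- state_intervals(hyp, "nrem")
  t_axis <- (seq_len(n) - 1) / fs

  # ---- LFP backgrounds -------------------------------------------------
  make_lfp <- isTRUE(cfg$make_lfp %||% TRUE)
  if (make_lfp) {
  ca1 <- stabilized_pink_noise(n, cfg$bg_alpha, fs)
  rsc <- stabilized_pink_noise(n, cfg$bg_alpha, fs)
  rsc <- stabilize_band(rsc, c(0.3, 4), fs, env_sd_s = 1.0)
  # state-dependent theta
  theta_amp <- numeric(n)
  for (i in seq_len(nrow(hyp))) {
    amp <- switch(hyp$state[i], rem = cfg$rem_theta_amp,
                  wake = cfg$wake_theta_amp, 0)
    if (amp > 0) {
      j <- (round(hyp$start_s[i] * fs) + 1L):min(n, round(hyp$end_s[i] * fs))
      theta_amp[j] <- amp
    }
  }
  theta_amp <- gaussian_smooth(theta_amp, 0.25 * fs)   # soften state edges
  theta <- theta_amp * sin(2 * pi * cfg$theta_hz * t_axis + runif(1, 0, 2 * pi))
  ca1 <- ca1 + theta
  rsc <- rsc + 0.3 * theta
  } else {
    # keep the RNG stream aligned with nothing: spikes-only sessions draw
    # event times and spikes from the same seeded stream
    ca1 <- rsc <- NULL
  }
  if (make_lfp) {
  # continuous large irregular slow activity in CA1 during NREM
  if (cfg$nrem_slow_amp > 0 && nrow(nrem) > 0) {
    slow <- bandpass(sampled_signal(pink_noise(n, 1, fs), fs, 0, "slow"),
                     c(0.5, 3))$samples
    slow <- slow / sd(slow)
    gate <- numeric(n)
    gate[in_intervals(t_axis, nrem)] <- 1
    gate <- gaussian_smooth(gate, 0.25 * fs)
    ca1 <- ca1 + cfg$nrem_slow_amp * gate * slow
  }
  }

  # ---- event times -----------------------------------------------------
  ripple_t <- place_event_times(cfg$n_ripples, nrem, cfg$ripple_min_sep,
                                cfg$seed_margin_s)
  delta_t <- place_event_times(cfg$n_delta, nrem, cfg$delta_min_sep,
                               cfg$seed_margin_s)
  spindle_t <- place_event_times(cfg$n_spindles, nrem, cfg$spindle_min_sep,
                                 cfg$seed_margin_s)

  rip_dur <- runif_range(length(ripple_t), cfg$ripple_dur)
  sw_dur <- runif_range(length(ripple_t), cfg$sharp_wave_dur)
  del_pos <- runif_range(length(delta_t), cfg$delta_pos_dur)
  del_neg <- runif_range(length(delta_t), cfg$delta_neg_dur)
  spi_dur <- runif_range(length(spindle_t), cfg$spindle_dur)

  if (make_lfp) {
  # During an event, the event IS the channel's content in its band: the
  # background's in-band component is suppressed inside event windows so
  # that the inserted waveform sets the local band amplitude.
  suppress_band <- function(bg, band, starts, ends, depth = 0.97,
                            taper_s = 0.010) {
    if (!length(starts)) return(bg)
    w <- numeric(length(bg))
    i0 <- pmax(1L, round(starts * fs)); i1 <- pmin(length(bg), round(ends * fs))
    for (k in seq_along(i0)) w[i0[k]:i1[k]] <- depth
    w <- gaussian_smooth(w, taper_s * fs)
    bg - w * bandpass(sampled_signal(bg, fs, 0, "b"), band)$samples
  }
  ca1 <- suppress_band(ca1, c(140, 250), ripple_t - rip_dur / 2 - 0.01,
                       ripple_t + rip_dur / 2 + 0.01)
  ca1 <- suppress_band(ca1, c(5, 40), ripple_t - sw_dur / 2 - 0.15,
                       ripple_t + sw_dur / 2 + 0.15)
  rsc <- suppress_band(rsc, c(0.3, 4), delta_t - 0.30,
                       delta_t + del_pos + del_neg + 0.15, taper_s = 0.05)
  rsc <- suppress_band(rsc, c(10, 20), spindle_t - spi_dur / 2 - 0.05,
                       spindle_t + spi_dur / 2 + 0.05)

  # two-pass amplitude calibration against each detector transform
  compose <- function(bg, times, durs, wf_fun, amps, center = TRUE) {
    x <- bg
    for (k in seq_along(times)) {
      wf <- wf_fun(k)
      t0 <- if (center) times[k] - (length(wf) - 1) / fs / 2 else times[k]
      x <- add_waveform(x, fs, t0, amps[k] * wf)
    }
    x
  }
  # Amplitudes are set so that each event's own contribution to the
  # detector trace reaches `target` in SD units of the composite signal:
  # the isolated-event trace (events on a zero background) is measured
  # against the composite trace's scale, which decouples calibration from
  # local background fluctuations and converges in a few passes.
  calibrate <- function(bg, times, durs, wf_fun, target, raw_transform, expo,
                        center = TRUE, measure_t = times) {
    if (!length(times)) return(list(x = bg, amp = numeric(0), z = numeric(0)))
    amps <- rep(1, length(times))
    zero <- numeric(length(bg))
    for (pass in 1:4) {
      x <- compose(bg, times, durs, wf_fun, amps, center)
      comp <- raw_transform(x)
      iso <- raw_transform(compose(zero, times, durs, wf_fun, amps, center))
      sigma <- sd(comp$samples)
      mu <- mean(comp$samples)
      peak_iso <- measured_z(sampled_signal(iso$samples, fs, 0, "iso"),
                             measure_t)
      z_iso <- (peak_iso - mu) / sigma
      amps <- amps * (target / pmax(z_iso, 0.05))^expo
    }
    x <- compose(bg, times, durs, wf_fun, amps, center)
    comp <- raw_transform(x)
    z_sig <- sampled_signal(zscore(comp$samples), fs, 0, "z")
    list(x = x, amp = amps, z = measured_z(z_sig, measure_t))
  }

  raw_power <- function(band, sm) function(x) {
    f <- bandpass(sampled_signal(x, fs, 0, "s"), band)
    sampled_signal(gaussian_smooth(f$samples^2, sm * fs), fs, 0, "p")
  }
  rip_tf <- raw_power(c(140, 250), 0.0125)
  spi_tf <- raw_power(c(10, 20), 0.025)
  sw_tf <- function(x) {
    f <- bandpass(sampled_signal(x, fs, 0, "ca1"), c(5, 40))
    f
  }
  del_tf <- function(x) {
    f <- bandpass(sampled_signal(x, fs, 0, "rsc"), c(0, 4))
    sampled_signal(f$samples, fs, 0, "d")
  }

  cal_sw <- calibrate(ca1, ripple_t, sw_dur,
                      function(k) sharp_wave_waveform(fs, sw_dur[k]),
                      cfg$sharp_wave_amp_sd, sw_tf, 1)
  cal_rip <- calibrate(cal_sw$x, ripple_t, rip_dur,
                       function(k) ripple_waveform(fs, rip_dur[k], cfg$ripple_hz),
                       cfg$ripple_amp_sd, rip_tf, 0.5)
  ca1_final <- cal_rip$x
  cal_del <- calibrate(rsc, delta_t, del_pos,
                       function(k) delta_waveform(fs, del_pos[k], del_neg[k]),
                       cfg$delta_amp_sd, del_tf, 1, center = FALSE,
                       measure_t = delta_t + 0.09 + del_pos / 2)
  cal_spi <- calibrate(cal_del$x, spindle_t, spi_dur,
                       function(k) spindle_waveform(fs, spi_dur[k], cfg$spindle_hz),
                       cfg$spindle_amp_sd, spi_tf, 0.5)
  rsc_final <- cal_spi$x

  # ---- EMG -------------------------------------------------------------
  ne <- round(cfg$duration_s * cfg$emg_rate_hz)
  emg_bg <- bandpass(sampled_signal(rnorm(ne), cfg$emg_rate_hz, 0, "w"),
                     c(20, min(150, cfg$emg_rate_hz / 2 - 1)))$samples
  gain <- rep(1, ne)
  te <- (seq_len(ne) - 1) / cfg$emg_rate_hz
  wake <- state_intervals(hyp, "wake")
  gain[in_intervals(te, wake)] <- cfg$emg_wake_gain
  if (nrow(wake) > 0 && cfg$emg_burst_rate > 0) {
    bursts <- place_event_times(round(interval_duration(wake) * cfg$emg_burst_rate),
                                wake, 1.0, 0.5)
    for (b in bursts) {
      j <- round(b * cfg$emg_rate_hz):round((b + 0.5) * cfg$emg_rate_hz)
      j <- j[j >= 1 & j <= ne]
      gain[j] <- cfg$emg_burst_gain
    }
  }
  gain <- gaussian_smooth(gain, 0.1 * cfg$emg_rate_hz)
  emg <- emg_bg * gain
  } else {
    na <- rep(NA_real_, length(ripple_t))
    cal_rip <- cal_sw <- list(z = na)
    cal_del <- list(z = rep(NA_real_, length(delta_t)))
    cal_spi <- list(z = rep(NA_real_, length(spindle_t)))
    ca1_final <- rsc_final <- emg <- NULL
  }

  # ---- spike trains ----------------------------------------------------
  swr_peaks <- ripple_t
  e_gain <- if (length(swr_peaks))
    rgamma(length(swr_peaks), shape = cfg$event_gain_shape,
           rate = cfg$event_gain_shape) else numeric(0)
  asm <- cfg$assembly
  asm_u <- if (length(swr_peaks) && asm$n_pairs > 0 && asm$strength > 0)
    pmin(rexp(length(swr_peaks)), 5) else numeric(0)

  unit_params <- list()
  trains <- list()
  mk_units <- function(region, n_units, rate_range, kernel) {
    for (u in seq_len(n_units)) {
      base <- runif_range(1, rate_range)
      id <- sprintf("%s-%02d", tolower(region), u)
      in_asm <- asm$n_pairs > 0 && u <= asm$n_pairs
      # Per-SWR latent excitability e_k: the source region's SWR bump
      # scales with e_k (exponent 1), the target's with e_k^strength, so
      # the source ensemble count in its bump window predicts the
      # target's response.
      coup <- cfg$coupling
      cstr <- 0
      if (coup$direction == "rsc2ca1")
        cstr <- if (region == "RSC") 1 else coup$strength
      if (coup$direction == "ca12rsc")
        cstr <- if (region == "CA1") 1 else coup$strength
      unit_params[[id]] <<- list(region = region, base = base,
                                 kernel = kernel, assembly = in_asm,
                                 coupling = cstr)
      trains[[id]] <<- simulate_unit_train(
        base, kernel, hyp, cfg$state_factor, swr_peaks, e_gain, cstr,
        in_asm, asm, asm_u, cfg$duration_s, region, id)
    }
  }
  mk_units("CA1", cfg$n_ca1, cfg$ca1_rate, cfg$ca1_kernel)
  mk_units("RSC", cfg$n_rsc, cfg$rsc_rate, cfg$rsc_kernel)

  # optional forced OFF periods in RSC trains (population silence)
  off_truth <- empty_intervals("off_period")
  if (cfg$n_off > 0) {
    if (!is.null(cfg$off_lag_s) && length(swr_peaks)) {
      o_st <- swr_peaks[seq_len(min(cfg$n_off, length(swr_peaks)))] + cfg$off_lag_s
    } else {
      o_st <- place_event_times(cfg$n_off, nrem, 1.0, cfg$seed_margin_s)
    }
    o_du <- runif_range(length(o_st), cfg$off_dur)
    off_truth <- interval_set(o_st, o_st + o_du, "off_period")
    for (id in names(trains)) {
      if (trains[[id]]$region == "RSC")
        trains[[id]]$times_s <-
          trains[[id]]$times_s[!in_intervals(trains[[id]]$times_s, off_truth)]
    }
  }

  truth <- list(
    hypnogram = hyp,
    events = list(
      ripple = interval_set(ripple_t - rip_dur / 2, ripple_t + rip_dur / 2,
                            "ripple", peak_s = ripple_t, peak_score = cal_rip$z),
      sharp_wave = interval_set(ripple_t - sw_dur / 2, ripple_t + sw_dur / 2,
                                "sharp_wave", peak_s = ripple_t,
                                peak_score = cal_sw$z),
      delta = interval_set(delta_t + 0.09, delta_t + 0.09 + del_pos + del_neg,
                           "delta", peak_s = delta_t + 0.09 + del_pos / 2,
                           peak_score = cal_del$z),
      spindle = interval_set(spindle_t - spi_dur / 2, spindle_t + spi_dur / 2,
                             "spindle", peak_s = spindle_t,
                             peak_score = cal_spi$z),
      off_period = off_truth),
    swr_peaks = swr_peaks,
    event_gain = e_gain,
    assembly_gain = asm_u,
    units = unit_params,
    config = cfg)

  sigs <- if (make_lfp) list(
    `CA1-lfp` = sampled_signal(ca1_final, fs, 0, "CA1-lfp"),
    `RSC-lfp` = sampled_signal(rsc_final, fs, 0, "RSC-lfp"),
    EMG = sampled_signal(emg, cfg$emg_rate_hz, 0, "EMG")) else list()
  ses <- session(signals = sigs, trains = unname(trains),
                 phase = "pre_sleep")
  list(session = ses, truth = truth)
}

# Inhomogeneous Poisson spikes by thinning.  Rate = base * state factor *
# peri-SWR kernel (scaled per event by a latent gain for coupled units) *
# assembly reactivation term.
simulate_unit_train <- function(base, kernel, hyp, state_factor, swr_peaks,
                                e_gain, coupling, in_assembly, asm, asm_u,
                                duration_s, region, id) {
  g_kernel <- kernel$gain %||% 1
  lam_max <- base * max(state_factor) * max(1, g_kernel) *
    (if (coupling > 0 && length(e_gain)) max(e_gain)^coupling else 1) *
    (if (in_assembly && length(asm_u)) 1 + asm$strength * max(asm_u) else 1)
  n_cand <- rpois(1, lam_max * duration_s)
  t <- sort(runif(n_cand, 0, duration_s))
  if (!length(t)) return(spike_train(id, region, numeric(0)))

  # state factor
  sf <- state_factor[hyp$state[pmax(1L, findInterval(t, hyp$start_s))]]
  sf[is.na(sf)] <- 1
  rate <- base * sf
  if (length(swr_peaks)) {
    idx <- findInterval(t, swr_peaks)
    near <- function(i) ifelse(i >= 1 & i <= length(swr_peaks),
                               swr_peaks[pmax(i, 1)], Inf)
    d1 <- abs(t - near(idx)); d2 <- abs(t - near(idx + 1L))
    k <- ifelse(d1 <= d2, pmax(idx, 1L), pmin(idx + 1L, length(swr_peaks)))
    lag <- t - swr_peaks[k]
    bump <- exp(-0.5 * ((lag - kernel$center) / kernel$sd)^2)
    ev_g <- if (coupling > 0) e_gain[k]^coupling else 1
    gain <- 1 + (g_kernel * ev_g - 1) * bump
    gain <- pmax(gain, 0.05)
    if (in_assembly && length(asm_u)) {
      hit <- abs(lag) <= asm$window_s
      gain <- gain * ifelse(hit, 1 + asm$strength * asm_u[k], 1)
    }
    rate <- rate * gain
  }
  keep <- runif(length(t)) < rate / lam_max
  spike_train(id, region, t[keep])
}
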