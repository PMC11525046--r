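# Direct construction of normalised traces lets the threshold rules be
# tested literally; LFP-level behaviour is covered via the generator in
# the acceptance suite.

zsig <- function(z, fs = 1000) sampled_signal(z, fs, 0, "z")

test_that("ripple rules: duration window, peak criterion, gap merging", {
  fs <- 1250
  t <- (0:(fs * 10 - 1)) / fs
  base <- 0.05 * sin(2 * pi * 180 * t)     # sub-threshold carrier
  add_burst <- function(x, at, dur, amp) {
    idx <- which(t >= at & t < at + dur)
    x[idx] <- x[idx] + amp * sin(2 * pi * 180 * t[idx])
    x
  }
  # one 50-ms burst -> one ripple; a 10-ms blip -> rejected
  x <- add_burst(base, 3, 0.05, 3)
  x <- add_burst(x, 6, 0.008, 3)
  rip <- detect_ripples(sampled_signal(x, fs, 0, "ca1"))
  expect_equal(nrow(rip), 1)
  expect_lt(abs(rip$peak_s - 3.025), 0.03)
  # two bursts 15 ms apart merge into one event
  x2 <- add_burst(base, 3, 0.04, 3)
  x2 <- add_burst(x2, 3.055, 0.04, 3)
  rip2 <- detect_ripples(sampled_signal(x2, fs, 0, "ca1"))
  expect_equal(nrow(rip2), 1)
  expect_error(detect_ripples(sampled_signal(x, 300, 0, "ca1")), "Nyquist")
})

test_that("ripple detector matches the literal one-pass oracle", {
  cfg <- sleep_config(duration_s = 10, n_ripples = 3, n_delta = 0,
                      n_spindles = 0, n_ca1 = 1, n_rsc = 1,
                      ripple_min_sep = 2, seed_margin_s = 1,
                      state_plan = data.frame(state = "nrem", dur_s = 10))
  for (sd in 1:3) {
    sim <- simulate_sleep_session(cfg, seed = sd)
    lfp <- sim$session$signals$`CA1-lfp`
    det <- detect_ripples(lfp)
    ora <- oracle_ripples(lfp)
    expect_equal(nrow(det), nrow(ora))
    expect_equal(det$start_s, ora$start_s, tolerance = 1e-9)
    expect_equal(det$end_s, ora$end_s, tolerance = 1e-9)
    expect_equal(det$peak_score, ora$peak_score, tolerance = 1e-9)
  }
})

test_that("sharp-wave rules: threshold, duration, flat signal", {
  fs <- 1250
  set.seed(4)
  x <- rnorm(fs * 10) * 0.3
  t <- (0:(fs * 10 - 1)) / fs
  # 80-ms deflection well above threshold -> detected
  idx <- which(t >= 4 & t < 4.08)
  x[idx] <- x[idx] - 8 * sin(pi * seq_along(idx) / length(idx))
  sw <- detect_sharp_waves(sampled_signal(x, fs, 0, "ca1"))
  expect_equal(nrow(sw), 1)
  expect_lt(abs(sw$peak_s - 4.04), 0.05)
  flat <- sampled_signal(rep(0, fs * 5), fs, 0, "ca1")
  expect_equal(nrow(detect_sharp_waves(flat)), 0)
  # duration rule on the thresholded trace itself: a 10-ms excursion is
  # below the 20-ms floor, an 80-ms one passes
  z <- rep(0, 1000)
  z[100:109] <- 3       # 10 ms at 1 kHz
  z[500:579] <- 3       # 80 ms
  ev <- swrpipe:::threshold_events(zsig(z), 2.5, 2.5, c(0.020, 0.400), 0,
                                   "sharp_wave")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 0.499, tolerance = 1e-9)
})

test_that("SWR pairing requires sharp-wave overlap and a valid state", {
  rip <- interval_set(c(1, 5, 9), c(1.05, 5.05, 9.05), "ripple",
                      peak_s = c(1.02, 5.02, 9.02), peak_score = c(5, 6, 7))
  sw <- interval_set(c(0.99, 8.99), c(1.08, 9.08), "sharp_wave")
  nrem <- interval_set(0, 6, "nrem")
  swr <- pair_swr(rip, sw, nrem)
  # ripple at 5 has no sharp wave; ripple at 9 is outside NREM
  expect_equal(swr$peak_s, 1.02)
  expect_equal(nrow(pair_swr(rip, empty_intervals("sharp_wave"), nrem)), 0)
  expect_equal(nrow(pair_swr(rip, sw, NULL)), 2)
})

test_that("delta clauses and the duration window are applied literally", {
  fs <- 1250
  dur_total <- 30
  t <- (0:(fs * dur_total - 1)) / fs
  set.seed(5)
  carrier <- 0.5 * sin(2 * pi * 1.5 * t)   # sets the z scale, peaks ~1.3 SD
  put_wave <- function(x, at, d_pos, d_neg, a_pos, a_neg) {
    i1 <- which(t >= at & t < at + d_pos)
    x[i1] <- x[i1] + a_pos * sin(pi * (t[i1] - at) / d_pos)
    i2 <- which(t >= at + d_pos & t < at + d_pos + d_neg)
    x[i2] <- x[i2] - a_neg * sin(pi * (t[i2] - at - d_pos) / d_neg)
    x
  }
  # clause 1: peak > 2 SD, end <= 0, duration ok (placed inside a carrier
  # trough so the onset zero-crossing belongs to the wave)
  x <- put_wave(carrier, 5.06, 0.2, 0.15, 3, 1)
  # fails both clauses: peak ~1.5 SD, trough not below -1.5
  x <- put_wave(x, 12, 0.2, 0.15, 0.55, 0.3)
  # too slow: onset->trough of ~650 ms -> rejected despite size
  x <- put_wave(x, 20, 0.5, 0.3, 3, 2)
  del <- detect_delta(sampled_signal(x, fs, 0, "rsc"))
  expect_equal(nrow(del), 1)
  expect_lt(abs(del$peak_s - 5.16), 0.1)
})

test_that("spindle rules: sustained duration, merging, merged-too-long", {
  fs <- 1000
  t <- (0:(fs * 40 - 1)) / fs
  base <- 0.3 * sin(2 * pi * 13 * t)
  put <- function(x, at, dur, amp) {
    idx <- which(t >= at & t < at + dur)
    x[idx] <- x[idx] + amp * sin(2 * pi * 13 * t[idx])
    x
  }
  x <- put(base, 5, 0.8, 4)      # detectable
  x <- put(x, 15, 0.3, 4)        # too short
  spi <- detect_spindles(sampled_signal(x, fs, 0, "rsc"))
  expect_equal(nrow(spi), 1)
  expect_true(spi$start_s > 4.5 && spi$end_s < 6.5)
  # two packets 300 ms apart merging beyond 3 s are discarded
  x2 <- put(base, 5, 1.6, 4)
  x2 <- put(x2, 6.9, 1.6, 4)
  spi2 <- detect_spindles(sampled_signal(x2, fs, 0, "rsc"))
  expect_equal(nrow(spi2), 0)
})

test_that("SWR-cortical pairing takes the nearest preceding SWR in 0-250 ms", {
  swrs <- interval_set(c(1, 2), c(1.1, 2.1), "swr", peak_s = c(1.05, 2.05))
  cort <- interval_set(c(1.05, 1.6, 2.6), c(1.4, 1.9, 2.9), "delta",
                       peak_s = c(1.11, 1.8, 2.65))
  pairs <- pair_sequences(swrs, cort)
  # 1.11: 60 ms after 1.05 -> paired; 1.8: 750 ms after -> no; 2.65: 600 ms -> no
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$lag_s, 0.06, tolerance = 1e-9)
  # a cortical peak before any SWR is not paired
  cort2 <- interval_set(0.5, 0.9, "delta", peak_s = 0.7)
  expect_equal(nrow(pair_sequences(swrs, cort2)), 0)
  expect_equal(nrow(pair_sequences(empty_intervals("swr"), cort)), 0)
})

test_that("SWR size classes partition by peak amplitude", {
  swrs <- interval_set(1:4, 1:4 + 0.1, "swr", peak_s = 1:4 + 0.05,
                       peak_score = c(12, 7, 4.5, 3))
  expect_equal(classify_swr_size(swrs), c("large", "medium", "small", NA))
  no_score <- interval_set(1, 2, "swr")
  expect_error(classify_swr_size(no_score), "peak_score")
  expect_error(classify_swr_size(swrs, thr = c(6, 4, 10)))
})

test_that("OFF periods: definition, merging, minimum unit count", {
  # dense background spiking (gaps 50 ms, below the 100-ms rule) with one
  # carved 150-ms silence and one silence pair split by a 3-ms doublet
  bg <- seq(0, 13, by = 0.05)
  bg <- bg[!(bg > 10.0 & bg < 10.15)]               # single OFF period
  bg <- bg[!(bg > 11.5 & bg < 11.9)]                # OFF pair below
  bg <- sort(c(bg, 11.7, 11.703))                   # split by < 5 ms
  trains <- c(lapply(1:4, function(k) mk_train(numeric(0), paste0("s", k),
                                               "RSC")),
              list(mk_train(bg, "a", "RSC")))
  off <- detect_off_periods(trains, span = c(0, 13))
  expect_equal(nrow(off), 2)
  # the carved 150-ms gap
  expect_equal(off$start_s[1], 10.0, tolerance = 1e-9)
  expect_equal(off$end_s[1], 10.15, tolerance = 1e-9)
  # the pair split by 3 ms merges into one OFF period
  expect_equal(off$start_s[2], 11.5, tolerance = 1e-9)
  expect_equal(off$end_s[2], 11.9, tolerance = 1e-9)
  # a 90-ms gap is not an OFF period
  bg2 <- seq(0, 5, by = 0.05)
  bg2 <- sort(c(bg2[!(bg2 > 2.0 & bg2 < 2.14)], 2.09))
  off2 <- detect_off_periods(list(mk_train(bg2, "a", "RSC")), min_units = 1,
                             span = c(0, 5))
  expect_equal(nrow(off2), 0)
  expect_null(detect_off_periods(trains[1:4]))
})

test_that("OFF detection equals the exact oracle on random rasters", {
  set.seed(10)
  for (i in 1:50) {
    n_units <- sample(5:8, 1)
    trains <- lapply(seq_len(n_units), function(k)
      poisson_train(runif(1, 0.5, 4), 20, paste0("r", k), "RSC"))
    off <- detect_off_periods(trains, span = c(0, 20))
    ora <- oracle_off(trains, c(0, 20))
    expect_equal(nrow(off), nrow(ora))
    if (nrow(ora)) {
      expect_equal(off$start_s, ora$start_s, tolerance = 1e-12)
      expect_equal(off$end_s, ora$end_s, tolerance = 1e-12)
    }
  }
})

test_that("ripple features report duration and rate per analysed minute", {
  rip <- interval_set(10, 10.06, "ripple", peak_s = 10.03, peak_score = 6.5)
  f <- ripple_features(rip, analyzed_s = 120)
  expect_equal(f$table$duration_s, 0.06, tolerance = 1e-9)
  expect_equal(f$rate_per_min, 0.5)
  expect_equal(f$table$peak_norm_power, 6.5)
  f0 <- ripple_features(empty_intervals("ripple"), 120)
  expect_equal(f0$rate_per_min, 0)
  expect_equal(nrow(f0$table), 0)
})

test_that("detector output is time-symmetric on a reversed signal", {
  cfg <- sleep_config(duration_s = 20, n_ripples = 4, n_delta = 0,
                      n_spindles = 0, n_ca1 = 1, n_rsc = 1,
                      ripple_min_sep = 2, seed_margin_s = 1.5,
                      state_plan = data.frame(state = "nrem", dur_s = 20))
  sim <- simulate_sleep_session(cfg, seed = 8)
  lfp <- sim$session$signals$`CA1-lfp`
  fwd <- detect_ripples(lfp)
  rev <- detect_ripples(sampled_signal(rev(lfp$samples), lfp$rate_hz, 0, "r"))
  expect_equal(nrow(fwd), nrow(rev))
})
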