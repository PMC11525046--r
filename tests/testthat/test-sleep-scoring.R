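test_that("EMG envelope z-scoring handles degenerate and scaled signals", {
  flat <- sampled_signal(rep(1, 5000), 1250, 0, "EMG")
  expect_true(all(compute_emg_z(flat)$samples == 0))
  set.seed(1)
  x <- rnorm(25000)
  x[12501:25000] <- x[12501:25000] * sqrt(10)
  z <- compute_emg_z(sampled_signal(x, 1250, 0, "EMG"))$samples
  expect_gt(mean(z[12501:25000]), mean(z[1:12500]))
  expect_error(compute_emg_z(sampled_signal(rnorm(10), 1250, 0, "EMG")),
               "warm-up")
})

test_that("theta/delta ratio separates band-limited tones", {
  fs <- 1250; n <- fs * 60
  t <- (0:(n - 1)) / fs
  set.seed(2)
  floor_noise <- 0.05 * rnorm(n)
  r8 <- theta_delta_ratio(sampled_signal(sin(2 * pi * 8 * t) + floor_noise,
                                         fs, 0, "lfp"))
  expect_gt(median(r8$samples), 2)
  r2 <- theta_delta_ratio(sampled_signal(sin(2 * pi * 2 * t) + floor_noise,
                                         fs, 0, "lfp"))
  expect_lt(median(r2$samples), 2)
  expect_error(theta_delta_ratio(sampled_signal(rnorm(100), 1250, 0, "l")),
               "window")
})

test_that("equal-power tones give a ratio near 1 (periodogram oracle)", {
  fs <- 1250; n <- fs * 60
  t <- (0:(n - 1)) / fs
  set.seed(3)
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 8 * t) + 0.05 * rnorm(n)
  r <- theta_delta_ratio(sampled_signal(x, fs, 0, "lfp"))
  expect_equal(median(r$samples), 1, tolerance = 0.15)
  # oracle: long-window periodogram of the same signal
  sp <- Mod(fft(x - mean(x)))^2
  fr <- (0:(n - 1)) * fs / n
  oracle <- sum(sp[fr >= 6 & fr <= 10]) / sum(sp[fr >= 1 & fr <= 4])
  expect_equal(oracle, 1, tolerance = 0.05)
})

test_that("state scoring applies the wake/REM/NREM and transition rules", {
  mk <- function(vals, rate = 0.5) sampled_signal(vals, rate, 1, "x")
  n <- 400  # 800 s at 0.5 Hz window grid
  # wake throughout
  hyp <- score_states(mk(rep(1, n)), mk(rep(2, n)))
  expect_equal(unique(hyp$state), "wake")
  # immobile, ratio 3 -> REM
  hyp <- score_states(mk(rep(3, n)), mk(rep(-1, n)))
  expect_equal(unique(hyp$state), "rem")
  # 20-s NREM block between wake blocks -> other (shorter than 30 s)
  emg <- rep(2, n); emg[101:110] <- -1      # 20 s immobile
  ratio <- rep(1, n)
  hyp <- score_states(mk(ratio), mk(emg))
  mid <- hyp$state[hyp$start_s <= 201 & hyp$end_s >= 219]
  expect_true(all(mid == "other"))
  # hypnogram tiles the span without gaps
  expect_equal(hyp$start_s[-1], hyp$end_s[-nrow(hyp)])
})

test_that("transition margins around genuine stage changes become other", {
  mk <- function(vals) sampled_signal(vals, 0.5, 1, "x")
  n <- 400
  ratio <- c(rep(1, 200), rep(4, 200))   # NREM then REM, both long
  hyp <- score_states(mk(ratio), mk(rep(-1, n)))
  expect_setequal(unique(hyp$state), c("nrem", "other", "rem"))
  oth <- hyp[hyp$state == "other", ]
  expect_equal(oth$end_s - oth$start_s, 5, tolerance = 2.1)
})

test_that("state firing-rate contrast follows the defining formula", {
  hyp <- interval_set(c(0, 100), c(100, 200), "hypnogram",
                      state = c("nrem", "wake"))
  # NREM FR 3 Hz, wake FR 1 Hz -> 0.5
  tr <- mk_train(c(seq(0.5, 99.5, length.out = 300),
                   seq(100.5, 199.5, length.out = 100)))
  expect_equal(state_rate_ratio(tr, hyp), 0.5, tolerance = 1e-6)
  # equal rates -> 0
  tr2 <- mk_train(c(seq(0.5, 99.5, length.out = 200),
                    seq(100.5, 199.5, length.out = 200)))
  expect_equal(state_rate_ratio(tr2, hyp), 0)
  # wake-only unit -> -1
  tr3 <- mk_train(seq(100.5, 199.5, length.out = 400))
  expect_equal(state_rate_ratio(tr3, hyp), -1)
  # silent unit -> NA; missing state -> error
  expect_true(is.na(state_rate_ratio(mk_train(numeric(0)), hyp)))
  hyp2 <- interval_set(0, 100, "hypnogram", state = "nrem")
  expect_error(state_rate_ratio(tr, hyp2), "nonzero duration")
})
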