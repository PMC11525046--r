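test_that("same seed gives identical sessions, different seeds differ", {
  cfg <- sleep_config(duration_s = 120, make_lfp = FALSE, n_ripples = 10,
                      n_delta = 0, n_spindles = 0, n_ca1 = 3, n_rsc = 3,
                      state_plan = data.frame(state = "nrem", dur_s = 120))
  a <- simulate_sleep_session(cfg, seed = 5)
  b <- simulate_sleep_session(cfg, seed = 5)
  expect_identical(a$truth$swr_peaks, b$truth$swr_peaks)
  expect_identical(lapply(a$session$trains, `[[`, "times_s"),
                   lapply(b$session$trains, `[[`, "times_s"))
  c <- simulate_sleep_session(cfg, seed = 6)
  expect_false(identical(a$truth$swr_peaks, c$truth$swr_peaks))
})

test_that("lfp sessions are reproducible byte-for-byte", {
  cfg <- sleep_config(duration_s = 60, n_ripples = 5, n_delta = 6,
                      n_spindles = 2,
                      state_plan = data.frame(state = "nrem", dur_s = 60))
  a <- simulate_sleep_session(cfg, seed = 11)
  b <- simulate_sleep_session(cfg, seed = 11)
  expect_identical(a$session$signals$`CA1-lfp`$samples,
                   b$session$signals$`CA1-lfp`$samples)
  expect_identical(a$session$signals$`RSC-lfp`$samples,
                   b$session$signals$`RSC-lfp`$samples)
})

test_that("unmodulated trains are Poisson: Fano factor of 1-s counts near 1", {
  cfg <- sleep_config(duration_s = 200, make_lfp = FALSE, n_ripples = 0,
                      n_delta = 0, n_spindles = 0, n_ca1 = 0, n_rsc = 1,
                      rsc_rate = c(4, 4),
                      state_plan = data.frame(state = "nrem", dur_s = 200))
  fanos <- vapply(1:5, function(sd) {
    tr <- simulate_sleep_session(cfg, seed = sd)$session$trains[[1]]
    counts <- bin_counts(list(tr), 1, c(0, 200))
    var(as.numeric(counts)) / mean(counts)
  }, numeric(1))
  expect_true(all(fanos > 0.8 & fanos < 1.2))
})

test_that("flat kernels give a flat peri-SWR PSTH", {
  cfg <- sleep_config(duration_s = 400, make_lfp = FALSE, n_ripples = 25,
                      n_delta = 0, n_spindles = 0, n_ca1 = 0, n_rsc = 4,
                      ca1_kernel = list(center = 0, sd = 0.03, gain = 1),
                      rsc_kernel = list(center = 0, sd = 0.03, gain = 1),
                      state_plan = data.frame(state = "nrem", dur_s = 400))
  sim <- simulate_sleep_session(cfg, seed = 3)
  p <- compute_psth(sim$session$trains, sim$truth$swr_peaks, c(0, 400),
                    min_anchors = 20)
  expect_lt(mean(abs(p$z)), 0.2)
})

test_that("task simulation rejects zero trials and records run epochs", {
  expect_error(simulate_task_session(task_config(n_trials = 0), 1), "zero")
  sim <- simulate_task_session(task_config(n_trials = 6), seed = 2)
  expect_equal(nrow(sim$session$trials), 6)
  expect_equal(nrow(sim$session$events$run), 6)
  expect_true(all(c("time_s", "x_cm", "y_cm") %in%
                    names(sim$session$trajectory)))
  # alternation of intended types on correct trials
  tt <- sim$session$trials
  expect_true(all(tt$type %in% c("L", "R")))
})

test_that("waveform generator records a recoverable identity map", {
  w <- simulate_waveforms(4, 4, noise_sd = 0, seed = 9)
  expect_equal(nrow(w$identity), 8)
  m <- match_units(w$phases$pre, w$phases$post)
  a <- m[m$accepted, ]
  truth_post <- w$identity$post_id[match(a$pre_id, w$identity$pre_id)]
  expect_equal(nrow(a), 8)
  expect_true(all(a$post_id == truth_post))
})
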