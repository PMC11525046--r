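test_that("anchor eligibility is greedy earliest-first with window bounds", {
  a <- eligible_anchors(c(0.5, 1.2, 1.35, 2.0, 2.25), min_sep_s = 0.3,
                        epoch = c(0, 10), span = c(-1, 1))
  # 0.5 loses the window bound; 1.35 and 2.25 lose the greedy gap
  expect_equal(a, c(1.2, 2.0))
  a2 <- eligible_anchors(c(2, 2.2, 2.5, 3), min_sep_s = 0.3)
  expect_equal(a2, c(2, 2.5, 3))
})

test_that("PSTH skips sessions with fewer than 50 eligible anchors", {
  set.seed(1)
  tr <- poisson_train(5, 100)
  anchors <- seq(2, 98, length.out = 49)
  expect_null(compute_psth(list(tr), anchors, c(0, 100)))
})

test_that("PSTH z-scoring and bump localisation behave on known kernels", {
  cfg <- sleep_config(duration_s = 600, make_lfp = FALSE, n_ripples = 60,
                      n_delta = 0, n_spindles = 0, n_ca1 = 0, n_rsc = 6,
                      rsc_rate = c(4, 8),
                      rsc_kernel = list(center = -0.06, sd = 0.05, gain = 3),
                      state_plan = data.frame(state = "nrem", dur_s = 600))
  peaks <- vapply(1:3, function(sd) {
    sim <- simulate_sleep_session(cfg, seed = sd)
    p <- compute_psth(sim$session$trains, sim$truth$swr_peaks, c(0, 600))
    # baseline-window z mean near 0 per unit
    bl <- p$lags_s >= -1 & p$lags_s < -0.5
    expect_lt(max(abs(rowMeans(p$z[, bl]))), 0.1)
    mean(p$lags_s[apply(p$z, 1, which.max)])
  }, numeric(1))
  expect_lt(max(abs(peaks - (-0.06))), 0.015)
})

test_that("modulation test is deterministic and flags zero-spike units", {
  set.seed(2)
  anchors <- eligible_anchors(sort(runif(60, 2, 298)), 0.3, c(0, 300))
  tr <- poisson_train(4, 300)
  set.seed(99)
  r1 <- test_modulation(tr, anchors, c(0, 300), n_shuffle = 50)
  set.seed(99)
  r2 <- test_modulation(tr, anchors, c(0, 300), n_shuffle = 50)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_scores, r2$null_scores)
  z <- test_modulation(mk_train(numeric(0), "z", "RSC"), anchors, c(0, 300),
                       n_shuffle = 10)
  expect_true(z$flagged)
  expect_false(z$modulated)
  expect_null(test_modulation(tr, anchors[1:10], c(0, 300), n_shuffle = 10))
})

test_that("cross-correlogram localises shifts and is antisymmetric", {
  set.seed(3)
  a <- sort(runif(200, 0, 100))
  b <- a + 0.06
  cc <- cross_correlogram(a, b, bin = 0.01, span = c(-0.5, 0.5))
  expect_equal(cc$lags_s[which.max(cc$counts)], 0.065, tolerance = 0.011)
  # antisymmetry: cc(a,b) at lag l == cc(b,a) at -l
  cc_ab <- cross_correlogram(a, b, bin = 0.02, span = c(-0.3, 0.3))
  cc_ba <- cross_correlogram(b, a, bin = 0.02, span = c(-0.3, 0.3))
  expect_equal(cc_ab$counts, rev(cc_ba$counts))
  # empty input -> zero histogram
  cc0 <- cross_correlogram(numeric(0), b)
  expect_true(all(cc0$counts == 0))
  # independent Poisson stays inside the jitter null band almost everywhere
  set.seed(4)
  x <- sort(runif(300, 0, 100)); y <- sort(runif(300, 0, 100))
  ccn <- cross_correlogram(x, y, bin = 0.05, span = c(-0.5, 0.5),
                           n_jitter = 50)
  inside <- mean(ccn$counts >= ccn$null_lo & ccn$counts <= ccn$null_hi)
  expect_gt(inside, 0.8)
})

test_that("size-stratified PSTH rejects a single usable class", {
  set.seed(5)
  swrs <- interval_set(seq(2, 58, by = 2), seq(2, 58, by = 2) + 0.05, "swr",
                       peak_s = seq(2, 58, by = 2) + 0.02,
                       peak_score = rep(5, 29))   # all small
  tr <- poisson_train(5, 60)
  expect_warning(
    expect_error(psth_by_size(list(tr), swrs, c(0, 60), min_events = 10),
                 "fewer than 2"),
    "omitted")
})

test_that("peri-SWR OFF statistics localise inserted onsets", {
  cfg <- sleep_config(duration_s = 400, make_lfp = FALSE, n_ripples = 40,
                      n_delta = 0, n_spindles = 0, n_ca1 = 0, n_rsc = 8,
                      rsc_rate = c(4, 8), n_off = 40, off_lag_s = 0.1,
                      rsc_kernel = list(center = 0, sd = 0.03, gain = 1),
                      state_plan = data.frame(state = "nrem", dur_s = 400))
  sim <- simulate_sleep_session(cfg, seed = 6)
  off <- detect_off_periods(session_trains(sim$session, "RSC"),
                            span = c(0, 400))
  swr <- interval_set(sim$truth$swr_peaks - 0.02, sim$truth$swr_peaks + 0.03,
                      "swr", peak_s = sim$truth$swr_peaks)
  res <- off_peri_swr(off, swr)
  expect_equal(res$lags_s[which.max(res$p_onset)], 0.11, tolerance = 0.05)
  expect_true(all(res$p_onset >= 0))
})

test_that("size-stratified PSTH finds amplitude-dependent firing", {
  set.seed(7)
  # construct SWRs in three amplitude classes and a unit whose event
  # response scales with class
  on <- seq(5, 293, by = 1.6)
  cls_score <- rep(c(5, 7, 11), length.out = length(on))
  swrs <- interval_set(on, on + 0.06, "swr", peak_s = on + 0.02,
                       peak_score = cls_score)
  mk_unit <- function(id) {
    base <- sort(runif(900, 0, 300))
    extra <- unlist(mapply(function(o, s) {
      n <- rpois(1, (s - 4) * 1.2)
      o + runif(n, 0, 0.05)
    }, on, cls_score))
    mk_train(sort(c(base, extra)), id, "RSC")
  }
  trains <- lapply(sprintf("u%d", 1:6), mk_unit)
  res <- psth_by_size(trains, swrs, c(0, 300), min_events = 20)
  early <- res$anova[res$anova$window == "early", ]
  expect_lt(early$p, 0.05)
  means <- colMeans(res$window_means$early)
  expect_true(means[["small"]] < means[["large"]])
})

test_that("baseline z mean tightens with many events", {
  cfg <- sleep_config(duration_s = 1200, make_lfp = FALSE, n_ripples = 500,
                      ripple_min_sep = 0.6, n_delta = 0, n_spindles = 0,
                      n_ca1 = 0, n_rsc = 2, rsc_rate = c(4, 6),
                      rsc_kernel = list(center = 0, sd = 0.03, gain = 1),
                      state_plan = data.frame(state = "nrem", dur_s = 1200))
  sim <- suppressWarnings(simulate_sleep_session(cfg, seed = 9))
  an <- eligible_anchors(sim$truth$swr_peaks, 0.3, c(0, 1200))
  expect_gte(length(an), 400)
  p <- compute_psth(sim$session$trains, an, c(0, 1200))
  bl <- p$lags_s >= -1 & p$lags_s < -0.5
  expect_lt(max(abs(rowMeans(p$z[, bl]))), 0.05)
})
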