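test_that("occurrence prediction rejects an all-zero outcome vector", {
  set.seed(1)
  rsc <- lapply(1:5, function(i) poisson_train(3, 60, paste0("r", i), "RSC"))
  expect_error(predict_swr_occurrence(rsc, empty_intervals("swr"), c(0, 60)),
               "all-zero")
})

test_that("prediction gain guards degenerate errors and caps", {
  # mean real error 0 and mean baseline 0 -> gain 1 (constant-zero target)
  expect_equal(swrpipe:::cv_gain(matrix(rpois(100, 2), 50, 2), rep(0, 50),
                                 k = 5, n_shuffle = 5, poisson()), 1)
})

test_that("cell-count prediction enforces eligibility and is seeded", {
  set.seed(2)
  swrs <- interval_set(seq(2, 118, by = 2), seq(2, 118, by = 2) + 0.05,
                       "swr", peak_s = seq(2, 118, by = 2) + 0.02)
  rsc <- lapply(1:6, function(i) poisson_train(5, 120, paste0("r", i), "RSC"))
  target <- poisson_train(12, 120, "c1", "CA1")
  # fewer than 5 predictor cells -> skipped
  expect_null(predict_cell_counts(rsc[1:4], target, swrs, c(0, 120),
                                  min_anchors = 30, min_active = 20))
  # inactive target -> skipped
  quiet <- poisson_train(0.05, 120, "c2", "CA1")
  expect_null(predict_cell_counts(rsc, quiet, swrs, c(0, 120),
                                  min_anchors = 30, min_active = 20))
  set.seed(7)
  r1 <- predict_cell_counts(rsc, target, swrs, c(0, 120), n_shuffle = 10,
                            n_control = 10, min_anchors = 30, min_active = 20)
  set.seed(7)
  r2 <- predict_cell_counts(rsc, target, swrs, c(0, 120), n_shuffle = 10,
                            n_control = 10, min_anchors = 30, min_active = 20)
  expect_identical(r1$gain_real, r2$gain_real)
  expect_identical(r1$gains_shuffled, r2$gains_shuffled)
  expect_gt(r1$gain_real, 0)
})

test_that("whole-set shuffle control gains centre on 1 under pure noise", {
  set.seed(3)
  gains <- replicate(60, {
    X <- matrix(rpois(80 * 5, 2), 80, 5)
    y <- rpois(80, 2)
    swrpipe:::cv_gain(X, y, k = 5, n_shuffle = 20, poisson())
  })
  expect_gt(median(gains), 0.95)
  expect_lt(median(gains), 1.05)
})

test_that("directional summary aggregates by window and direction", {
  mk_res <- function(g, id) structure(list(predicted_unit = id,
    gain_real = g, gains_shuffled = rnorm(20, 1, 0.02), p = 0.5),
    class = "prediction_result")
  res <- list(mk_res(1.5, "a"), mk_res(1.4, "b"), mk_res(1.0, "c"), NULL)
  tab <- directional_summary(res,
    direction = c("rsc2ca1", "rsc2ca1", "ca12rsc", "ca12rsc"),
    window = c("(-100,0)", "(-100,0)", "(0,100)", "(0,100)"))
  expect_equal(nrow(tab), 2)
  r1 <- tab[tab$direction == "rsc2ca1", ]
  expect_equal(r1$n_units, 2)
  expect_lt(r1$p, 0.05)
  # single result -> 1x1 grid using the per-unit p
  tab1 <- directional_summary(res[3])
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$n_units, 1)
})

test_that("binomial occurrence prediction runs end to end with both classes", {
  set.seed(4)
  cfg <- sleep_config(duration_s = 300, make_lfp = FALSE, n_ripples = 40,
                      n_delta = 0, n_spindles = 0, n_ca1 = 0, n_rsc = 6,
                      rsc_rate = c(4, 8),
                      rsc_kernel = list(center = -0.03, sd = 0.04, gain = 4),
                      state_plan = data.frame(state = "nrem", dur_s = 300))
  sim <- simulate_sleep_session(cfg, seed = 4)
  swr <- interval_set(sim$truth$swr_peaks, sim$truth$swr_peaks + 0.05, "swr",
                      peak_s = sim$truth$swr_peaks + 0.02)
  res <- predict_swr_occurrence(session_trains(sim$session, "RSC"), swr,
                                c(0, 300), n_shuffle = 10, n_control = 15)
  expect_equal(res$n_swr, 40)
  expect_gt(res$gain_real, 1)          # strong bump makes bins separable
  expect_lt(res$p, 0.2)
})
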