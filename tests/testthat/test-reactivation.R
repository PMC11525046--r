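test_that("template construction follows the cell-pair correlation formula", {
  set.seed(1)
  n <- 1000
  shared <- rnorm(n)
  ca1 <- cbind(shared, matrix(rnorm(n * 3), n, 3)) + 5
  rsc <- cbind(shared, matrix(rnorm(n * 3), n, 3)) + 5
  tpl <- build_template(ca1, rsc)
  expect_equal(dim(tpl$C), c(4, 4))
  expect_gt(tpl$C[1, 1], 0.9)
  expect_lt(max(abs(tpl$C[-1, -1])), 0.15)
  # fewer than 4 cells per region is rejected
  expect_error(build_template(ca1[, 1:3], rsc), "at least 4")
  # silent unit excluded with warning, then ensemble size re-checked
  ca1_sil <- cbind(ca1, 0)
  expect_warning(tpl2 <- build_template(ca1_sil, rsc), "silent")
  expect_equal(nrow(tpl2$C), 4)
})

test_that("template entries are invariant to per-cell affine count scaling", {
  set.seed(2)
  ca1 <- matrix(rpois(400 * 4, 3), 400, 4)
  rsc <- matrix(rpois(400 * 4, 3), 400, 4)
  t1 <- build_template(ca1, rsc)
  t2 <- build_template(sweep(ca1, 2, c(2, 3, 0.5, 10), "*") + 7, rsc)
  expect_equal(t1$C, t2$C, tolerance = 1e-12)
})

test_that("reactivation strength implements z C z' with epoch z-scoring", {
  # raw arithmetic: z_ca1 = (1,2), z_rsc = (3,4), C = I -> raw R = 11
  tpl <- list(C = diag(2), ca1_keep = 1:2, rsc_keep = 1:2, n_bins = 10)
  za <- matrix(c(1, 2), 1)
  zb <- matrix(c(3, 4), 1)
  raw <- as.numeric(za %*% tpl$C %*% t(zb))
  expect_equal(raw, 11)
  # through the full function: C = 0 gives R identically 0
  set.seed(3)
  ca1 <- matrix(rpois(200 * 4, 3), 200, 4)
  rsc <- matrix(rpois(200 * 4, 3), 200, 4)
  tpl0 <- list(C = matrix(0, 4, 4), ca1_keep = 1:4, rsc_keep = 1:4,
               n_bins = 200)
  tr <- reactivation_strength(tpl0, ca1, rsc, seq(0.05, by = 0.1,
                                                  length.out = 200))
  expect_true(all(tr$R_raw == 0))
  # dimension mismatch
  expect_error(reactivation_strength(tpl0, ca1[, 1:3], rsc,
                                     seq_len(200) / 10), "mismatch")
})

test_that("mean reactivation is near zero for independent regions", {
  set.seed(4)
  means <- vapply(1:20, function(i) {
    run_a <- matrix(rpois(300 * 4, 3), 300, 4)
    run_b <- matrix(rpois(300 * 4, 3), 300, 4)
    tpl <- build_template(run_a, run_b)
    sa <- matrix(rpois(500 * 4, 3), 500, 4)
    sb <- matrix(rpois(500 * 4, 3), 500, 4)
    mean(reactivation_strength(tpl, sa, sb,
                               seq(0.05, by = 0.1, length.out = 500))$R_raw)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.01)
})

test_that("pair correlations recover identical trains and flag silent pairs", {
  set.seed(5)
  t_sp <- sort(runif(600, 0, 120))
  ca1 <- list(mk_train(t_sp, "c1"), poisson_train(4, 120, "c2", "CA1"))
  rsc <- list(mk_train(t_sp, "r1", "RSC"),
              mk_train(numeric(0), "r2", "RSC"))
  epochs <- list(task_run = interval_set(0, 120, "epoch"))
  pc <- pair_correlations(ca1, rsc, epochs)
  r11 <- pc[pc$ca1_unit == "c1" & pc$rsc_unit == "r1", ]
  expect_equal(r11$r_task_run, 1)
  expect_equal(r11$class, "positive")
  expect_true(all(pc$class[pc$rsc_unit == "r2"] == "unreliable"))
  expect_true(all(is.na(pc$r_task_run[pc$rsc_unit == "r2"])))
})

test_that("peri-SWR reactivation errors without SWRs and returns a band", {
  set.seed(6)
  tr <- structure(list(t = seq(0.05, by = 0.1, length.out = 600),
                       R_z = rnorm(600), R_raw = rnorm(600)),
                  class = "reactivation_trace")
  expect_error(peri_swr_reactivation(tr, numeric(0)), "no SWRs")
  res <- peri_swr_reactivation(tr, runif(30, 5, 55), n_shuffle = 30)
  expect_length(res$mean_R, 21)
  expect_true(all(res$null_lo <= res$null_hi))
  expect_true(res$p_lag0 >= 0 && res$p_lag0 <= 1)
})
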