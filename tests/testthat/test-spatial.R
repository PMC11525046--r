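test_that("rate maps conserve speed-filtered spikes and exclude sparse units", {
  sim <- simulate_task_session(task_config(n_trials = 20), seed = 1)
  ses <- sim$session
  ca1 <- session_trains(ses, "CA1")
  tr <- ca1[[which.max(vapply(ca1, function(x) length(x$times_s), numeric(1)))]]
  rm <- rate_map(tr, ses$trajectory)
  expect_equal(sum(rm$rate_hz * rm$occupancy_s), rm$n_spikes,
               tolerance = 0.02)
  expect_true(all(rm$rate_hz >= 0))
  sparse <- mk_train(ses$trajectory$time_s[c(10, 50, 90)], "sp", "CA1")
  expect_null(rate_map(sparse, ses$trajectory))
})

test_that("place-field rule: >= 40 contiguous bins inside a 7x7 box", {
  mk_map <- function(m) structure(list(rate_hz = m, mean_rate_hz = 0.5),
                                  class = "rate_map")
  flat <- mk_map(matrix(0.5, 40, 40))
  expect_equal(nrow(find_place_fields(flat)), 0)
  # 45 supra-threshold bins in a 7x7 patch -> one field
  m <- matrix(0.4, 40, 40)
  patch <- matrix(3, 7, 7); patch[1, 1:4] <- 0.4   # 45 bins
  m[10:16, 20:26] <- patch
  f <- find_place_fields(mk_map(m))
  expect_equal(nrow(f), 1)
  expect_equal(f$n_bins, 45)
  # 20 bins -> no field; 8x8 block -> bounding box too large
  m2 <- matrix(0.4, 40, 40); m2[5:8, 5:9] <- 3
  expect_equal(nrow(find_place_fields(mk_map(m2))), 0)
  m3 <- matrix(0.4, 40, 40); m3[5:12, 5:12] <- 3
  expect_equal(nrow(find_place_fields(mk_map(m3))), 0)
})

test_that("field detection is translation invariant", {
  mk_map <- function(m) structure(list(rate_hz = m, mean_rate_hz = 0.5),
                                  class = "rate_map")
  base <- matrix(0.4, 50, 50)
  base[10:16, 10:16] <- 3
  f1 <- find_place_fields(mk_map(base))
  shifted <- matrix(0.4, 50, 50)
  shifted[25:31, 30:36] <- 3
  f2 <- find_place_fields(mk_map(shifted))
  expect_equal(f1$n_bins, f2$n_bins)
  expect_equal(f2$x_lo - f1$x_lo, 15)
})

test_that("stem classification follows the two-way ANOVA label rules", {
  set.seed(2)
  mk_rates <- function(fn) {
    do.call(rbind, lapply(1:20, function(tr) {
      ty <- if (tr %% 2) "L" else "R"
      data.frame(trial_id = tr, type = ty, subarea = 1:3,
                 rate_hz = fn(ty) + rnorm(3, 0, 0.3))
    }))
  }
  # trial-type effect in subarea 3 -> splitter
  split_rates <- mk_rates(function(ty) c(2, 2, if (ty == "L") 10 else 2))
  expect_equal(classify_stem_cells(split_rates)$label, "splitter")
  # subarea-only profile -> location_related
  loc_rates <- mk_rates(function(ty) c(2, 6, 10))
  expect_equal(classify_stem_cells(loc_rates)$label, "location_related")
  # missing trial type -> error
  only_l <- split_rates[split_rates$type == "L", ]
  expect_error(classify_stem_cells(only_l), "absent")
})

test_that("stem trial rates exclude incorrect trials", {
  sim <- simulate_task_session(task_config(n_trials = 12, p_error = 0.4),
                               seed = 3)
  ses <- sim$session
  tr <- session_trains(ses, "RSC")[[1]]
  sr <- stem_trial_rates(tr, ses$trajectory, ses$trials,
                         sim$truth$config$geometry)
  expect_true(all(sr$trial_id %in% ses$trials$trial_id[ses$trials$correct]))
  expect_true(all(sr$subarea %in% 1:3))
})

test_that("speed score errors on degenerate trajectories and filters labels", {
  traj <- data.frame(time_s = seq(0, 10, by = 0.04),
                     x_cm = seq(0, 50, length.out = 251), y_cm = 5)
  tr <- mk_train(seq(0.5, 9.5, by = 0.21))
  expect_error(speed_score(tr, traj), "constant")
  labs <- c(a = "splitter", b = "location_related")
  flags <- c(a = TRUE, b = FALSE)
  out <- exclude_speed_cells(labs, flags)
  expect_equal(names(out), "b")
  expect_warning(exclude_speed_cells(labs["a"], flags["a"]), "all cells")
})
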