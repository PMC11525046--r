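test_that("interval sets enforce ordering, merging and the half-open rule", {
  iv <- interval_set(c(5, 1), c(6, 2), "ripple")
  expect_equal(iv$start_s, c(1, 5))
  expect_error(interval_set(1, 1, "ripple"), "start_s")
  expect_error(interval_set(0, 1, "ripple", peak_s = 2), "peak_s")

  # merging: gap < gap_s fuses, peak of highest score survives
  iv <- interval_set(c(0, 0.5, 2), c(0.4, 1, 3), "ripple",
                     peak_s = c(0.2, 0.7, 2.5), peak_score = c(3, 5, 4))
  m <- merge_intervals(iv, gap_s = 0.2)
  expect_equal(nrow(m), 2)
  expect_equal(m$peak_s[1], 0.7)   # score 5 wins inside the merged pair
  expect_equal(m$end_s[1], 1)

  expect_equal(in_intervals(c(1, 2, 2.5), interval_set(1, 2.5)),
               c(TRUE, TRUE, FALSE))
  a <- interval_set(c(0, 10), c(5, 12))
  b <- interval_set(c(3, 11), c(4, 20))
  ab <- intersect_intervals(a, b)
  expect_equal(ab$start_s, c(3, 11))
  expect_equal(ab$end_s, c(4, 12))
  expect_equal(interval_duration(ab), 2)
})

test_that("restrict keeps spikes in the half-open union and is idempotent", {
  tr <- mk_train(c(1, 2, 3))
  ivs <- interval_set(1.5, 2.5)
  expect_equal(restrict(tr, ivs)$times_s, 2)
  expect_equal(restrict(tr, empty_intervals())$times_s, numeric(0))
  # spike exactly at end_s excluded
  expect_equal(restrict(mk_train(2.5), ivs)$times_s, numeric(0))
  # idempotence
  r1 <- restrict(tr, ivs)
  expect_identical(restrict(r1, ivs)$times_s, r1$times_s)
})

test_that("bin_counts tiles half-open bins and conserves counts", {
  tr <- mk_train(c(0.05, 0.12))
  m <- bin_counts(list(tr), 0.1, c(0, 0.2))
  expect_equal(dim(m), c(2, 1))
  expect_equal(as.numeric(m), c(1, 1))
  # spike exactly on an interior edge goes to the later bin
  m2 <- bin_counts(list(mk_train(0.1)), 0.1, c(0, 0.2))
  expect_equal(as.numeric(m2), c(0, 1))
  expect_equal(sum(bin_counts(list(mk_train(numeric(0)))[1], 0.1, c(0, 1))), 0)
  expect_error(bin_counts(list(tr), 0.5, c(0, 0.2)), "span")
  # conservation within span
  set.seed(1)
  tr3 <- poisson_train(20, 10)
  m3 <- bin_counts(list(tr3), 0.25, c(0, 10))
  expect_equal(sum(m3), sum(tr3$times_s >= 0 & tr3$times_s < 10))
})

test_that("sessions round-trip through the on-disk layout", {
  set.seed(2)
  d <- file.path(tempdir(), "ses-rt")
  unlink(d, recursive = TRUE)
  sig <- sampled_signal(rnorm(2000), 1250, t0_s = 3.5, label = "CA1-lfp")
  ses <- session(
    signals = list(`CA1-lfp` = sig),
    trains = list(mk_train(c(4, 4.5, 5), "u1"), mk_train(5.2, "u2", "RSC")),
    events = list(ripple = interval_set(4.1, 4.2, "ripple", peak_s = 4.15,
                                        peak_score = 6)),
    hypnogram = interval_set(c(0, 10), c(10, 20), "hypnogram",
                             state = c("nrem", "wake")),
    trajectory = data.frame(time_s = c(0, 0.04), x_cm = c(1, 2),
                            y_cm = c(3, 4)),
    phase = "post_sleep")
  write_session(ses, d)
  back <- read_session(d)
  expect_equal(back$phase, "post_sleep")
  expect_equal(length(back$signals), 1)
  expect_equal(back$signals$`CA1-lfp`$t0_s, 3.5)
  expect_equal(back$signals$`CA1-lfp`$samples, sig$samples, tolerance = 1e-6)
  expect_equal(sort(vapply(back$trains, `[[`, "", "unit_id")), c("u1", "u2"))
  u1 <- Filter(function(x) x$unit_id == "u1", back$trains)[[1]]
  expect_identical(u1$times_s, c(4, 4.5, 5))    # times bit-exact via %.17g
  expect_equal(back$events$ripple$peak_s, 4.15)
  expect_equal(back$hypnogram$state, c("nrem", "wake"))
  expect_equal(back$trajectory$x_cm, c(1, 2))
})

test_that("read_session raises named validation and format errors", {
  d <- file.path(tempdir(), "ses-bad")
  unlink(d, recursive = TRUE); dir.create(d)
  write.table(data.frame(unit_id = "7", region = "CA1",
                         time_s = c(2, 1), cell_class = "unclassified"),
              file.path(d, "spikes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_session(d), "unit 7")
  # missing sidecar
  d2 <- file.path(tempdir(), "ses-side")
  unlink(d2, recursive = TRUE); dir.create(d2)
  writeBin(numeric(10), file.path(d2, "x.f32"), size = 4)
  expect_error(read_signal(file.path(d2, "x.f32")), "sidecar")
  # empty events dir -> empty map
  d3 <- file.path(tempdir(), "ses-empty")
  unlink(d3, recursive = TRUE); dir.create(file.path(d3, "events"),
                                           recursive = TRUE)
  expect_length(read_session(d3)$events, 0)
})

test_that("spike trains reject out-of-order times", {
  expect_error(spike_train("u9", "CA1", c(2, 1)), "u9")
})
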