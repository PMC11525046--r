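# Shared fixtures and small oracles, all built in code.

options(swrpipe.verbose = FALSE)

# A deterministic mini spike train.
mk_train <- function(times, id = "u1", region = "CA1") {
  spike_train(id, region, times)
}

# Homogeneous Poisson train on [0, dur].
poisson_train <- function(rate_hz, dur_s, id = "p", region = "RSC") {
  spike_train(id, region, sort(runif(rpois(1, rate_hz * dur_s), 0, dur_s)))
}

# Literal O(n) single-pass ripple detector: walks the normalised power
# trace sample by sample, merges gaps < merge_gap, then applies the
# duration and peak rules exactly as stated.
oracle_ripples <- function(lfp, thr_env = 1, thr_peak = 4,
                           dur = c(0.015, 0.200), merge_gap = 0.020,
                           smooth_sd_s = 0.0125) {
  z_sig <- swrpipe:::normalized_band_power(lfp, c(140, 250), smooth_sd_s)
  z <- z_sig$samples
  fs <- z_sig$rate_hz
  segs <- list()
  i <- 1L
  while (i <= length(z)) {
    if (z[i] > thr_env) {
      j <- i
      while (j < length(z) && z[j + 1L] > thr_env) j <- j + 1L
      segs[[length(segs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(segs)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  # merge
  merged <- list(segs[[1]])
  for (k in seq_along(segs)[-1]) {
    last <- merged[[length(merged)]]
    gap_s <- (segs[[k]][1] - 1 - last[2]) / fs
    if (gap_s < merge_gap) merged[[length(merged)]] <- c(last[1], segs[[k]][2])
    else merged[[length(merged) + 1L]] <- segs[[k]]
  }
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    peak_s = numeric(0), peak_score = numeric(0))
  for (m in merged) {
    d <- (m[2] - m[1] + 1) / fs
    pk <- m[1] - 1L + which.max(z[m[1]:m[2]])
    if (d >= dur[1] && d <= dur[2] && z[pk] > thr_peak)
      out <- rbind(out, data.frame(start_s = (m[1] - 1) / fs, end_s = m[2] / fs,
                                   peak_s = (pk - 1) / fs, peak_score = z[pk]))
  }
  out
}

# Exact merge-sort OFF-period oracle on pooled spikes.
oracle_off <- function(trains, span, min_gap = 0.100, merge_gap = 0.005) {
  pooled <- sort(unlist(lapply(trains, `[[`, "times_s")))
  pooled <- c(span[1], pooled[pooled >= span[1] & pooled <= span[2]], span[2])
  st <- en <- numeric(0)
  for (i in seq_len(length(pooled) - 1)) {
    if (pooled[i + 1] - pooled[i] > min_gap) {
      st <- c(st, pooled[i]); en <- c(en, pooled[i + 1])
    }
  }
  # merge close OFF periods
  if (length(st) > 1) {
    keep_st <- st[1]; keep_en <- en[1]; os <- oe <- numeric(0)
    for (i in seq_along(st)[-1]) {
      if (st[i] - keep_en < merge_gap) keep_en <- en[i]
      else { os <- c(os, keep_st); oe <- c(oe, keep_en)
             keep_st <- st[i]; keep_en <- en[i] }
    }
    st <- c(os, keep_st); en <- c(oe, keep_en)
  }
  data.frame(start_s = st, end_s = en)
}

# Per-bin hypnogram agreement away from true transitions.
scoring_agreement <- function(sim, margin_s = 5) {
  ses <- sim$session
  ratio <- theta_delta_ratio(ses$signals$`CA1-lfp`)
  emgz <- compute_emg_z(ses$signals$EMG)
  hyp <- score_states(ratio, emgz)
  tru <- sim$truth$hypnogram
  grid <- seq(0.1, max(tru$end_s) - 0.1, by = 0.2)
  tl <- tru$state[findInterval(grid, tru$start_s)]
  el <- hyp$state[pmax(1, findInterval(grid, hyp$start_s))]
  trans <- tru$start_s[-1]
  away <- vapply(grid, function(g) all(abs(g - trans) > margin_s), logical(1))
  mean((tl == el)[away])
}

# Accepted-match accuracy of unit tracking against the identity map.
match_accuracy <- function(w) {
  m <- match_units(w$phases$pre, w$phases$post)
  a <- m[m$accepted, ]
  truth_post <- w$identity$post_id[match(a$pre_id, w$identity$pre_id)]
  fam <- w$identity$family
  pre_f <- fam[match(a$pre_id, w$identity$pre_id)]
  post_f <- fam[match(a$post_id, w$identity$post_id)]
  list(n_accepted = nrow(a),
       correct = sum(a$post_id == truth_post),
       cross_family = sum(pre_f != post_f))
}
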