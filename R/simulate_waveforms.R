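# Two-family synthetic waveforms (wide/narrow trough-to-peak) replicated
# across recording phases with additive noise and amplitude drift, plus
# the true identity map for benchmarking tracking and classification.

waveform_template <- function(ttp_ms, trough_w_ms, amp_post, amp_pre,
                              post_w_frac = 0.45, dt_ms = 1 / 30,
                              window_ms = c(-0.2, 0.8)) {
  t <- seq(window_ms[1], window_ms[2], by = dt_ms)
  w <- -exp(-0.5 * (t / trough_w_ms)^2) +
    amp_post * exp(-0.5 * ((t - ttp_ms) / (post_w_frac * ttp_ms))^2) +
    amp_pre * exp(-0.5 * ((t + 0.12) / 0.05)^2)
  list(t = t, w = w)
}

#' Simulate per-phase unit waveforms with a known identity map
#'
#' Each unit draws a family (wide: trough-to-peak ~ U(0.6, 0.8) ms;
#' narrow: ~ U(0.2, 0.4) ms) and private shape parameters; each phase
#' observes template x amplitude drift + additive Gaussian noise scaled to
#' the peak-to-trough amplitude.  Units are distributed over channels
#' (`units_per_channel` each) and post/task orders are shuffled so that
#' matching is non-trivial.
#'
#' @param n_wide,n_narrow family sizes.
#' @param noise_sd additive noise SD as a fraction of peak-to-trough
#'   amplitude (e.g. 0.05).
#' @param seed integer seed.
#' @param phases phase names, default pre/task/post.
#' @param units_per_channel channel packing, default 4.
#' @param drift amplitude drift range across phases, default
#'   `c(0.95, 1.05)`.
#' @return list: `phases` (named list of [unit_waveform()] lists),
#'   `identity` (data.frame pre_id/task_id/post_id/family),
#'   `families` (per latent unit).
#' @export
simulate_waveforms <- function(n_wide, n_narrow, noise_sd, seed = 1,
                               phases = c("pre", "task", "post"),
                               units_per_channel = 4,
                               drift = c(0.95, 1.05)) {
  set.seed(child_seed(seed, "waveforms"))
  n <- n_wide + n_narrow
  fam <- c(rep("wide", n_wide), rep("narrow", n_narrow))
  params <- lapply(seq_len(n), function(u) {
    ttp <- if (fam[u] == "wide") runif(1, 0.6, 0.8) else runif(1, 0.2, 0.4)
    list(ttp = ttp, trough_w = runif(1, 0.06, 0.10),
         amp_post = runif(1, 0.25, 0.5), amp_pre = runif(1, 0.05, 0.2),
         scale = runif(1, 80, 250))
  })
  channel <- ((seq_len(n) - 1) %/% units_per_channel) + 1L
  out <- list()
  orders <- list()
  for (ph in phases) {
    ord <- if (ph == phases[1]) seq_len(n) else sample.int(n)
    orders[[ph]] <- ord
    out[[ph]] <- lapply(seq_len(n), function(k) {
      u <- ord[k]
      p <- params[[u]]
      tpl <- waveform_template(p$ttp, p$trough_w, p$amp_post, p$amp_pre)
      w <- tpl$w * p$scale * runif(1, drift[1], drift[2])
      p2t <- max(w) - min(w)
      w <- w + rnorm(length(w), 0, noise_sd * p2t)
      unit_waveform(sprintf("%s-%02d", ph, k), w, dt_ms = 1 / 30,
                    trough_index = which.min(w), channel = channel[u])
    })
  }
  identity <- data.frame(latent = seq_len(n), family = fam)
  for (ph in phases)
    identity[[paste0(ph, "_id")]] <-
      sprintf("%s-%02d", ph, match(seq_len(n), orders[[ph]]))
  list(phases = out, identity = identity, families = fam)
}
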