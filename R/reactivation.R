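# Cross-regional assembly reactivation: pairwise CA1-RSC correlations,
# run-epoch co-firing template, time-resolved reactivation strength R(t)
# and its peri-SWR statistics.

# z-score count matrix columns (bins x cells); returns NULL-variance mask.
zscore_counts <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  ok <- is.finite(sdv) & sdv > 0
  z <- sweep(sweep(m, 2, mu), 2, ifelse(ok, sdv, 1), "/")
  z[, !ok] <- 0
  list(z = z, ok = ok)
}

#' Pairwise CA1-RSC spike-count correlations per phase
#'
#' Pearson r on 50-ms binned counts within each phase's epochs.  Task-run
#' significance is assessed per pair against a circular-shift surrogate
#' null of the RSC counts (`n_surrogate` draws, two-sided): pairs above
#' the `1 - alpha/2` quantile are `positive`, below `alpha/2` `negative`,
#' otherwise (or with zero-variance counts) `unreliable`.
#'
#' @param ca1_trains,rsc_trains lists of [spike_train()].
#' @param epochs named list of [interval_set()] per phase, e.g.
#'   `list(pre_nrem = ..., task_run = ..., post_nrem = ...)`.
#' @param bin bin width (s), default 0.050.
#' @param sig_phase phase used for the significance class (default
#'   `"task_run"`).
#' @param n_surrogate surrogate draws (default 100).
#' @param alpha two-sided level (default 0.05).
#' @return data.frame with one row per (CA1, RSC) pair: r per phase and
#'   `class`.
#' @export
pair_correlations <- function(ca1_trains, rsc_trains, epochs, bin = 0.050,
                              sig_phase = "task_run", n_surrogate = 100,
                              alpha = 0.05) {
  count_phase <- function(ph) {
    ivs <- epochs[[ph]]
    blocks <- lapply(seq_len(nrow(ivs)), function(i) {
      span <- c(ivs$start_s[i], ivs$end_s[i])
      if (diff(span) < bin) return(NULL)
      bin_counts(c(ca1_trains, rsc_trains), bin, span)
    })
    do.call(rbind, Filter(Negate(is.null), blocks))
  }
  counts <- lapply(names(epochs), count_phase)
  names(counts) <- names(epochs)
  n_ca1 <- length(ca1_trains); n_rsc <- length(rsc_trains)
  pairs <- expand.grid(ca1 = seq_len(n_ca1), rsc = seq_len(n_rsc))
  out <- data.frame(
    ca1_unit = vapply(ca1_trains, `[[`, "", "unit_id")[pairs$ca1],
    rsc_unit = vapply(rsc_trains, `[[`, "", "unit_id")[pairs$rsc])
  for (ph in names(epochs)) {
    m <- counts[[ph]]
    out[[paste0("r_", ph)]] <- vapply(seq_len(nrow(pairs)), function(k) {
      x <- m[, pairs$ca1[k]]; y <- m[, n_ca1 + pairs$rsc[k]]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    }, numeric(1))
  }
  # significance class on the sig_phase counts
  m <- counts[[sig_phase]]
  nb <- nrow(m)
  shifts <- sample.int(nb - 2, min(n_surrogate, nb - 2)) + 1L
  cls <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- m[, pairs$ca1[k]]; y <- m[, n_ca1 + pairs$rsc[k]]
    if (sd(x) == 0 || sd(y) == 0) return("unreliable")
    r <- cor(x, y)
    null_r <- vapply(shifts, function(s)
      cor(x, y[(seq_len(nb) + s - 1L) %% nb + 1L]), numeric(1))
    lo <- quantile(null_r, alpha / 2); hi <- quantile(null_r, 1 - alpha / 2)
    if (r > hi) "positive" else if (r < lo) "negative" else "unreliable"
  }, "")
  out$class <- cls
  out
}

#' Build the run-epoch CA1-RSC co-firing template
#'
#' `C = t(Z_CA1) %*% Z_RSC / n_bins`: the cell-pair correlation matrix of
#' z-scored run-epoch counts (CA1 cells x RSC cells).  Silent units are
#' excluded with a warning and the >= 4 + 4 ensemble-size requirement is
#' re-checked afterwards.
#'
#' @param ca1_counts_run,rsc_counts_run count matrices (bins x cells) on a
#'   common bin grid (100 ms in the standard pipeline).
#' @param min_cells minimum cells per region (default 4).
#' @return list `(C, ca1_keep, rsc_keep, n_bins)`.
#' @export
build_template <- function(ca1_counts_run, rsc_counts_run, min_cells = 4) {
  stopifnot(nrow(ca1_counts_run) == nrow(rsc_counts_run))
  za <- zscore_counts(ca1_counts_run)
  zb <- zscore_counts(rsc_counts_run)
  if (any(!za$ok) || any(!zb$ok))
    warning(sprintf("build_template: excluded %d silent unit(s)",
                    sum(!za$ok) + sum(!zb$ok)))
  if (sum(za$ok) < min_cells || sum(zb$ok) < min_cells)
    stop(sprintf("build_template: need at least %d cells per region",
                 min_cells))
  n_bins <- nrow(ca1_counts_run)
  C <- crossprod(za$z[, za$ok, drop = FALSE],
                 zb$z[, zb$ok, drop = FALSE]) / n_bins
  list(C = C, ca1_keep = which(za$ok), rsc_keep = which(zb$ok),
       n_bins = n_bins)
}

#' Time-resolved reactivation strength
#'
#' `R(t) = z_CA1(t) %*% C %*% t(z_RSC(t))` per sleep bin, where the sleep
#' counts are z-scored with the sleep-epoch statistics, then R is z-scored
#' over the epoch.
#'
#' @param template result of [build_template()].
#' @param ca1_counts_sleep,rsc_counts_sleep count matrices (bins x cells,
#'   full cell sets; the template's kept columns are used).
#' @param t_bins bin-centre times (s) aligned with the rows.
#' @return a `reactivation_trace`: list `(t, R_z, R_raw, template)`.
#' @export
reactivation_strength <- function(template, ca1_counts_sleep,
                                  rsc_counts_sleep, t_bins) {
  if (ncol(ca1_counts_sleep) < max(template$ca1_keep) ||
      ncol(rsc_counts_sleep) < max(template$rsc_keep))
    stop("reactivation_strength: dimension mismatch with template")
  za <- zscore_counts(ca1_counts_sleep[, template$ca1_keep, drop = FALSE])$z
  zb <- zscore_counts(rsc_counts_sleep[, template$rsc_keep, drop = FALSE])$z
  if (ncol(za) != nrow(template$C) || ncol(zb) != ncol(template$C))
    stop("reactivation_strength: dimension mismatch with template")
  raw <- rowSums((za %*% template$C) * zb)
  structure(list(t = t_bins, R_z = as.numeric(zscore(raw)),
                 R_raw = raw, template = template),
            class = "reactivation_trace")
}

#' Peri-SWR reactivation strength with a random-onset null
#'
#' Averages R(t) in a +-1 s window around SWR onsets, draws `n_shuffle`
#' random onset sets of matched size for a null band, and tests the
#' real lag-0 values against the null lag-0 mean with a one-sided
#' Wilcoxon signed-rank test.
#'
#' @param trace a [reactivation_strength()] result.
#' @param swr_onsets SWR onset times (s).
#' @param window lag window (s), default `c(-1, 1)`.
#' @param n_shuffle random-onset draws, default 100.
#' @return list `(lags_s, mean_R, null_mean, null_lo, null_hi, p_lag0)`.
#' @export
peri_swr_reactivation <- function(trace, swr_onsets, window = c(-1, 1),
                                  n_shuffle = 100) {
  if (!length(swr_onsets)) stop("peri_swr_reactivation: no SWRs")
  bin <- stats::median(diff(trace$t))
  n_lag <- round(window[2] / bin)
  lags <- (-n_lag):n_lag
  t0 <- trace$t[1]
  n_bins <- length(trace$R_z)
  snip <- function(onsets) {
    ctr <- round((onsets - t0) / bin) + 1L
    ctr <- ctr[ctr - n_lag >= 1 & ctr + n_lag <= n_bins]
    if (!length(ctr)) return(NULL)
    t(vapply(ctr, function(c0) trace$R_z[c0 + lags],
             numeric(length(lags))))
  }
  real <- snip(swr_onsets)
  if (is.null(real)) stop("peri_swr_reactivation: no SWR windows inside trace")
  null_means <- matrix(NA_real_, n_shuffle, length(lags))
  lo <- t0 + n_lag * bin
  hi <- trace$t[n_bins] - n_lag * bin
  null_lag0 <- numeric(n_shuffle)
  for (s in seq_len(n_shuffle)) {
    rnd <- runif(nrow(real), lo, hi)
    m <- snip(rnd)
    null_means[s, ] <- colMeans(m)
    null_lag0[s] <- mean(m[, n_lag + 1])
  }
  mu_null <- mean(null_lag0)
  x <- real[, n_lag + 1] - mu_null
  p <- if (all(x == 0)) 0.5 else
    suppressWarnings(wilcox.test(x, alternative = "greater")$p.value)
  list(lags_s = lags * bin, mean_R = colMeans(real),
       null_mean = colMeans(null_means),
       null_lo = apply(null_means, 2, quantile, 0.025),
       null_hi = apply(null_means, 2, quantile, 0.975),
       p_lag0 = p, n_events = nrow(real))
}
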