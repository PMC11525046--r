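# Waveform-based putative cell-type classification and the autocorrelogram
# rise constant used by the CA1 rule.

#' Construct a unit waveform
#'
#' @param unit_id unit identifier.
#' @param mean_waveform average waveform (microvolts), covering -0.2 to
#'   +0.8 ms around the trough.
#' @param dt_ms sample interval (ms), > 0.
#' @param trough_index index of the trough (1-based).
#' @param channel optional channel id (restricts tracking candidates).
#' @return a `unit_waveform` object.
#' @export
unit_waveform <- function(unit_id, mean_waveform, dt_ms, trough_index,
                          channel = NA_integer_) {
  stopifnot(dt_ms > 0, trough_index >= 1,
            trough_index <= length(mean_waveform))
  structure(list(unit_id = as.character(unit_id),
                 mean_waveform = as.numeric(mean_waveform),
                 dt_ms = dt_ms, trough_index = as.integer(trough_index),
                 channel = channel),
            class = "unit_waveform")
}

#' Scalar features of a mean waveform
#'
#' `trough_to_peak_ms`: trough to the following positive peak;
#' `trough_to_peak_amp_uv`: amplitude of that excursion;
#' `peak_to_trough_amp_uv`: amplitude difference between the trough and
#' the first peak before the trough.
#'
#' @param wf a [unit_waveform()].
#' @return named list of the three features.
#' @export
waveform_features <- function(wf) {
  w <- wf$mean_waveform; ti <- wf$trough_index
  post <- w[ti:length(w)]
  ipk <- ti - 1L + which.max(post)
  pre <- w[1:ti]
  ipre <- which.max(pre)
  list(trough_to_peak_ms = (ipk - ti) * wf$dt_ms,
       trough_to_peak_amp_uv = w[ipk] - w[ti],
       peak_to_trough_amp_uv = w[ipre] - w[ti])
}

# Waveform scaled to unit peak-to-trough amplitude.
normalize_waveform <- function(wf) {
  amp <- max(wf$mean_waveform) - min(wf$mean_waveform)
  if (amp == 0) stop("normalize_waveform: flat waveform")
  wf$mean_waveform / amp
}

#' Classify RSC units as wide or narrow spiking
#'
#' Waveforms are normalised by peak-to-trough amplitude, reduced to their
#' 3 major principal components, hierarchically clustered (Ward linkage on
#' Euclidean distance) and cut into 3 clusters.  The clusters with the
#' longest and shortest mean trough-to-peak duration become
#' wide/excitatory and narrow/inhibitory; the middle cluster is assigned
#' to the nearer class centroid and flagged.
#'
#' @param waveforms list of [unit_waveform()] (>= 3 units).
#' @return data.frame `(unit_id, cluster, label, flagged)` with labels
#'   `"wide"`/`"narrow"`.
#' @export
classify_rsc <- function(waveforms) {
  n <- length(waveforms)
  if (n < 3) stop("classify_rsc: need at least 3 units (degenerate input)")
  mat <- t(vapply(waveforms, normalize_waveform,
                  numeric(length(waveforms[[1]]$mean_waveform))))
  if (all(apply(mat, 2, var) < 1e-14))
    stop("classify_rsc: identical waveforms give zero-variance PCA")
  pcs <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(3, ncol(pcs))), drop = FALSE]
  cl <- stats::cutree(stats::hclust(stats::dist(pcs), method = "ward.D2"),
                      k = min(3, n))
  ttp <- vapply(waveforms, function(w) waveform_features(w)$trough_to_peak_ms,
                numeric(1))
  cl_ttp <- tapply(ttp, cl, mean)
  ord <- order(cl_ttp)                        # narrow ... wide
  label <- rep(NA_character_, n)
  flagged <- rep(FALSE, n)
  label[cl == names(cl_ttp)[ord[1]]] <- "narrow"
  label[cl == names(cl_ttp)[ord[length(ord)]]] <- "wide"
  if (length(ord) == 3) {
    mid <- names(cl_ttp)[ord[2]]
    d_lo <- abs(cl_ttp[ord[2]] - cl_ttp[ord[1]])
    d_hi <- abs(cl_ttp[ord[2]] - cl_ttp[ord[3]])
    label[cl == mid] <- if (d_lo <= d_hi) "narrow" else "wide"
    flagged[cl == mid] <- TRUE
  }
  data.frame(unit_id = vapply(waveforms, `[[`, "", "unit_id"),
             cluster = as.integer(cl), label = label, flagged = flagged)
}

#' Classify CA1 units by the trough-to-peak / ACG rule
#'
#' Narrow interneurons (putative inhibitory): trough-to-peak <= 0.425 ms.
#' Pyramidal cells (putative excitatory): trough-to-peak > 0.425 ms and
#' `acg_tau_rise` <= 6 ms.  Everything else (including wide waveforms with
#' a missing tau) is unclassified.
#'
#' @param features data.frame with columns `unit_id`, `trough_to_peak_ms`,
#'   `acg_tau_rise_ms` (may be NA).
#' @param ttp_thr_ms,tau_thr_ms rule thresholds (defaults 0.425 and 6 ms).
#' @return data.frame `(unit_id, label, reason)` with labels
#'   `"inhibitory"`, `"excitatory"`, `"unclassified"`.
#' @export
classify_ca1 <- function(features, ttp_thr_ms = 0.425, tau_thr_ms = 6) {
  lab <- rep("unclassified", nrow(features))
  reason <- rep("", nrow(features))
  ttp <- features$trough_to_peak_ms
  tau <- features$acg_tau_rise_ms
  lab[ttp <= ttp_thr_ms] <- "inhibitory"
  exc <- ttp > ttp_thr_ms & !is.na(tau) & tau <= tau_thr_ms
  lab[exc] <- "excitatory"
  miss <- ttp > ttp_thr_ms & is.na(tau)
  reason[miss] <- "missing acg_tau_rise"
  reason[ttp > ttp_thr_ms & !is.na(tau) & tau > tau_thr_ms] <-
    "acg_tau_rise above threshold"
  data.frame(unit_id = features$unit_id, label = lab, reason = reason)
}

#' Autocorrelogram rise constant
#'
#' The spike-train autocorrelogram (0.5 ms bins, +-50 ms) is fitted with
#' the rise-decay double-exponential-plus-burst form used by waveform-based
#' cell typing pipelines:
#' `acg(t) = max(c * (exp(-(t - t0)/tau_decay) - d * exp(-(t - t0)/tau_rise))
#'  + h * exp(-(t - t0)/tau_burst) + r0, 0)`.
#' Returns the rise constant `tau_rise` in ms, or `NA` on fit failure or
#' an essentially flat autocorrelogram.
#'
#' @param train a [spike_train()].
#' @param bin_ms bin width (ms), default 0.5.
#' @param max_lag_ms maximum lag (ms), default 50.
#' @param min_spikes minimum spike count, default 200.
#' @return tau_rise (ms) or `NA`.
#' @export
acg_tau_rise <- function(train, bin_ms = 0.5, max_lag_ms = 50,
                         min_spikes = 200) {
  t <- train$times_s
  if (length(t) < min_spikes) return(NA_real_)
  lags <- spike_lag_pairs(t, t, max_lag_ms / 1000)
  lags <- lags[lags > 0] * 1000                 # ms, positive side
  nb <- round(max_lag_ms / bin_ms)
  counts <- tabulate(pmin(floor(lags / bin_ms) + 1L, nb), nbins = nb)
  x <- (seq_len(nb) - 0.5) * bin_ms
  asym <- mean(counts[x > 30])
  if (asym <= 0) return(NA_real_)
  y <- counts / asym                            # normalised to the tail
  # a flat autocorrelogram (no early dip) has no defined rise constant
  if (mean(y[x <= 2]) > 0.75) {
    swr_log("acg_tau_rise: flat autocorrelogram, tau undefined")
    return(NA_real_)
  }
  ctl <- minpack.lm::nls.lm.control(maxiter = 300)
  # stage 1: rise-only model a * (1 - d * exp(-(x - t0)/tr)) pins the rise
  # constant; stage 2 refines with the decay and burst components, which
  # otherwise trade off against the rise near the origin.
  rise <- function(p) pmax(p["a"] * (1 - p["d"] *
                                       exp(-(x - p["t0"]) / p["tr"])), 0)
  f1 <- tryCatch(minpack.lm::nls.lm(
    par = c(a = 1, d = 1, tr = 3, t0 = 0.5),
    fn = function(p) y - rise(p),
    lower = c(a = 0, d = 0, tr = 0.1, t0 = 0),
    upper = c(a = 10, d = 2, tr = 25, t0 = 8), control = ctl),
    error = function(e) NULL)
  if (is.null(f1) || !f1$info %in% 1:4) return(NA_real_)
  tr1 <- unname(f1$par["tr"])
  model <- function(p) {
    pmax(p["cc"] * (exp(-(x - p["t0"]) / p["td"]) -
                      p["dd"] * exp(-(x - p["t0"]) / p["tr"])) +
           p["hh"] * exp(-(x - p["t0"]) / p["tb"]) + p["r0"], 0)
  }
  f2 <- tryCatch(minpack.lm::nls.lm(
    par = c(cc = 0.2, dd = 1, td = 50, tr = tr1, tb = 0.7, hh = 0.1,
            t0 = unname(f1$par["t0"]), r0 = unname(f1$par["a"])),
    fn = function(p) y - model(p),
    lower = c(cc = 0, dd = 0, td = 1, tr = 0.1, tb = 0.1, hh = 0,
              t0 = 0, r0 = 0),
    upper = c(cc = 50, dd = 5, td = 500, tr = 25, tb = 20, hh = 50,
              t0 = 8, r0 = 5),
    control = ctl),
    error = function(e) NULL)
  if (is.null(f2) || !f2$info %in% 1:4) return(tr1)
  # prefer the refined fit only when it genuinely improves the residual
  if (f2$deviance < 0.98 * f1$deviance) unname(f2$par["tr"]) else tr1
}

# All (b - a) lag pairs within +-max_lag_s; both inputs sorted.
spike_lag_pairs <- function(a, b, max_lag_s) {
  if (!length(a) || !length(b)) return(numeric(0))
  lo <- findInterval(a - max_lag_s, b) + 1L
  hi <- findInterval(a + max_lag_s, b)
  keep <- hi >= lo
  if (!any(keep)) return(numeric(0))
  counts <- hi[keep] - lo[keep] + 1L
  idx <- sequence(counts) + rep(lo[keep], counts) - 1L
  b[idx] - rep(a[keep], counts)
}
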