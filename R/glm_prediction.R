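# Cross-validated GLM prediction of peri-SWR spiking from the other
# region's ensemble, and binomial prediction of SWR occurrence.  The
# prediction gain is mean shuffled-baseline error / mean real error; a
# whole-set predictor<->event shuffle re-run through the identical
# pipeline provides the control gain distribution.

# Poisson/binomial fit with a ridge fallback for degenerate folds.
fit_glm_safe <- function(X, y, family) {
  Xd <- cbind(1, X)
  fit <- tryCatch(
    suppressWarnings(glm.fit(Xd, y, family = family)),
    error = function(e) NULL)
  beta <- if (!is.null(fit) && all(is.finite(fit$coefficients)))
    fit$coefficients else NULL
  if (is.null(beta)) {
    swr_log("fit_glm_safe: ridge-stabilised refit")
    beta <- ridge_irls(Xd, y, family, lambda = 1e-2)
  }
  beta
}

ridge_irls <- function(Xd, y, family, lambda = 1e-2, iters = 50) {
  p <- ncol(Xd)
  beta <- rep(0, p)
  beta[1] <- family$linkfun(max(mean(y), 1e-3))
  pen <- diag(lambda, p); pen[1, 1] <- 0
  for (it in seq_len(iters)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- family$linkinv(eta)
    w <- pmax(family$mu.eta(eta)^2 / family$variance(mu), 1e-8)
    z <- eta + (y - mu) / pmax(family$mu.eta(eta), 1e-8)
    XtW <- t(Xd * w)
    new_beta <- tryCatch(solve(XtW %*% Xd + pen, XtW %*% z),
                         error = function(e) beta)
    if (max(abs(new_beta - beta)) < 1e-8) { beta <- new_beta; break }
    beta <- as.numeric(new_beta)
  }
  beta
}

predict_mu <- function(beta, X, family) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  family$linkinv(pmin(pmax(eta, -30), 30))
}

# Equal-size random fold assignment; stratified on y > 0 when asked.
make_folds <- function(n, k, strat = NULL) {
  fold <- integer(n)
  if (is.null(strat)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    for (cls in unique(strat)) {
      idx <- which(strat == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

# One full cross-validated gain computation on a fixed design.
cv_gain <- function(X, y, k, n_shuffle, family, gain_cap = 10) {
  fold <- make_folds(length(y), k, strat = if (family$family == "binomial")
    y > 0 else NULL)
  err_real <- err_base <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    beta <- fit_glm_safe(X[tr, , drop = FALSE], y[tr], family)
    mu <- predict_mu(beta, X[te, , drop = FALSE], family)
    err_real[f] <- mean(abs(mu - y[te]))
    perm_err <- vapply(seq_len(n_shuffle), function(s)
      mean(abs(mu - sample(y[te]))), numeric(1))
    err_base[f] <- mean(perm_err)
  }
  mr <- mean(err_real); mb <- mean(err_base)
  if (mr == 0) return(if (mb == 0) 1 else gain_cap)
  min(mb / mr, gain_cap)
}

#' Predict one cell's peri-SWR spike count from the other region's ensemble
#'
#' Per SWR, the predictor vector holds each predictor cell's spike count
#' in `predictor_window` (ms relative to SWR onset) and the outcome is the
#' predicted cell's count in `target_window`.  A 5-fold cross-validated
#' Poisson GLM (log link) yields a prediction error (mean absolute
#' difference); the gain is the mean within-fold-shuffled baseline error
#' over the mean real error.  `n_control` whole-set predictor<->SWR
#' shuffles re-run the identical pipeline for the control distribution.
#'
#' @param predictor_trains list of >= 5 [spike_train()] (other region).
#' @param target_train predicted cell.
#' @param swrs SWR [interval_set()] (onsets used).
#' @param epoch `c(t0, t1)`.
#' @param predictor_window,target_window windows in ms relative to onset.
#' @param k folds (5), n_shuffle baseline shuffles (100), n_control
#'   whole-set shuffles (100).
#' @param min_anchors,min_sep_s,min_active eligibility: >= 50 SWRs
#'   separated by >= 300 ms; the target must spike in more than
#'   `min_active` SWRs.
#' @param n_shuffle,n_control see above.
#' @return a `prediction_result` list `(predicted_unit, gain_real,
#'   gains_shuffled, p, n_swr)`, or `NULL` when eligibility fails (logged).
#' @export
predict_cell_counts <- function(predictor_trains, target_train, swrs, epoch,
                                predictor_window = c(-100, 0),
                                target_window = c(0, 100), k = 5,
                                n_shuffle = 100, n_control = 100,
                                min_anchors = 50, min_sep_s = 0.3,
                                min_active = 50) {
  on <- eligible_anchors(swrs$start_s, min_sep_s, epoch, span = c(-1, 1))
  if (length(on) < min_anchors) {
    swr_log("predict_cell_counts: insufficient SWRs, skipped")
    return(NULL)
  }
  if (length(predictor_trains) < 5) {
    swr_log("predict_cell_counts: fewer than 5 predictor cells, skipped")
    return(NULL)
  }
  win_counts <- function(tr, w) {
    vapply(on, function(o)
      sum(tr$times_s >= o + w[1] / 1000 & tr$times_s < o + w[2] / 1000),
      numeric(1))
  }
  X <- vapply(predictor_trains, win_counts, numeric(length(on)),
              w = predictor_window)
  y <- win_counts(target_train, target_window)
  if (sum(y > 0) <= min_active) {
    swr_log(sprintf("predict_cell_counts: target %s spiked in %d SWRs (<= %d), skipped",
                    target_train$unit_id, sum(y > 0), min_active))
    return(NULL)
  }
  fam <- poisson()
  gain_real <- cv_gain(X, y, k, n_shuffle, fam)
  gains_shuffled <- vapply(seq_len(n_control), function(s)
    cv_gain(X[sample.int(nrow(X)), , drop = FALSE], y, k, n_shuffle, fam),
    numeric(1))
  p <- (1 + sum(gains_shuffled >= gain_real)) / (1 + n_control)
  structure(list(predicted_unit = target_train$unit_id,
                 predictor_window = predictor_window,
                 target_window = target_window,
                 gain_real = gain_real, gains_shuffled = gains_shuffled,
                 p = p, n_swr = length(on)),
            class = "prediction_result")
}

#' Predict SWR occurrence from RSC population activity
#'
#' The post-sleep epoch is tiled with 100-ms bins; the outcome is 1 when
#' an SWR onset falls in the bin.  A stratified 5-fold cross-validated
#' binomial GLM (logit link) on the per-bin RSC ensemble counts yields the
#' prediction gain as above; the control shuffles the occurrence vector
#' (preserving the SWR count) and re-runs the identical pipeline.
#'
#' @param rsc_trains list of RSC [spike_train()].
#' @param swrs SWR [interval_set()].
#' @param epoch `c(t0, t1)`.
#' @param bin bin width (s), default 0.1.
#' @param k,n_shuffle,n_control as in [predict_cell_counts()].
#' @return a `prediction_result` (predicted unit `"swr_occurrence"`).
#' @export
predict_swr_occurrence <- function(rsc_trains, swrs, epoch, bin = 0.1,
                                   k = 5, n_shuffle = 100, n_control = 100) {
  X <- bin_counts(rsc_trains, bin, epoch)
  n_bins <- nrow(X)
  y <- numeric(n_bins)
  idx <- floor((swrs$start_s - epoch[1]) / bin) + 1L
  idx <- idx[idx >= 1 & idx <= n_bins]
  y[unique(idx)] <- 1
  if (sum(y) == 0) stop("predict_swr_occurrence: all-zero occurrence vector")
  fam <- binomial()
  gain_real <- cv_gain(X, y, k, n_shuffle, fam)
  gains_shuffled <- vapply(seq_len(n_control), function(s)
    cv_gain(X, sample(y), k, n_shuffle, fam), numeric(1))
  p <- (1 + sum(gains_shuffled >= gain_real)) / (1 + n_control)
  structure(list(predicted_unit = "swr_occurrence", gain_real = gain_real,
                 gains_shuffled = gains_shuffled, p = p,
                 n_swr = sum(y), n_bins = n_bins),
            class = "prediction_result")
}

#' Summarise prediction results over windows and directions
#'
#' For each (direction, window[, cell class]) cell of the grid, compares
#' the real gains across predicted units with the pooled shuffled gains
#' by a two-sided rank-sum test.
#'
#' @param results list of [predict_cell_counts()] results.
#' @param direction,window,cell_class vectors aligned with `results`
#'   (recycled labels describing each entry).
#' @return data.frame `(direction, window, cell_class, n_units,
#'   mean_gain, mean_gain_shuffled, p)`.
#' @export
directional_summary <- function(results,
                                direction = rep("rsc2ca1", length(results)),
                                window = rep("(-100,0)", length(results)),
                                cell_class = rep("all", length(results))) {
  keep <- !vapply(results, is.null, logical(1))
  results <- results[keep]
  direction <- direction[keep]; window <- window[keep]
  cell_class <- cell_class[keep]
  key <- paste(direction, window, cell_class, sep = "|")
  rows <- lapply(unique(key), function(kk) {
    sel <- which(key == kk)
    gains <- vapply(results[sel], `[[`, numeric(1), "gain_real")
    shuf <- unlist(lapply(results[sel], `[[`, "gains_shuffled"))
    p <- if (length(gains) >= 2)
      suppressWarnings(wilcox.test(gains, shuf)$p.value)
    else results[[sel[1]]]$p
    parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
    data.frame(direction = parts[1], window = parts[2],
               cell_class = parts[3], n_units = length(gains),
               mean_gain = mean(gains), mean_gain_shuffled = mean(shuf),
               p = p)
  })
  do.call(rbind, rows)
}
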