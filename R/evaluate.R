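# Benchmarking helpers: compare detected events against a ground-truth
# event set.

#' Precision and recall of detected events against ground truth
#'
#' Greedy one-to-one matching: a detected event matches a true event when
#' their peaks (falling back to interval midpoints) are within `tol_s`.
#'
#' @param detected,truth [interval_set()]s.
#' @param tol_s matching tolerance (s), default 0.1.
#' @return list `(recall, precision, n_detected, n_true, n_matched,
#'   peak_err_s)`.
#' @export
detector_performance <- function(detected, truth, tol_s = 0.1) {
  peak_of <- function(ivs) {
    p <- ivs$peak_s
    if (is.null(p)) p <- (ivs$start_s + ivs$end_s) / 2
    p
  }
  dp <- peak_of(detected); tp <- peak_of(truth)
  used <- rep(FALSE, length(tp))
  err <- numeric(0)
  matched <- 0L
  for (d in dp) {
    cand <- which(!used & abs(tp - d) <= tol_s)
    if (length(cand)) {
      j <- cand[which.min(abs(tp[cand] - d))]
      used[j] <- TRUE
      matched <- matched + 1L
      err <- c(err, d - tp[j])
    }
  }
  list(recall = if (length(tp)) matched / length(tp) else NA_real_,
       precision = if (length(dp)) matched / length(dp) else NA_real_,
       n_detected = length(dp), n_true = length(tp), n_matched = matched,
       peak_err_s = err)
}
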