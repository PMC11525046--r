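# Cross-session single-unit matching from average spike waveforms:
# feature similarities plus DTW-aligned global similarities, combined as
# weighted L2 norms, with greedy one-to-one acceptance and review flags in
# place of manual curation.

#' Dynamic time warping of two sequences
#'
#' Classic DTW with a Sakoe-Chiba band (default 10% of the longer length,
#' ~0.1 ms on an upsampled 1-ms waveform: enough to absorb sampling
#' offsets, not enough to warp one cell type onto another) and symmetric
#' steps.  Returns the alignment path and both sequences expanded along
#' it.
#'
#' @param a,b numeric vectors.
#' @param band band half-width as a fraction of `max(length(a), length(b))`;
#'   `Inf` disables the constraint.
#' @return list `(path_i, path_j, a_warped, b_warped, distance)`.
#' @export
dtw_align <- function(a, b, band = 0.1) {
  n <- length(a); m <- length(b)
  w <- if (is.finite(band)) max(ceiling(band * max(n, m)), abs(n - m) + 1) else
    max(n, m)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    j0 <- max(1L, i - w); j1 <- min(m, i + w)
    for (j in j0:j1) {
      cost <- abs(a[i] - b[j])
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  # backtrack
  i <- n; j <- m
  pi <- pj <- integer(0)
  while (i >= 1 && j >= 1) {
    pi <- c(i, pi); pj <- c(j, pj)
    step <- which.min(c(D[i, j], D[i, j + 1], D[i + 1, j]))
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
  }
  list(path_i = pi, path_j = pj, a_warped = a[pi], b_warped = b[pj],
       distance = D[n + 1, m + 1])
}

# max(0, 1 - |pre - post| / |pre|)
local_similarity <- function(pre, post) {
  if (pre == 0) return(ifelse(post == 0, 1, 0))
  max(0, 1 - abs(pre - post) / abs(pre))
}

#' Condition a mean waveform for comparison
#'
#' Light Gaussian smoothing plus cubic-spline upsampling: residual noise
#' on an averaged waveform otherwise shifts the discrete peak positions
#' that the local feature similarities depend on.
#'
#' @param wf a [unit_waveform()].
#' @param smooth_sd smoothing SD in (original) samples, default 3.
#' @param upsample integer upsampling factor, default 3.
#' @return a `unit_waveform` on the finer grid, trough re-located.
#' @export
prep_waveform <- function(wf, smooth_sd = 3, upsample = 3) {
  w <- gaussian_smooth(wf$mean_waveform, smooth_sd)
  n <- length(w)
  if (upsample > 1) {
    s <- stats::spline(seq_len(n), w, n = (n - 1) * upsample + 1)
    w <- s$y
  }
  unit_waveform(wf$unit_id, w, wf$dt_ms / upsample, which.min(w),
                channel = wf$channel)
}

# Local + global similarity components for one candidate pair; inputs
# are expected to be prep_waveform()-conditioned.
pair_similarity <- function(wf_pre, wf_post, band = 0.1) {
  fp <- waveform_features(wf_pre)
  fq <- waveform_features(wf_post)
  local <- c(duration = local_similarity(fp$trough_to_peak_ms,
                                         fq$trough_to_peak_ms),
             t2p_amp = local_similarity(fp$trough_to_peak_amp_uv,
                                        fq$trough_to_peak_amp_uv),
             p2t_amp = local_similarity(fp$peak_to_trough_amp_uv,
                                        fq$peak_to_trough_amp_uv))
  na <- normalize_waveform(wf_pre)
  nb <- normalize_waveform(wf_post)
  al <- dtw_align(na, nb, band)
  global <- c(
    waveform_similarity = max(0, 1 - max(abs(al$a_warped - al$b_warped))),
    waveform_correlation = suppressWarnings(
      cor(al$a_warped, al$b_warped)) %||% 0,
    dtw_scale_factor = length(na) / length(al$path_i))
  global[!is.finite(global)] <- 0
  list(local = local, global = global)
}

#' Match single units across two recording phases
#'
#' For every pre-phase unit, candidates are the post-phase units on the
#' same channel.  Three local feature similarities
#' `max(0, 1 - |pre - post| / pre)` and three DTW-aligned global
#' similarities (waveform similarity, warped-waveform Pearson correlation,
#' DTW scale factor) are combined as
#' `score = (1/5) * ||local||_2 + (4/5) * ||global||_2`.
#' A pre unit accepts its highest-scoring candidate when warped
#' correlation >= `min_corr` and duration similarity >= `min_dur_sim`; a
#' post unit claimed by several pre units keeps only the largest score.
#' Ambiguous winners (runner-up within `flag_margin`) carry a review flag
#' in place of manual curation.
#'
#' @param pre_waveforms,post_waveforms lists of [unit_waveform()] with
#'   `channel` set.
#' @param min_corr acceptance threshold on warped correlation (0.95).
#' @param min_dur_sim acceptance threshold on duration similarity (0.7).
#' @param w_local,w_global category weights (1/5 and 4/5).
#' @param flag_margin review-flag margin on the score.
#' @param band DTW band fraction.
#' @return data.frame, one row per (pre, candidate) best pair:
#'   `(pre_id, post_id, sim_duration, sim_t2p_amp, sim_p2t_amp,
#'   waveform_similarity, waveform_correlation, dtw_scale_factor, score,
#'   accepted, review_flag)`.
#' @export
match_units <- function(pre_waveforms, post_waveforms, min_corr = 0.95,
                        min_dur_sim = 0.7, w_local = 1 / 5, w_global = 4 / 5,
                        flag_margin = 0.05, band = 0.1) {
  pre_waveforms <- lapply(pre_waveforms, prep_waveform)
  post_waveforms <- lapply(post_waveforms, prep_waveform)
  rows <- list()
  post_ch <- vapply(post_waveforms, function(w) as.numeric(w$channel),
                    numeric(1))
  for (p in pre_waveforms) {
    cand <- which(is.na(p$channel) | is.na(post_ch) | post_ch == p$channel)
    if (!length(cand)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = p$unit_id, post_id = NA_character_, sim_duration = NA,
        sim_t2p_amp = NA, sim_p2t_amp = NA, waveform_similarity = NA,
        waveform_correlation = NA, dtw_scale_factor = NA, score = NA,
        accepted = FALSE, review_flag = TRUE)
      next
    }
    for (ci in cand) {
      q <- post_waveforms[[ci]]
      s <- pair_similarity(p, q, band)
      score <- w_local * sqrt(sum(s$local^2)) +
        w_global * sqrt(sum(s$global^2))
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = p$unit_id, post_id = q$unit_id,
        sim_duration = s$local[["duration"]],
        sim_t2p_amp = s$local[["t2p_amp"]],
        sim_p2t_amp = s$local[["p2t_amp"]],
        waveform_similarity = s$global[["waveform_similarity"]],
        waveform_correlation = s$global[["waveform_correlation"]],
        dtw_scale_factor = s$global[["dtw_scale_factor"]],
        score = score, accepted = FALSE, review_flag = FALSE)
    }
  }
  all_pairs <- do.call(rbind, rows)
  if (is.null(all_pairs)) return(all_pairs)

  # per pre unit: best candidate meeting the acceptance criteria
  for (pid in unique(all_pairs$pre_id)) {
    sel <- which(all_pairs$pre_id == pid & !is.na(all_pairs$score))
    if (!length(sel)) next
    ord <- sel[order(-all_pairs$score[sel])]
    best <- ord[1]
    ok <- isTRUE(all_pairs$waveform_correlation[best] >= min_corr &&
                   all_pairs$sim_duration[best] >= min_dur_sim)
    if (ok) {
      all_pairs$accepted[best] <- TRUE
      if (length(ord) > 1 &&
          all_pairs$score[best] - all_pairs$score[ord[2]] < flag_margin)
        all_pairs$review_flag[best] <- TRUE
    }
  }
  # one-to-one: a post unit claimed by several pre units keeps the largest
  acc <- which(all_pairs$accepted)
  if (length(acc)) {
    for (qid in unique(all_pairs$post_id[acc])) {
      sel <- acc[all_pairs$post_id[acc] == qid]
      if (length(sel) > 1) {
        keep <- sel[which.max(all_pairs$score[sel])]
        drop <- setdiff(sel, keep)
        all_pairs$accepted[drop] <- FALSE
        all_pairs$review_flag[keep] <- TRUE
      }
      acc <- which(all_pairs$accepted)
    }
  }
  all_pairs
}

#' Track units present in all three recording phases
#'
#' Intersects pre-sleep/post-sleep and task/post-sleep accepted matches on
#' the post-sleep unit; a post unit reached by inconsistent chains is
#' flagged and excluded.
#'
#' @param pre_post,task_post data.frames from [match_units()].
#' @return data.frame `(pre_id, task_id, post_id)`, one row per unit
#'   tracked through all 3 phases.
#' @export
track_three_phases <- function(pre_post, task_post) {
  a <- pre_post[pre_post$accepted, c("pre_id", "post_id")]
  b <- task_post[task_post$accepted, c("pre_id", "post_id")]
  names(b) <- c("task_id", "post_id")
  m <- merge(a, b, by = "post_id")
  m[, c("pre_id", "task_id", "post_id")]
}
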