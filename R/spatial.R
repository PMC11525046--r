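# Spatial coding on the figure-eight maze: occupancy-normalised rate
# maps, place-field detection, splitter / location-related classification
# on the stem, and speed-cell screening.

#' Occupancy-normalised spatial rate map
#'
#' Spikes and occupancy are restricted to frames with running speed above
#' `speed_min`; spike and time maps are smoothed with a 2-D Gaussian
#' kernel over the neighbouring 5 x 5 bins and divided.
#'
#' @param train a [spike_train()].
#' @param traj data.frame `(time_s, x_cm, y_cm)`.
#' @param bounds `c(x_max, y_max)` of the arena (cm); default 78 x 52.
#' @param bin_cm square bin size (cm), default 0.36.
#' @param speed_min speed filter (cm/s), default 3.
#' @param min_spikes units with fewer speed-filtered spikes are excluded
#'   (default 200) and `NULL` is returned with a logged reason.
#' @param kernel_sd_bins Gaussian SD of the 5 x 5 kernel (default 1).
#' @return a `rate_map`: list `(rate_hz, occupancy_s, spike_counts,
#'   x_edges, y_edges, mean_rate_hz, n_spikes)`, or `NULL`.
#' @export
rate_map <- function(train, traj, bounds = c(78, 52), bin_cm = 0.36,
                     speed_min = 3, min_spikes = 200, kernel_sd_bins = 1) {
  speed <- trajectory_speed(traj)
  moving <- speed > speed_min
  dt <- c(diff(traj$time_s), median(diff(traj$time_s)))
  nx <- ceiling(bounds[1] / bin_cm); ny <- ceiling(bounds[2] / bin_cm)
  xb <- pmin(pmax(floor(traj$x_cm / bin_cm) + 1L, 1L), nx)
  yb <- pmin(pmax(floor(traj$y_cm / bin_cm) + 1L, 1L), ny)
  occ <- matrix(0, nx, ny)
  sel <- which(moving)
  for (i in sel) occ[xb[i], yb[i]] <- occ[xb[i], yb[i]] + dt[i]
  # spike -> frame assignment; keep spikes on moving frames
  fr <- findInterval(train$times_s, traj$time_s)
  fr <- fr[fr >= 1 & fr <= nrow(traj)]
  fr <- fr[moving[fr]]
  if (length(fr) < min_spikes) {
    swr_log(sprintf("rate_map: unit %s has %d speed-filtered spikes (< %d), excluded",
                    train$unit_id, length(fr), min_spikes))
    return(NULL)
  }
  spk <- matrix(0, nx, ny)
  for (i in fr) spk[xb[i], yb[i]] <- spk[xb[i], yb[i]] + 1
  k1 <- gauss5 <- local({
    g <- exp(-0.5 * ((-2:2) / kernel_sd_bins)^2); g / sum(g)
  })
  smooth2 <- function(m) {
    m <- apply(m, 2, function(col) as.numeric(stats::filter(col, k1, sides = 2)))
    m[is.na(m)] <- 0
    m <- t(apply(m, 1, function(row) as.numeric(stats::filter(row, k1, sides = 2))))
    m[is.na(m)] <- 0
    m
  }
  occ_s <- smooth2(occ); spk_s <- smooth2(spk)
  rate <- matrix(0, nx, ny)
  pos <- occ_s > 1e-9
  rate[pos] <- spk_s[pos] / occ_s[pos]
  total_t <- sum(dt[sel])
  structure(list(rate_hz = rate, occupancy_s = occ, spike_counts = spk,
                 x_edges = (0:nx) * bin_cm, y_edges = (0:ny) * bin_cm,
                 mean_rate_hz = length(fr) / total_t, n_spikes = length(fr)),
            class = "rate_map")
}

# 8-connected component labelling of a logical matrix (BFS).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  nr <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(mask)) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Detect robust place fields in a rate map
#'
#' Fields are connected components (8-neighbour) of bins firing at least
#' `rate_factor` times the unit's mean rate, containing at least
#' `min_bins` bins and fitting inside a `patch x patch` bounding box.
#'
#' @param map a [rate_map()].
#' @param rate_factor threshold multiple of the mean rate (default 2).
#' @param min_bins minimum component size (default 40).
#' @param patch bounding-box limit in bins (default 7).
#' @return data.frame, one row per field `(n_bins, x_lo, x_hi, y_lo, y_hi,
#'   peak_rate_hz)`; zero rows when no field qualifies.
#' @export
find_place_fields <- function(map, rate_factor = 2, min_bins = 40,
                              patch = 7) {
  thr <- rate_factor * map$mean_rate_hz
  mask <- map$rate_hz >= thr
  lab <- label_components(mask)
  out <- data.frame(n_bins = integer(0), x_lo = integer(0),
                    x_hi = integer(0), y_lo = integer(0), y_hi = integer(0),
                    peak_rate_hz = numeric(0))
  if (!any(mask)) return(out)
  for (cc in seq_len(max(lab))) {
    cells <- which(lab == cc, arr.ind = TRUE)
    if (nrow(cells) < min_bins) next
    bx <- range(cells[, 1]); by <- range(cells[, 2])
    if (diff(bx) + 1 > patch || diff(by) + 1 > patch) next
    out <- rbind(out, data.frame(
      n_bins = nrow(cells), x_lo = bx[1], x_hi = bx[2], y_lo = by[1],
      y_hi = by[2], peak_rate_hz = max(map$rate_hz[lab == cc])))
  }
  out
}

#' Per-trial stem subarea firing rates
#'
#' For each correct trial, the firing rate (spikes / time) in each of the
#' stem's subareas during the trial's stem traversal.  Incorrect trials
#' are excluded.
#'
#' @param train a [spike_train()].
#' @param traj trajectory data.frame.
#' @param trials trial table `(trial_id, type, correct, start_s, end_s)`.
#' @param geom a [stem_geometry()].
#' @return data.frame `(trial_id, type, subarea, rate_hz)`.
#' @export
stem_trial_rates <- function(train, traj, trials, geom = stem_geometry()) {
  sub <- stem_subarea(traj, geom)
  dt <- c(diff(traj$time_s), median(diff(traj$time_s)))
  idx <- findInterval(train$times_s, traj$time_s)
  valid <- idx >= 1 & idx <= nrow(traj)
  sp_fr <- idx[valid]; sp_t <- train$times_s[valid]
  rows <- list()
  for (k in seq_len(nrow(trials))) {
    if (!trials$correct[k]) next
    in_tr <- traj$time_s >= trials$start_s[k] & traj$time_s < trials$end_s[k]
    fr_tr <- sp_fr[sp_t >= trials$start_s[k] & sp_t < trials$end_s[k]]
    for (sa in seq_len(geom$n_subareas)) {
      t_sa <- sum(dt[in_tr & !is.na(sub) & sub == sa])
      n_sa <- sum(!is.na(sub[fr_tr]) & sub[fr_tr] == sa)
      if (t_sa > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = trials$trial_id[k], type = trials$type[k],
          subarea = sa, rate_hz = n_sa / t_sa)
    }
  }
  do.call(rbind, rows)
}

#' Classify a stem cell as splitter / location-related / neither
#'
#' Two-way ANOVA of per-trial subarea firing rate with subarea (3 levels)
#' and trial type (L/R) as factors.  Splitter: significant main effect of
#' trial type or trial type x subarea interaction.  Location-related:
#' significant subarea main effect only.  Otherwise neither.
#'
#' @param stem_rates data.frame from [stem_trial_rates()].
#' @param alpha significance level (default 0.05).
#' @param min_trials minimum correct trials per type (default 5).
#' @return list `(label, anova)` with the three ANOVA p-values.
#' @export
classify_stem_cells <- function(stem_rates, alpha = 0.05, min_trials = 5) {
  if (length(unique(stem_rates$type)) < 2)
    stop("classify_stem_cells: a trial type is absent")
  n_per <- table(unique(stem_rates[, c("trial_id", "type")])$type)
  if (any(n_per < min_trials))
    stop("classify_stem_cells: fewer than min_trials correct trials per type")
  df <- data.frame(rate = stem_rates$rate_hz,
                   subarea = factor(stem_rates$subarea),
                   type = factor(stem_rates$type))
  fit <- aov(rate ~ subarea * type, data = df)
  s <- summary(fit)[[1]]
  p <- setNames(s$`Pr(>F)`[1:3], c("subarea", "type", "interaction"))
  label <- if (p["type"] < alpha || p["interaction"] < alpha) "splitter"
  else if (p["subarea"] < alpha) "location_related"
  else "neither"
  list(label = label, anova = p)
}

#' Speed score and speed-cell flag
#'
#' The score is the absolute Pearson correlation between the
#' instantaneous firing rate (per-frame spike counts smoothed over
#' `rate_smooth_s`) and locomotion speed, over frames in the
#' `speed_range`.  A cell is speed-tuned when the score exceeds the 99th
#' percentile of `n_shuffle` circular spike-train shifts (uniform
#' 10-30 s) and the correlation p-value is below `p_max`.  A tuning curve
#' over 1 cm/s bins is returned descriptively.
#'
#' @param train a [spike_train()].
#' @param traj trajectory data.frame.
#' @param speed_range analysed speeds (cm/s), default `c(5, 35)`.
#' @param rate_smooth_s rate smoothing (s), default 0.25.
#' @param n_shuffle shuffles, default 100.
#' @param shift_range_s circular shift range (s), default `c(10, 30)`.
#' @param p_max correlation p threshold, default 0.01.
#' @return list `(score, p, threshold_99, speed_cell, tuning)`.
#' @export
speed_score <- function(train, traj, speed_range = c(5, 35),
                        rate_smooth_s = 0.25, n_shuffle = 100,
                        shift_range_s = c(10, 30), p_max = 0.01) {
  speed <- trajectory_speed(traj)
  if (sd(speed) < 1e-8) stop("speed_score: constant-speed trajectory")
  dt <- median(diff(traj$time_s))
  t0 <- traj$time_s[1]
  L <- traj$time_s[nrow(traj)] - t0 + dt
  sel <- speed >= speed_range[1] & speed <= speed_range[2]
  if (!any(sel)) stop("speed_score: no samples in the speed range")
  frame_rate <- function(times) {
    idx <- floor((times - t0) / dt) + 1L
    counts <- tabulate(idx[idx >= 1 & idx <= nrow(traj)], nbins = nrow(traj))
    gaussian_smooth(counts / dt, rate_smooth_s / dt)
  }
  r_inst <- frame_rate(train$times_s)
  ct <- suppressWarnings(cor.test(r_inst[sel], speed[sel]))
  score <- abs(ct$estimate)
  null_scores <- vapply(seq_len(n_shuffle), function(s) {
    sh <- runif(1, shift_range_s[1], shift_range_s[2]) *
      sample(c(1, -1), 1)
    shifted <- ((train$times_s - t0 + sh) %% L) + t0
    abs(suppressWarnings(cor(frame_rate(shifted)[sel], speed[sel])))
  }, numeric(1))
  thr <- quantile(null_scores, 0.99, names = FALSE)
  # descriptive tuning curve over 1 cm/s bins
  sb <- floor(speed)
  keep <- sb >= speed_range[1] & sb < speed_range[2]
  occ <- tapply(rep(dt, sum(keep)), sb[keep], sum)
  fr <- findInterval(train$times_s, traj$time_s)
  fr <- fr[fr >= 1 & fr <= nrow(traj)]
  spk <- tapply(keep[fr], sb[fr], sum)
  tuning <- data.frame(speed_bin = as.numeric(names(occ)),
                       rate_hz = as.numeric(spk[names(occ)]) /
                         as.numeric(occ))
  list(score = as.numeric(score), p = ct$p.value, threshold_99 = thr,
       speed_cell = score > thr && ct$p.value < p_max, tuning = tuning)
}

#' Remove speed-tuned cells from stem-cell labels
#'
#' @param labels named character vector (unit -> label).
#' @param speed_flags named logical vector (unit -> speed cell).
#' @return filtered labels; logs every removal, warns when none remain.
#' @export
exclude_speed_cells <- function(labels, speed_flags) {
  drop <- names(labels)[names(labels) %in%
                          names(speed_flags)[speed_flags %in% TRUE]]
  for (u in drop) swr_log("exclude_speed_cells: dropping speed cell ", u)
  out <- labels[!names(labels) %in% drop]
  if (!length(out)) warning("exclude_speed_cells: all cells were speed cells")
  out
}
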