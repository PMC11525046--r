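# Figure-eight task session generator: maze trajectory with alternating
# left/right trials, place / trial-type (splitter) / speed tuning, and a
# cross-region co-firing assembly active during running.

#' Stem geometry of the figure-eight maze
#'
#' The stem runs vertically through the maze centre; its usable 30 cm are
#' split into 3 subareas of 10 cm x 6 cm.
#'
#' @param maze_cm maze footprint `c(x, y)` in cm.
#' @param stem_y `c(low, high)` of the usable stem (cm).
#' @param stem_w stem width (cm).
#' @param n_subareas number of stem subareas.
#' @return list with stem bounds and subarea edges.
#' @export
stem_geometry <- function(maze_cm = c(78, 52), stem_y = c(11, 41),
                          stem_w = 6, n_subareas = 3) {
  len <- diff(stem_y)
  if (len %% n_subareas != 0)
    stop("stem_geometry: stem length must divide evenly into subareas")
  list(maze_cm = maze_cm, stem_x = maze_cm[1] / 2, stem_y = stem_y,
       stem_w = stem_w, n_subareas = n_subareas,
       subarea_edges = seq(stem_y[1], stem_y[2], length.out = n_subareas + 1))
}

#' Default task-session generator configuration
#'
#' Unit roles (`splitter`, `location`, `speed`, `untuned`, `place`) control
#' the tuning each unit expresses; effect sizes are multiplicative rate
#' gains.
#'
#' @param ... overrides merged by name.
#' @return a named list.
#' @export
task_config <- function(...) {
  cfg <- list(
    n_trials = 40,
    p_error = 0.1,
    video_hz = 25,
    run_speed = c(mean = 18, sd = 3),     # cm/s along the path
    trial_speed_jitter = 5,               # per-trial mean-speed offset (cm/s)
    pause_s = c(1, 6),                    # inter-trial pause at base
    geometry = stem_geometry(),
    # RSC stem units
    n_splitter = 2, splitter_subarea = 3, splitter_gain = 5,
    n_location = 2, location_profile = c(1, 3, 6),
    n_speed = 1, speed_k = 0.2,
    n_untuned = 3,
    rsc_base = c(3, 6),
    # CA1 place cells
    n_place = 6, place_width_cm = 8, place_gain = 8, ca1_base = c(0.5, 2),
    # assembly co-firing during run (shared log-normal gain per 100 ms bin)
    assembly = list(n_pairs = 0, sigma = 0))
  modifyList(cfg, list(...))
}

# Polyline waypoints for one trial; L/R arm mirrored around the stem.
trial_waypoints <- function(geom, type) {
  mx <- geom$maze_cm[1]; my <- geom$maze_cm[2]
  x0 <- geom$stem_x
  base_y <- geom$stem_y[1] - 5
  top_y <- geom$stem_y[2] + 5
  side_x <- if (type == "L") 8 else mx - 8
  rbind(c(x0, base_y),          # delay area
        c(x0, top_y),           # up the stem
        c(side_x, top_y),       # along the top arm
        c(side_x, base_y),      # down the side (reward at the end)
        c(x0, base_y))          # return
}

# Walk a polyline at per-frame speeds; returns x/y per frame.
walk_polyline <- function(wp, speeds, hz) {
  seg <- diff(wp)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- sum(seg_len)
  d <- cumsum(speeds / hz)
  d <- d[d <= total]
  i <- pmin(findInterval(d, cum), length(seg_len))
  frac <- (d - cum[i]) / seg_len[i]
  cbind(x = wp[i, 1] + frac * seg[i, 1],
        y = wp[i, 2] + frac * seg[i, 2])
}

#' Simulate a figure-eight task session with ground truth
#'
#' @param cfg a [task_config()].
#' @param seed integer seed.
#' @return list with `session` (trajectory, trials, `run` epochs, spike
#'   trains) and `truth` (per-unit roles and tuning, assembly spec).
#' @export
simulate_task_session <- function(cfg = task_config(), seed = 1) {
  set.seed(child_seed(seed, "task"))
  if (cfg$n_trials <= 0) stop("simulate_task_session: zero trials")
  geom <- cfg$geometry
  hz <- cfg$video_hz

  # ---- trajectory ------------------------------------------------------
  xs <- ys <- ts <- numeric(0)
  trial_rows <- list()
  run_st <- run_en <- numeric(0)
  t_now <- 0
  want <- rep(c("L", "R"), length.out = cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    correct <- runif(1) >= cfg$p_error
    type <- if (correct) want[k] else setdiff(c("L", "R"), want[k])
    wp <- trial_waypoints(geom, type)
    total_len <- sum(sqrt(rowSums(diff(wp)^2)))
    mean_k <- cfg$run_speed["mean"] + runif(1, -1, 1) * cfg$trial_speed_jitter
    n_fr <- ceiling(total_len / (max(mean_k, 6) / hz)) + 80
    sp <- pmax(4, mean_k +
                 as.numeric(stats::filter(rnorm(n_fr, 0, cfg$run_speed["sd"]),
                                          0.8, "recursive")) * sqrt(1 - 0.8^2))
    pos <- walk_polyline(wp, sp, hz)
    nf <- nrow(pos)
    tt <- t_now + (seq_len(nf)) / hz
    # stem entry/exit (first/last frame inside the usable stem going up)
    in_stem <- abs(pos[, 1] - geom$stem_x) <= geom$stem_w / 2 &
      pos[, 2] >= geom$stem_y[1] & pos[, 2] < geom$stem_y[2]
    up <- c(diff(pos[, 2]) > 0, FALSE)
    stem_idx <- which(in_stem & up)
    entry_s <- if (length(stem_idx)) tt[stem_idx[1]] else tt[1]
    exit_s <- if (length(stem_idx)) tt[stem_idx[length(stem_idx)]] else tt[1]
    # run epoch: trial start to arrival at the reward (end of side arm)
    arrive <- which(pos[, 2] <= geom$stem_y[1] - 4 &
                      abs(pos[, 1] - geom$stem_x) > 10)
    t_rew <- if (length(arrive)) tt[arrive[1]] else tt[nf]
    run_st <- c(run_st, tt[1]); run_en <- c(run_en, t_rew)
    xs <- c(xs, pos[, 1]); ys <- c(ys, pos[, 2]); ts <- c(ts, tt)
    trial_rows[[k]] <- data.frame(trial_id = k, type = type,
                                  correct = correct, entry_s = entry_s,
                                  exit_s = exit_s,
                                  start_s = tt[1], end_s = tt[nf])
    t_now <- tt[nf]
    # pause at base between trials
    n_p <- round(runif_range(1, cfg$pause_s) * hz)
    jit <- matrix(rnorm(2 * n_p, 0, 0.12), ncol = 2)
    xs <- c(xs, geom$stem_x + cumsum(jit[, 1]) * 0)
    ys <- c(ys, geom$stem_y[1] - 5 + cumsum(jit[, 2]) * 0)
    ts <- c(ts, t_now + seq_len(n_p) / hz)
    t_now <- t_now + n_p / hz
  }
  traj <- data.frame(time_s = ts, x_cm = xs, y_cm = ys)
  trials <- do.call(rbind, trial_rows)
  run_iv <- interval_set(run_st, run_en, "run")
  speed <- trajectory_speed(traj)

  # ---- units -----------------------------------------------------------
  units <- list()
  add_unit <- function(region, role, base, tuning) {
    id <- sprintf("%s-%02d", tolower(region), length(units) + 1L)
    units[[id]] <<- c(list(id = id, region = region, role = role,
                           base = base), tuning)
  }
  for (i in seq_len(cfg$n_splitter))
    add_unit("RSC", "splitter", runif_range(1, cfg$rsc_base),
             list(subarea = cfg$splitter_subarea,
                  lr_gain = c(L = cfg$splitter_gain, R = 1)))
  for (i in seq_len(cfg$n_location))
    add_unit("RSC", "location", runif_range(1, cfg$rsc_base),
             list(profile = cfg$location_profile))
  for (i in seq_len(cfg$n_speed))
    add_unit("RSC", "speed", 0, list(speed_k = cfg$speed_k))
  for (i in seq_len(cfg$n_untuned))
    add_unit("RSC", "untuned", runif_range(1, cfg$rsc_base), list())
  for (i in seq_len(cfg$n_place)) {
    ctr <- traj[sample.int(nrow(traj), 1), c("x_cm", "y_cm")]
    add_unit("CA1", "place", runif_range(1, cfg$ca1_base),
             list(center = as.numeric(ctr), width = cfg$place_width_cm,
                  gain = cfg$place_gain))
  }

  # assembly gain shared per 100 ms bin during run epochs
  asm <- cfg$assembly
  bin_id <- floor(ts / 0.1)
  asm_gain <- rep(1, length(ts))
  if (asm$n_pairs > 0 && asm$sigma > 0) {
    ub <- unique(bin_id)
    z <- setNames(rnorm(length(ub), 0, asm$sigma), ub)
    g <- exp(z[as.character(bin_id)] - asm$sigma^2 / 2)
    g[!in_intervals(ts, run_iv)] <- 1
    asm_gain <- as.numeric(g)
  }
  asm_ids <- character(0)
  if (asm$n_pairs > 0) {
    ids <- names(units)
    rsc_ids <- ids[vapply(units, function(u) u$region == "RSC", TRUE)]
    ca1_ids <- ids[vapply(units, function(u) u$region == "CA1", TRUE)]
    asm_ids <- c(head(ca1_ids, asm$n_pairs), head(rsc_ids, asm$n_pairs))
  }

  trial_type_at <- rep(NA_character_, length(ts))
  for (k in seq_len(nrow(trials))) {
    sel <- ts >= trials$start_s[k] & ts < trials$end_s[k]
    trial_type_at[sel] <- trials$type[k]
  }
  subarea_at <- stem_subarea(traj, geom)

  trains <- lapply(units, function(u) {
    r <- rep(u$base, length(ts))
    if (!is.null(u$center)) {
      d2 <- (traj$x_cm - u$center[1])^2 + (traj$y_cm - u$center[2])^2
      r <- r * (1 + (u$gain - 1) * exp(-0.5 * d2 / u$width^2))
    }
    if (!is.null(u$lr_gain)) {
      sel <- !is.na(subarea_at) & subarea_at == u$subarea &
        !is.na(trial_type_at)
      r[sel] <- r[sel] * u$lr_gain[trial_type_at[sel]]
    }
    if (!is.null(u$profile)) {
      sel <- !is.na(subarea_at)
      r[sel] <- r[sel] * u$profile[subarea_at[sel]]
    }
    if (!is.null(u$speed_k)) r <- u$speed_k * speed
    if (u$id %in% asm_ids) r <- r * asm_gain
    counts <- rpois(length(ts), pmax(r, 0) / hz)
    sp <- rep(ts, counts) - runif(sum(counts)) / hz
    spike_train(u$id, u$region, sort(sp))
  })

  ses <- session(trains = unname(trains),
                 events = list(run = run_iv),
                 trajectory = traj, trials = trials, phase = "task")
  list(session = ses,
       truth = list(units = units, assembly_ids = asm_ids, config = cfg))
}

#' Instantaneous locomotion speed from a trajectory
#'
#' Distance between contiguous frames divided by the frame interval.
#'
#' @param traj data.frame `(time_s, x_cm, y_cm)`.
#' @return numeric speed (cm/s) per frame (first frame repeats the second).
#' @export
trajectory_speed <- function(traj) {
  d <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  dt <- diff(traj$time_s)
  v <- d / pmax(dt, 1e-6)
  c(v[1], v)
}

# Subarea index (1..n) per trajectory frame; NA outside the stem.
stem_subarea <- function(traj, geom) {
  inside <- abs(traj$x_cm - geom$stem_x) <= geom$stem_w / 2 &
    traj$y_cm >= geom$stem_y[1] & traj$y_cm < geom$stem_y[2]
  sub <- findInterval(traj$y_cm, geom$subarea_edges,
                      rightmost.closed = FALSE)
  sub[!inside] <- NA_integer_
  sub
}
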