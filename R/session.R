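# The session container: one recording phase's signals, spike trains,
# events, hypnogram, trajectory and trial table on a single clock.

#' Construct a spike train
#'
#' @param unit_id unit identifier (coerced to character).
#' @param region `"CA1"` or `"RSC"`.
#' @param times_s sorted spike times (s).
#' @param cell_class optional `"excitatory"`, `"inhibitory"` or
#'   `"unclassified"`.
#' @return a `spike_train` object.
#' @export
spike_train <- function(unit_id, region = c("CA1", "RSC"), times_s,
                        cell_class = "unclassified") {
  region <- match.arg(region)
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s))
    stop(sprintf("spike_train: times not nondecreasing for unit %s", unit_id))
  structure(list(unit_id = as.character(unit_id), region = region,
                 times_s = times_s, cell_class = cell_class),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s (%s, %s) %d spikes>\n", x$unit_id, x$region,
              x$cell_class, length(x$times_s)))
  invisible(x)
}

#' Construct a session
#'
#' @param signals named list of [sampled_signal()] (names = labels).
#' @param trains list of [spike_train()].
#' @param events named list of [interval_set()] keyed by kind.
#' @param hypnogram optional hypnogram `interval_set` (with a `state`
#'   column) tiling the session.
#' @param trajectory optional data.frame `(time_s, x_cm, y_cm)`.
#' @param trials optional data.frame
#'   `(trial_id, type, correct, entry_s, exit_s)`.
#' @param phase `"pre_sleep"`, `"task"` or `"post_sleep"`.
#' @return a `session` object.
#' @export
session <- function(signals = list(), trains = list(), events = list(),
                    hypnogram = NULL, trajectory = NULL, trials = NULL,
                    phase = c("pre_sleep", "task", "post_sleep")) {
  phase <- match.arg(phase)
  structure(list(signals = signals, trains = trains, events = events,
                 hypnogram = hypnogram, trajectory = trajectory,
                 trials = trials, phase = phase),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session phase=%s: %d signals, %d trains, %d event kinds%s%s>\n",
              x$phase, length(x$signals), length(x$trains), length(x$events),
              if (!is.null(x$hypnogram)) ", hypnogram" else "",
              if (!is.null(x$trajectory)) ", trajectory" else ""))
  invisible(x)
}

#' Span of a session on its clock
#' @param s a [session()].
#' @return `c(t0, t1)` covering all signals and spikes.
#' @export
session_span <- function(s) {
  t0 <- Inf; t1 <- -Inf
  for (sig in s$signals) {
    t0 <- min(t0, sig$t0_s); t1 <- max(t1, signal_end_s(sig))
  }
  for (tr in s$trains) {
    if (length(tr$times_s)) {
      t0 <- min(t0, tr$times_s[1]); t1 <- max(t1, tr$times_s[length(tr$times_s)])
    }
  }
  if (!is.finite(t0)) c(0, 0) else c(t0, t1)
}

#' Spike trains of a session, optionally filtered by region
#' @param s a [session()].
#' @param region `"CA1"`, `"RSC"`, or `NULL` for all trains.
#' @return list of [spike_train()].
#' @export
session_trains <- function(s, region = NULL) {
  tr <- s$trains
  if (!is.null(region)) tr <- Filter(function(x) x$region == region, tr)
  tr
}

# ---------------------------------------------------------------- disk I/O

iv_to_df <- function(ivs) {
  df <- as.data.frame(ivs)
  if (is.null(df$peak_s)) df$peak_s <- NA_real_
  if (is.null(df$peak_score)) df$peak_score <- NA_real_
  cols <- c("start_s", "peak_s", "end_s", "peak_score")
  if (!is.null(df$state)) cols <- c(cols, "state")
  df[, cols, drop = FALSE]
}

df_to_iv <- function(df, kind) {
  pk <- if ("peak_s" %in% names(df) && !all(is.na(df$peak_s))) df$peak_s
  sc <- if ("peak_score" %in% names(df) && !all(is.na(df$peak_score))) df$peak_score
  st <- if ("state" %in% names(df)) df$state
  interval_set(df$start_s, df$end_s, kind, peak_s = pk, peak_score = sc,
               state = st)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a session directory
#'
#' Layout: `<label>.f32`/`<label>.json` per signal, `spikes.tsv`
#' (unit_id, region, time_s, cell_class), `events/<kind>.tsv`
#' (start_s, peak_s, end_s, peak_score), `hypnogram.tsv` (adds a state
#' column), optional `trajectory.tsv` and `trials.tsv`, and `phase.json`.
#'
#' @param s a [session()].
#' @param dir_path output directory (created if needed).
#' @return invisibly, `dir_path`.
#' @export
write_session <- function(s, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (sig in s$signals) write_signal(sig, dir_path)
  sp <- do.call(rbind, lapply(s$trains, function(tr) {
    if (!length(tr$times_s)) return(NULL)
    data.frame(unit_id = tr$unit_id, region = tr$region,
               time_s = sprintf("%.17g", tr$times_s),
               cell_class = tr$cell_class)
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(0), region = character(0),
                     time_s = character(0), cell_class = character(0))
  write_tsv(sp, file.path(dir_path, "spikes.tsv"))
  dir.create(file.path(dir_path, "events"), showWarnings = FALSE)
  for (kind in names(s$events))
    write_tsv(iv_to_df(s$events[[kind]]),
              file.path(dir_path, "events", paste0(kind, ".tsv")))
  if (!is.null(s$hypnogram))
    write_tsv(iv_to_df(s$hypnogram), file.path(dir_path, "hypnogram.tsv"))
  if (!is.null(s$trajectory))
    write_tsv(s$trajectory, file.path(dir_path, "trajectory.tsv"))
  if (!is.null(s$trials))
    write_tsv(s$trials, file.path(dir_path, "trials.tsv"))
  jsonlite::write_json(list(phase = s$phase),
                       file.path(dir_path, "phase.json"), auto_unbox = TRUE)
  invisible(dir_path)
}

#' Read a session directory
#'
#' Inverse of [write_session()]; unknown files are ignored with a logged
#' warning, a `.f32` without its sidecar is a format error, and
#' out-of-order spike times are a validation error naming the unit.
#'
#' @param dir_path session directory.
#' @return a [session()].
#' @export
read_session <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("read_session: no such directory ", dir_path)
  files <- list.files(dir_path)
  known <- c("spikes.tsv", "hypnogram.tsv", "trajectory.tsv", "trials.tsv",
             "phase.json", "events", "ground_truth.json")
  signals <- list()
  for (f in files[grepl("\\.f32$", files)]) {
    sig <- read_signal(file.path(dir_path, f))
    signals[[sig$label]] <- sig
  }
  sidecars <- sub("\\.f32$", ".json", files[grepl("\\.f32$", files)])
  unknown <- setdiff(files, c(known, files[grepl("\\.f32$", files)], sidecars))
  for (f in unknown) swr_log("read_session: ignoring unknown file ", f)

  trains <- list()
  spath <- file.path(dir_path, "spikes.tsv")
  if (file.exists(spath)) {
    sp <- read.delim(spath, colClasses = c(unit_id = "character"))
    if (nrow(sp)) {
      for (uid in unique(sp$unit_id)) {
        rows <- sp[sp$unit_id == uid, ]
        if (is.unsorted(rows$time_s))
          stop(sprintf("read_session: spike times out of order for unit %s", uid))
        trains[[length(trains) + 1L]] <-
          spike_train(uid, rows$region[1], rows$time_s,
                      cell_class = rows$cell_class[1] %||% "unclassified")
      }
    }
  }

  events <- list()
  edir <- file.path(dir_path, "events")
  if (dir.exists(edir)) {
    for (f in list.files(edir, pattern = "\\.tsv$")) {
      kind <- sub("\\.tsv$", "", f)
      df <- read.delim(file.path(edir, f))
      events[[kind]] <- if (nrow(df)) df_to_iv(df, kind) else empty_intervals(kind)
    }
  }

  hyp <- NULL
  hpath <- file.path(dir_path, "hypnogram.tsv")
  if (file.exists(hpath)) hyp <- df_to_iv(read.delim(hpath), "hypnogram")
  traj <- NULL
  tpath <- file.path(dir_path, "trajectory.tsv")
  if (file.exists(tpath)) traj <- read.delim(tpath)
  trials <- NULL
  trpath <- file.path(dir_path, "trials.tsv")
  if (file.exists(trpath)) trials <- read.delim(trpath)
  phase <- "pre_sleep"
  ppath <- file.path(dir_path, "phase.json")
  if (file.exists(ppath))
    phase <- jsonlite::read_json(ppath)$phase %||% "pre_sleep"

  session(signals = signals, trains = trains, events = events,
          hypnogram = hyp, trajectory = traj, trials = trials, phase = phase)
}
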