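# Pipeline orchestration over pre-sleep / task / post-sleep phases, and
# the pre- versus post-sleep contrast tables.

#' Default pipeline configuration
#'
#' Controls the synthetic study set the pipeline runs on and the
#' per-stage settings.  Every numeric constant of the analysis stages is
#' reachable here.
#'
#' @param ... overrides merged by name.
#' @return a named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_sessions = 1,
    sleep_pre = sleep_config(duration_s = 420, n_ripples = 45, n_delta = 55,
                             n_spindles = 20),
    sleep_post = sleep_config(duration_s = 420, n_ripples = 55, n_delta = 65,
                              n_spindles = 25),
    task = task_config(n_trials = 30),
    stages = c("score_sleep", "detect", "psth", "react", "glm", "spatial"),
    psth = list(n_shuffle = 200, min_anchors = 30),
    react = list(bin = 0.1, n_shuffle = 100),
    glm = list(n_targets = 2, n_shuffle = 30, n_control = 20,
               min_anchors = 30, min_active = 10),
    spatial = list(n_shuffle = 100))
  modifyList(cfg, list(...))
}

run_sleep_stages <- function(ses, truth, cfg, out_dir, tag) {
  out <- list()
  fs_dir <- function(f) file.path(out_dir, paste0(tag, "_", f))
  # --- sleep scoring
  emgz <- compute_emg_z(ses$signals$EMG)
  ratio <- theta_delta_ratio(ses$signals$`CA1-lfp`)
  hyp <- score_states(ratio, emgz)
  write_tsv(iv_to_df(hyp), fs_dir("hypnogram.tsv"))
  nrem <- state_intervals(hyp, "nrem")
  # --- detection
  rip <- detect_ripples(ses$signals$`CA1-lfp`)
  sw <- detect_sharp_waves(ses$signals$`CA1-lfp`)
  swr <- pair_swr(rip, sw, nrem)
  del <- detect_delta(ses$signals$`RSC-lfp`)
  spi <- detect_spindles(ses$signals$`RSC-lfp`)
  off <- detect_off_periods(session_trains(ses, "RSC"),
                            span = session_span(ses))
  for (nm in c("ripple", "sharp_wave", "swr", "delta", "spindle")) {
    obj <- switch(nm, ripple = rip, sharp_wave = sw, swr = swr,
                  delta = del, spindle = spi)
    write_tsv(iv_to_df(obj), fs_dir(paste0(nm, ".tsv")))
  }
  if (!is.null(off)) write_tsv(iv_to_df(off), fs_dir("off_period.tsv"))
  out$hypnogram <- hyp; out$swr <- swr; out$delta <- del
  out$spindle <- spi; out$off <- off; out$nrem <- nrem
  out$pairs_delta <- pair_sequences(swr, del)
  out$pairs_spindle <- pair_sequences(swr, spi)
  # --- peri-SWR statistics
  if ("psth" %in% cfg$stages) {
    epoch <- session_span(ses)
    mods <- lapply(ses$trains, function(tr) {
      win <- if (tr$region == "CA1") c(0, 0.1) else c(-0.2, 0.2)
      test_modulation(tr, swr$peak_s, epoch, window = win,
                      n_shuffle = cfg$psth$n_shuffle,
                      min_anchors = cfg$psth$min_anchors)
    })
    tab <- do.call(rbind, lapply(mods, function(m) {
      if (is.null(m)) return(NULL)
      data.frame(unit_id = m$unit_id, score = m$score, p = m$p,
                 modulated = m$modulated)
    }))
    if (!is.null(tab)) write_tsv(tab, fs_dir("modulation.tsv"))
    out$modulation <- tab
  }
  out
}

#' Run the full pipeline on a synthetic study set
#'
#' Simulates `n_sessions` pre-sleep / task / post-sleep triplets, runs
#' sleep scoring, event detection, peri-SWR statistics, reactivation,
#' GLM prediction and spatial classification in dependency order, writes
#' every stage's tables under `out_dir`, and stamps the bundle with the
#' configuration hash and seed.  Identical `(config, seed)` give a
#' byte-identical bundle.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return invisibly, a list of per-session results plus the contrast
#'   table.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = "swrpipe_out") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- list()
  for (si in seq_len(config$n_sessions)) {
    sseed <- child_seed(seed, paste0("session", si))
    pre <- simulate_sleep_session(config$sleep_pre, sseed)
    post <- simulate_sleep_session(config$sleep_post, child_seed(sseed, "post"))
    task <- simulate_task_session(config$task, sseed)
    res <- list()
    set.seed(child_seed(sseed, "stages-pre"))
    res$pre <- run_sleep_stages(pre$session, pre$truth, config, out_dir,
                                sprintf("s%02d_pre", si))
    set.seed(child_seed(sseed, "stages-post"))
    res$post <- run_sleep_stages(post$session, post$truth, config, out_dir,
                                 sprintf("s%02d_post", si))
    # --- reactivation: template from task run epochs, matched in post NREM
    set.seed(child_seed(sseed, "react"))
    react <- tryCatch(
      session_reactivation(task$session, post$session, res$post$swr,
                           res$post$nrem, bin = config$react$bin,
                           n_shuffle = config$react$n_shuffle),
      error = function(e) NULL)
    if (!is.null(react)) {
      write_tsv(data.frame(t = react$trace$t, R_z = react$trace$R_z),
                file.path(out_dir, sprintf("s%02d_reactivation.tsv", si)))
      write_tsv(data.frame(lag_s = react$peri$lags_s, R = react$peri$mean_R,
                           null_lo = react$peri$null_lo,
                           null_hi = react$peri$null_hi),
                file.path(out_dir, sprintf("s%02d_peri_swr_react.tsv", si)))
    }
    res$react <- react
    # --- GLM: RSC (-100,0) -> CA1 (0,100) for the first eligible targets
    if ("glm" %in% config$stages) {
      set.seed(child_seed(sseed, "glm"))
      epoch <- session_span(post$session)
      rsc <- session_trains(post$session, "RSC")
      ca1 <- session_trains(post$session, "CA1")
      glms <- list()
      for (tr in ca1) {
        if (length(glms) >= config$glm$n_targets) break
        r <- predict_cell_counts(rsc, tr, res$post$swr, epoch,
                                 n_shuffle = config$glm$n_shuffle,
                                 n_control = config$glm$n_control,
                                 min_anchors = config$glm$min_anchors,
                                 min_active = config$glm$min_active)
        if (!is.null(r)) glms[[length(glms) + 1L]] <- r
      }
      if (length(glms)) {
        tab <- directional_summary(glms)
        write_tsv(tab, file.path(out_dir, sprintf("s%02d_glm.tsv", si)))
        res$glm <- tab
      }
    }
    # --- spatial stage on the task session
    if ("spatial" %in% config$stages) {
      set.seed(child_seed(sseed, "spatial"))
      geom <- config$task$geometry
      labs <- list()
      for (tr in session_trains(task$session, "RSC")) {
        sr <- stem_trial_rates(tr, task$session$trajectory,
                               task$session$trials, geom)
        lab <- tryCatch(classify_stem_cells(sr)$label,
                        error = function(e) NA_character_)
        sc <- tryCatch(speed_score(tr, task$session$trajectory,
                                   n_shuffle = config$spatial$n_shuffle),
                       error = function(e) list(speed_cell = NA))
        labs[[tr$unit_id]] <- data.frame(unit_id = tr$unit_id, label = lab,
                                         speed_cell = isTRUE(sc$speed_cell))
      }
      tab <- do.call(rbind, labs)
      write_tsv(tab, file.path(out_dir, sprintf("s%02d_stem_labels.tsv", si)))
      res$spatial <- tab
    }
    sessions[[si]] <- res
  }
  contrasts <- pre_post_contrasts(sessions)
  write_tsv(contrasts, file.path(out_dir, "pre_post_contrasts.tsv"))
  manifest <- list(seed = seed,
                   config_hash = config_hash(config),
                   n_sessions = config$n_sessions,
                   stages = config$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sessions = sessions, contrasts = contrasts,
                 manifest = manifest))
}

#' Hash of a configuration object
#'
#' Deterministic md5 of the deparsed configuration, used to stamp output
#' bundles.
#'
#' @param config any R object.
#' @return md5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

# Template from the task session's run epochs, matched in post-sleep NREM.
session_reactivation <- function(task_ses, sleep_ses, swr, nrem, bin = 0.1,
                                 n_shuffle = 100) {
  run <- task_ses$events$run
  ca1_t <- session_trains(task_ses, "CA1")
  rsc_t <- session_trains(task_ses, "RSC")
  stack_counts <- function(trains, ivs) {
    do.call(rbind, Filter(Negate(is.null),
                          lapply(seq_len(nrow(ivs)), function(i) {
                            span <- c(ivs$start_s[i], ivs$end_s[i])
                            if (diff(span) < bin) return(NULL)
                            bin_counts(trains, bin, span)
                          })))
  }
  tpl <- build_template(stack_counts(ca1_t, run), stack_counts(rsc_t, run))
  # sleep counts on a continuous NREM-restricted grid
  ca1_s <- session_trains(sleep_ses, "CA1")
  rsc_s <- session_trains(sleep_ses, "RSC")
  span <- session_span(sleep_ses)
  ca1_counts <- bin_counts(ca1_s, bin, span)
  rsc_counts <- bin_counts(rsc_s, bin, span)
  t_bins <- span[1] + (seq_len(nrow(ca1_counts)) - 0.5) * bin
  keep <- in_intervals(t_bins, nrem)
  trace <- reactivation_strength(tpl, ca1_counts[keep, , drop = FALSE],
                                 rsc_counts[keep, , drop = FALSE],
                                 t_bins[keep])
  # peri-SWR statistics need a regular grid: use the unrestricted trace
  trace_full <- reactivation_strength(tpl, ca1_counts, rsc_counts, t_bins)
  peri <- peri_swr_reactivation(trace_full, swr$start_s,
                                n_shuffle = n_shuffle)
  list(template = tpl, trace = trace_full, trace_nrem = trace, peri = peri)
}

#' Pre- versus post-sleep contrast table
#'
#' Incidence ratios (SWR, SWR-delta, SWR-spindle pairs per NREM minute,
#' post over pre) and OFF-period duration comparisons per session, with a
#' paired signed-rank test across sessions when several are available.
#'
#' @param sessions list of per-session results from [run_pipeline()].
#' @return data.frame `(metric, session, pre, post, ratio, p_paired)`.
#' @export
pre_post_contrasts <- function(sessions) {
  rows <- list()
  per_metric <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    rate <- function(stage, what) {
      mins <- interval_duration(stage$nrem) / 60
      n <- switch(what, swr = nrow(stage$swr),
                  swr_delta = nrow(stage$pairs_delta),
                  swr_spindle = nrow(stage$pairs_spindle))
      if (mins > 0) n / mins else NA_real_
    }
    for (m in c("swr", "swr_delta", "swr_spindle")) {
      pre <- rate(s$pre, m); post <- rate(s$post, m)
      per_metric[[m]] <- rbind(per_metric[[m]], c(pre, post))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, session = si, pre = pre, post = post,
        ratio = if (isTRUE(pre > 0)) post / pre else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$p_paired <- NA_real_
  for (m in names(per_metric)) {
    v <- per_metric[[m]]
    p <- if (nrow(v) >= 6)
      suppressWarnings(wilcox.test(v[, 1], v[, 2], paired = TRUE)$p.value)
    else NA_real_
    out$p_paired[out$metric == m] <- p
  }
  if (nrow(out) && all(is.na(out$p_paired)))
    swr_log("pre_post_contrasts: too few sessions, tests underpowered")
  out
}
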