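# Typed time intervals and the algebra the pipeline leans on.
#
# All intervals are half-open [start_s, end_s) on a single session clock in
# seconds.  An `interval_set` is a data.frame (start_s, end_s, optional
# peak_s, peak_score, state) sorted by start and non-overlapping within one
# kind, plus a `kind` attribute.

INTERVAL_KINDS <- c("ripple", "sharp_wave", "swr", "delta", "spindle",
                    "off_period", "nrem", "rem", "wake", "other",
                    "immobility", "hypnogram", "run", "epoch")

#' Construct a typed interval set
#'
#' @param start_s,end_s numeric vectors of interval bounds (seconds,
#'   half-open `[start_s, end_s)`).
#' @param kind one of `"ripple"`, `"sharp_wave"`, `"swr"`, `"delta"`,
#'   `"spindle"`, `"off_period"`, `"nrem"`, `"rem"`, `"wake"`, `"other"`,
#'   `"immobility"`, `"hypnogram"`, `"run"`, `"epoch"`.
#' @param peak_s optional event peak times, each inside its interval.
#' @param peak_score optional peak score in detector SD units.
#' @param state optional per-interval state label (hypnograms).
#' @return an `interval_set`: a sorted data.frame with a `kind` attribute.
#' @export
interval_set <- function(start_s, end_s, kind = "other", peak_s = NULL,
                         peak_score = NULL, state = NULL) {
  kind <- match.arg(kind, INTERVAL_KINDS)
  n <- length(start_s)
  stopifnot(length(end_s) == n)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  if (!is.null(peak_s)) df$peak_s <- as.numeric(peak_s)
  if (!is.null(peak_score)) df$peak_score <- as.numeric(peak_score)
  if (!is.null(state)) df$state <- as.character(state)
  if (n > 0) {
    if (any(df$end_s <= df$start_s))
      stop("interval_set: start_s must be < end_s for every interval")
    if (!is.null(peak_s) &&
        any(peak_s < df$start_s | peak_s > df$end_s, na.rm = TRUE))
      stop("interval_set: peak_s outside [start_s, end_s]")
    df <- df[order(df$start_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, kind = kind, class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set kind=%s n=%d span=%.3f s>\n", iv_kind(x),
              nrow(x), sum(x$end_s - x$start_s)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

iv_kind <- function(ivs) attr(ivs, "kind") %||% "other"

empty_intervals <- function(kind = "other") interval_set(numeric(0), numeric(0), kind)

#' Merge overlapping or nearby intervals
#'
#' Intervals whose gap is strictly smaller than `gap_s` are fused; the
#' merged peak is the constituent peak with the largest score (first peak
#' when scores are absent).
#'
#' @param ivs an [interval_set()].
#' @param gap_s merge events separated by less than this many seconds;
#'   `0` fuses only overlapping/abutting intervals.
#' @return an `interval_set` of the same kind.
#' @export
merge_intervals <- function(ivs, gap_s = 0) {
  if (nrow(ivs) <= 1) return(ivs)
  st <- ivs$start_s; en <- ivs$end_s
  pk <- ivs$peak_s; sc <- ivs$peak_score
  grp <- cumsum(c(1, as.integer(st[-1] - cummax(en)[-length(en)] >= gap_s)))
  out_st <- tapply(st, grp, min)
  out_en <- tapply(en, grp, max)
  out_pk <- out_sc <- NULL
  if (!is.null(pk)) {
    pick <- function(i) {
      if (is.null(sc)) i[1] else i[which.max(sc[i])]
    }
    idx <- vapply(split(seq_along(st), grp), pick, integer(1))
    out_pk <- pk[idx]
    if (!is.null(sc)) out_sc <- sc[idx]
  }
  interval_set(out_st, out_en, iv_kind(ivs), peak_s = out_pk, peak_score = out_sc)
}

#' Intersect an interval set with another
#'
#' @param a,b interval sets (each internally non-overlapping).
#' @return interval set of kind `kind(a)` covering the pointwise
#'   intersection of the two unions.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals(iv_kind(a)))
  st <- en <- numeric(0)
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end_s[j] <= a$start_s[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start_s[k] < a$end_s[i]) {
      st <- c(st, max(a$start_s[i], b$start_s[k]))
      en <- c(en, min(a$end_s[i], b$end_s[k]))
      k <- k + 1L
    }
  }
  keep <- en > st
  interval_set(st[keep], en[keep], iv_kind(a))
}

#' Total duration of an interval set (seconds)
#' @param ivs an [interval_set()].
#' @export
interval_duration <- function(ivs) sum(ivs$end_s - ivs$start_s)

#' Membership of time points in an interval set
#'
#' Half-open convention: `t` is inside iff `start_s <= t < end_s` for some
#' interval.
#'
#' @param t numeric vector of times (s).
#' @param ivs an [interval_set()].
#' @return logical vector.
#' @export
in_intervals <- function(t, ivs) {
  if (nrow(ivs) == 0 || length(t) == 0) return(rep(FALSE, length(t)))
  edges <- as.vector(rbind(ivs$start_s, ivs$end_s))
  findInterval(t, edges) %% 2L == 1L
}

#' Restrict a spike train to an interval set
#'
#' Keeps spikes in the union of the half-open intervals; needed e.g. to
#' limit SWR detection and PSTHs to NREM sleep.
#'
#' @param train a [spike_train()].
#' @param ivs an [interval_set()].
#' @return a `spike_train` with the retained spikes.
#' @export
restrict <- function(train, ivs) {
  stopifnot(inherits(train, "spike_train"))
  keep <- in_intervals(train$times_s, ivs)
  spike_train(train$unit_id, train$region, train$times_s[keep],
              cell_class = train$cell_class)
}

#' Bin spike counts over a span
#'
#' Bins tile `[span[1], span[2])` left to right with half-open edges; the
#' final partial bin (if any) is dropped so all bins have equal width.
#'
#' @param trains list of [spike_train()] objects.
#' @param bin_s bin width (s), > 0.
#' @param span numeric length-2, `c(start_s, end_s)`.
#' @return integer matrix, bins x units, with unit ids as column names.
#' @export
bin_counts <- function(trains, bin_s, span) {
  stopifnot(bin_s > 0, length(span) == 2)
  if (diff(span) < bin_s) stop("bin_counts: span shorter than one bin")
  n_bins <- floor((span[2] - span[1]) / bin_s + 1e-9)
  edges <- span[1] + bin_s * (0:n_bins)
  m <- vapply(trains, function(tr) {
    t <- tr$times_s
    t <- t[t >= edges[1] & t < edges[n_bins + 1]]
    tabulate(findInterval(t, edges), nbins = n_bins)
  }, integer(n_bins))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_bins)
  colnames(m) <- vapply(trains, function(tr) as.character(tr$unit_id), "")
  m
}

# Complement of an interval set within [t0, t1).
complement_intervals <- function(ivs, t0, t1, kind = "other") {
  if (nrow(ivs) == 0) return(interval_set(t0, t1, kind))
  st <- c(t0, ivs$end_s)
  en <- c(ivs$start_s, t1)
  keep <- en > st
  interval_set(st[keep], en[keep], kind)
}
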