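#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov cor cor.test fft mad median nextn p.adjust pnorm
#'   poisson binomial quantile rbinom rexp rgamma rnorm rpois runif sd var
#'   wilcox.test glm.fit fivenum setNames complete.cases
#' @importFrom utils head tail read.delim write.table modifyList
NULL

swr_log <- function(..., verbose = getOption("swrpipe.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[swrpipe] ", ...)
  invisible(NULL)
}

#' z-score a numeric vector
#'
#' Centres and scales by the sample standard deviation.  A zero-variance
#' input returns all zeros rather than NaN so that degenerate signals
#' (e.g. a flat EMG) propagate harmlessly.
#'
#' @param x numeric vector.
#' @param mu,sigma optional externally supplied centre/scale (e.g. baseline
#'   statistics); defaults to `mean(x)` and `sd(x)`.
#' @return numeric vector of the same length.
#' @export
zscore <- function(x, mu = mean(x, na.rm = TRUE), sigma = sd(x, na.rm = TRUE)) {
  if (!is.finite(sigma) || sigma == 0) return(rep(0, length(x)))
  (x - mu) / sigma
}

# Normalised Gaussian kernel truncated at 4 SD; sd in samples.
gaussian_kernel <- function(sd_samples) {
  if (sd_samples <= 0) return(1)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- exp(-0.5 * ((-half:half) / sd_samples)^2)
  k / sum(k)
}

#' Gaussian smoothing of a regularly sampled series
#'
#' FFT-based convolution with a Gaussian kernel, edge-corrected by dividing
#' by the smoothed all-ones signal so the output is an unbiased local mean
#' near the boundaries.
#'
#' @param x numeric vector.
#' @param sd_samples kernel standard deviation in samples.
#' @return smoothed vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sd_samples) {
  n <- length(x)
  if (n == 0 || sd_samples <= 0) return(x)
  k <- gaussian_kernel(sd_samples)
  half <- (length(k) - 1L) / 2L
  nf <- nextn(n + length(k), 2)
  xf <- c(x, rep(0, nf - n))
  kf <- c(k, rep(0, nf - length(k)))
  full <- Re(fft(fft(xf) * fft(kf), inverse = TRUE)) / nf
  num <- full[(half + 1L):(half + n)]
  of <- c(rep(1, n), rep(0, nf - n))
  fullo <- Re(fft(fft(of) * fft(kf), inverse = TRUE)) / nf
  den <- fullo[(half + 1L):(half + n)]
  num / den
}

# 1/f^alpha ("pink") Gaussian noise, unit variance, via spectral shaping.
pink_noise <- function(n, alpha = 1, rate_hz = 1250, f_floor = 0.5) {
  nf <- nextn(n, 2)
  white <- rnorm(nf)
  wf <- fft(white)
  freqs <- c(0, seq_len(nf - 1)) * rate_hz / nf
  freqs <- pmin(freqs, rate_hz - freqs)   # two-sided
  shape <- 1 / pmax(freqs, f_floor)^(alpha / 2)
  shape[1] <- 0                            # no DC
  x <- Re(fft(wf * shape, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  as.numeric(zscore(x))
}

# 1/f background with a variance-stabilised high-frequency band: the
# content above `cut_hz` is divided by its own running RMS envelope so the
# ripple-band envelope is light-tailed (ripple-band power excursions then
# reflect inserted events, not chance background bursts).
stabilized_pink_noise <- function(n, alpha = 1, rate_hz = 1250,
                                  cut_hz = 100, stab_sd_s = 0.008) {
  x <- pink_noise(n, alpha, rate_hz)
  lp <- signal::butter(3, cut_hz / (rate_hz / 2), type = "low")
  x_lo <- signal::filtfilt(lp, x)
  x_hi <- x - x_lo
  env <- sqrt(pmax(gaussian_smooth(x_hi^2, stab_sd_s * rate_hz), 1e-12))
  x_hi <- x_hi / env * mean(env)
  as.numeric(x_lo + x_hi)
}

# Flatten the amplitude envelope of one band of a signal (leaves the rest
# untouched); depth 1 fully stabilises the band's running RMS.
stabilize_band <- function(x, band, rate_hz, env_sd_s, depth = 1) {
  bp <- if (band[1] <= 0) signal::butter(3, band[2] / (rate_hz / 2), "low")
  else signal::butter(3, band / (rate_hz / 2), "pass")
  xb <- signal::filtfilt(bp, x)
  env <- sqrt(pmax(gaussian_smooth(xb^2, env_sd_s * rate_hz), 1e-12))
  flat <- xb / env * mean(env)
  as.numeric(x + depth * (flat - xb))
}

# Factory: FFT-cached Gaussian smoother for repeated same-length calls
# (the shuffle tests smooth hundreds of equal-length vectors).
make_smoother <- function(n, sd_samples) {
  if (n == 0 || sd_samples <= 0) return(identity)
  k <- gaussian_kernel(sd_samples)
  half <- (length(k) - 1L) / 2L
  nf <- nextn(n + length(k), 2)
  kf <- fft(c(k, rep(0, nf - length(k))))
  fullo <- Re(fft(fft(c(rep(1, n), rep(0, nf - n))) * kf, inverse = TRUE)) / nf
  den <- fullo[(half + 1L):(half + n)]
  idx <- (half + 1L):(half + n)
  function(x) {
    full <- Re(fft(fft(c(x, rep(0, nf - n))) * kf, inverse = TRUE)) / nf
    full[idx] / den
  }
}

# Derive a reproducible child seed (< 2^31) from a base seed and a tag.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
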