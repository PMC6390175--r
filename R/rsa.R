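#' Spearman rank correlation between two cell vectors
#'
#' Pearson correlation of mid-ranks (average ranks for ties; ties are heavy
#' in categorical model matrices, so this matters).
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rsa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: Spearman correlation undefined")
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("rank-constant input: Spearman correlation undefined")
  stats::cor(ra, rb)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all vectors, removes the least-squares projection of the
#' ranks of `a` and `b` onto the control ranks (plus intercept), and
#' correlates the residuals. Used to ask whether a model matrix relates to
#' brain-pattern similarity beyond what category structure explains.
#'
#' @param a,b numeric vectors of equal length.
#' @param controls a numeric vector, or a list / matrix of control vectors;
#'   NULL or empty reduces exactly to [spearman_rsa()].
#' @return Partial rho.
#' @export
partial_spearman <- function(a, b, controls = NULL) {
  if (is.null(controls) || (is.list(controls) && !length(controls)))
    return(spearman_rsa(a, b))
  if (is.list(controls)) controls <- do.call(cbind, controls)
  controls <- as.matrix(controls)
  stopifnot(length(a) == length(b), nrow(controls) == length(a))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input: Spearman correlation undefined")
  rc <- apply(controls, 2L, rank)
  if (any(apply(rc, 2L, stats::sd) == 0))
    stop("rank-constant control vector")
  X <- cbind(1, rc)
  res_a <- stats::lsfit(X, rank(a), intercept = FALSE)$residuals
  res_b <- stats::lsfit(X, rank(b), intercept = FALSE)$residuals
  if (stats::sd(res_a) < 1e-12 * stats::sd(rank(a)) ||
      stats::sd(res_b) < 1e-12 * stats::sd(rank(b)))
    stop("control(s) collinear with an input: zero residual rank variance")
  stats::cor(res_a, res_b)
}

#' Fisher r-to-z transform
#'
#' z = atanh(rho), the variance-stabilizing transform applied to
#' correlations before group-level t-tests.
#'
#' @param rho correlation(s), |rho| < 1.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1))
    stop("|rho| >= 1: Fisher z is infinite/undefined")
  atanh(rho)
}

# ---- Butterworth low-pass (no design routine in the available stack) ----

#' Low-pass Butterworth filter coefficients
#'
#' Digital IIR coefficients via the analog Butterworth prototype and the
#' bilinear transform with frequency prewarping.
#'
#' @param order filter order (default 5).
#' @param cutoff cutoff frequency, Hz.
#' @param sampling_rate sampling rate, Hz; cutoff must be below Nyquist.
#' @return list(b, a) numerator/denominator coefficient vectors.
#' @export
butter_lowpass <- function(order = 5L, cutoff, sampling_rate) {
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0 || order < 1L) stop("invalid filter specification")
  warped <- 2 * sampling_rate * tan(pi * cutoff / sampling_rate)
  k <- seq_len(order)
  poles_s <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * sampling_rate
  poles_z <- (fs2 + poles_s) / (fs2 - poles_s)
  gain <- Re(prod((fs2 - poles_s))) # analog gain warped^order / bilinear denom
  a <- Re(poly_from_roots(poles_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order))) * (warped^order / gain)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

normalize_ba <- function(b, a) {
  b <- b / a[1L]; a <- a / a[1L]
  n <- max(length(a), length(b))
  list(b = c(b, rep(0, n - length(b))), a = c(a, rep(0, n - length(a))),
       n = n)
}

# steady-state DFII-transposed state for a unit-step input, so that
# filtering a constant produces that constant from sample one
iir_step_state <- function(b, a) {
  co <- normalize_ba(b, a)
  n <- co$n
  y_ss <- sum(co$b) / sum(co$a)
  z <- numeric(n - 1L)
  z[n - 1L] <- co$b[n] - co$a[n] * y_ss
  if (n > 2L)
    for (i in (n - 2L):1L)
      z[i] <- z[i + 1L] + co$b[i + 1L] - co$a[i + 1L] * y_ss
  z
}

iir_filter <- function(b, a, x, zi = NULL) {
  # direct-form II transposed
  co <- normalize_ba(b, a)
  b <- co$b; a <- co$a; n <- co$n
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (n > 2L)
      z[seq_len(n - 2L)] <- b[2:(n - 1L)] * x[i] + z[2:(n - 1L)] -
        a[2:(n - 1L)] * y[i]
    z[n - 1L] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

filtfilt_1d <- function(b, a, x) {
  # zero-phase: forward-backward with odd-reflection padding at both ends
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad,
         " samples)")
  pre <- 2 * x[1L] - x[npad + 1L - seq_len(npad) + 1L]
  post <- 2 * x[length(x)] - x[length(x) - seq_len(npad)]
  ext <- c(pre, x, post)
  zi <- iir_step_state(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[npad + seq_along(x)]
}

#' Zero-phase low-pass smoothing of an RSA timecourse
#'
#' Order-5 Butterworth low-pass applied forward and backward (zero phase
#' lag), the mild matched-filter smoothing applied to per-participant RSA
#' correlation timecourses before group statistics.
#'
#' @param z numeric vector (map over time) or matrix (maps in rows).
#' @param sampling_rate Hz of the map's time axis.
#' @param cutoff low-pass cutoff, Hz (default 10).
#' @param order Butterworth order (default 5).
#' @export
smooth_timecourse <- function(z, sampling_rate, cutoff = 10, order = 5L) {
  co <- butter_lowpass(order, cutoff, sampling_rate)
  if (is.matrix(z))
    t(apply(z, 1L, function(r) filtfilt_1d(co$b, co$a, r)))
  else filtfilt_1d(co$b, co$a, z)
}

gaussian_kernel <- function(fwhm, step) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / step))
  x <- seq(-half, half) * step
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_renorm <- function(x, k) {
  # kernel-weight renormalisation at the edges keeps a constant map constant
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2L)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2L)
  (num / den)[half + seq_len(n)]
}

#' Separable Gaussian smoothing of a time-frequency RSA map
#'
#' Convolves with a normalised Gaussian per axis (sigma = FWHM / 2.355),
#' renormalising kernel mass at the map edges so constant maps pass through
#' unchanged.
#'
#' @param z numeric matrix, frequencies x time.
#' @param freq_step,time_step grid spacing (Hz, ms).
#' @param fwhm_freq,fwhm_time smoothing FWHMs (default 4 Hz, 20 ms).
#' @export
smooth_tf_map <- function(z, freq_step, time_step,
                          fwhm_freq = 4, fwhm_time = 20) {
  stopifnot(is.matrix(z))
  if (fwhm_freq <= 0 || fwhm_time <= 0) stop("FWHM must be positive")
  kf <- gaussian_kernel(fwhm_freq, freq_step)
  kt <- gaussian_kernel(fwhm_time, time_step)
  z1 <- apply(z, 2L, convolve_renorm, k = kf)
  if (!is.matrix(z1)) z1 <- matrix(z1, nrow = nrow(z))
  t(apply(z1, 1L, convolve_renorm, k = kt))
}

#' Group-level one-sample t map
#'
#' Per map coordinate, t = mean / (sd / sqrt(n)) over participants. Zero-
#' variance coordinates with nonzero mean are flagged +/-Inf; all-zero
#' coordinates give t = 0.
#'
#' @param zmaps participants x coordinates matrix of Fisher-z maps.
#' @return Numeric vector of t values, one per coordinate.
#' @export
group_t_map <- function(zmaps) {
  stopifnot(is.matrix(zmaps), nrow(zmaps) >= 2L)
  n <- nrow(zmaps)
  m <- colMeans(zmaps)
  s <- sqrt(colSums(sweep(zmaps, 2L, m)^2) / (n - 1L))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t
}
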