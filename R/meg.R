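#' Epoch-set container
#'
#' Trials x channels x time multichannel responses with sampling metadata,
#' per-trial stimulus labels and per-channel type (axial magnetometer or
#' planar gradiometer; artifact thresholds differ by type).
#'
#' @param data numeric array trials x channels x time.
#' @param sampling_rate Hz.
#' @param times numeric vector (ms relative to stimulus onset), length =
#'   dim(data)[3].
#' @param stimulus_id per-trial stimulus labels, length = dim(data)[1].
#' @param channel_names,channel_types per-channel metadata; types are
#'   "axial" or "planar".
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, sampling_rate, times, stimulus_id,
                      channel_names = NULL, channel_types = NULL) {
  stopifnot(length(dim(data)) == 3L)
  d <- dim(data)
  if (length(times) != d[3L])
    stop("times length must equal the time dimension")
  dt <- diff(times)
  if (max(abs(dt - dt[1L])) > 1e-6 * abs(dt[1L]))
    stop("time axis must be uniform")
  if (length(stimulus_id) != d[1L])
    stop("stimulus_id length must equal the trial dimension")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2L]))
  if (is.null(channel_types)) channel_types <- rep("axial", d[2L])
  channel_types <- match.arg(channel_types, c("axial", "planar"),
                             several.ok = TRUE)
  stopifnot(length(channel_names) == d[2L], length(channel_types) == d[2L])
  structure(list(data = data, sampling_rate = sampling_rate, times = times,
                 stimulus_id = as.character(stimulus_id),
                 channel_names = channel_names,
                 channel_types = channel_types),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
    d[1L], d[2L], d[3L], x$sampling_rate, min(x$times), max(x$times)))
  invisible(x)
}

#' Amplitude-threshold artifact rejection
#'
#' Removes whole trials on which any sample of any channel exceeds the
#' channel-type-specific absolute amplitude limit (axial magnetometers and
#' planar gradiometers are in different units, hence separate limits).
#'
#' @param epochs an `epoch_set`.
#' @param axial_limit,planar_limit positive absolute-amplitude thresholds in
#'   the respective channel units (fT and fT/mm for real MEG data).
#' @return The cleaned `epoch_set`; attribute `rejection_log` is a data.frame
#'   (trial, channel, sample, value) with one row per offending trial
#'   recording the first threshold crossing.
#' @export
reject_artifacts <- function(epochs, axial_limit = 2000, planar_limit = 50) {
  stopifnot(axial_limit > 0, planar_limit > 0)
  limits <- ifelse(epochs$channel_types == "axial", axial_limit, planar_limit)
  d <- dim(epochs$data)
  log <- list()
  bad <- logical(d[1L])
  for (tr in seq_len(d[1L])) {
    sl <- abs(epochs$data[tr, , , drop = FALSE])
    dim(sl) <- d[2:3]
    over <- which(sl > limits, arr.ind = TRUE)  # limits recycle down columns
    if (nrow(over)) {
      first <- over[order(over[, 2L], over[, 1L])[1L], ]
      bad[tr] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        trial = tr, channel = epochs$channel_names[first[1L]],
        sample = unname(first[2L]),
        value = epochs$data[tr, first[1L], first[2L]])
    }
  }
  if (all(bad)) stop("all trials rejected by artifact thresholds")
  out <- epoch_set(epochs$data[!bad, , , drop = FALSE], epochs$sampling_rate,
                   epochs$times, epochs$stimulus_id[!bad],
                   epochs$channel_names, epochs$channel_types)
  attr(out, "rejection_log") <-
    if (length(log)) do.call(rbind, log)
    else data.frame(trial = integer(), channel = character(),
                    sample = integer(), value = numeric())
  out
}

#' Baseline-corrected evoked (trial-averaged) responses
#'
#' Per stimulus: subtract each trial's per-channel mean over the pre-stimulus
#' baseline window, then average across trials. Phase-locked activity
#' survives this average; induced (phase-random) oscillations cancel.
#'
#' @param epochs an `epoch_set`.
#' @param baseline length-2 window (ms) for the baseline mean; default the
#'   full pre-stimulus interval (-500, 0\].
#' @return Object of class `evoked_set`: list with `data` (stimuli x channels
#'   x time array), `stimulus_ids`, `times`, `sampling_rate`.
#' @export
evoked_average <- function(epochs, baseline = c(-500, 0)) {
  bidx <- which(epochs$times > baseline[1L] & epochs$times <= baseline[2L])
  if (!length(bidx)) stop("baseline window contains no samples")
  stims <- sort(unique(epochs$stimulus_id))
  d <- dim(epochs$data)
  out <- array(0, c(length(stims), d[2L], d[3L]),
               dimnames = list(stims, epochs$channel_names, NULL))
  for (si in seq_along(stims)) {
    tr <- which(epochs$stimulus_id == stims[si])
    if (!length(tr))
      stop("no surviving trials for stimulus ", stims[si])
    x <- epochs$data[tr, , , drop = FALSE]
    bmean <- apply(x[, , bidx, drop = FALSE], c(1L, 2L), mean)
    x <- sweep(x, c(1L, 2L), bmean)
    out[si, , ] <- apply(x, c(2L, 3L), mean)
  }
  structure(list(data = out, stimulus_ids = stims, times = epochs$times,
                 sampling_rate = epochs$sampling_rate,
                 channel_names = epochs$channel_names),
            class = "evoked_set")
}

morlet_wavelet_fft <- function(freq, n_cycles, sampling_rate, n_fft) {
  # complex Morlet, L2-normalised; returned as its FFT for fast convolution
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(5 * sigma_t * sampling_rate)
  t <- seq(-half, half) / sampling_rate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w <- w / sqrt(sum(Mod(w)^2))
  if (length(w) > n_fft)
    stop("epoch too short for the ", freq, " Hz wavelet")
  wp <- complex(n_fft)
  wp[seq_along(w)] <- w
  # edge flag uses 2.5 sigma: beyond that the Gaussian envelope is < 4%
  # in amplitude, so edge transients are negligible in power
  list(fft = stats::fft(wp), half = half,
       edge_half = ceiling(2.5 * sigma_t * sampling_rate))
}

#' Morlet wavelet time-frequency power
#'
#' Convolves every trial with complex Morlet wavelets (factor = number of
#' cycles, default 7), takes squared magnitude, and averages power over
#' trials within each stimulus — so non-phase-locked (induced) oscillations
#' are retained.
#'
#' @param epochs an `epoch_set`.
#' @param freqs frequency grid in Hz (default 4-50 Hz in 2 Hz steps).
#' @param n_cycles wavelet factor: cycles per wavelet (>= 1).
#' @return Object of class `tf_power`: `data` is stimuli x channels x
#'   frequencies x time raw power; `edges` is a frequencies x time logical
#'   matrix flagging samples within 2.5 wavelet sigma of an epoch edge
#'   (filter-transient contamination; the envelope is < 4% beyond that).
#' @export
morlet_power <- function(epochs, freqs = seq(4, 50, by = 2), n_cycles = 7) {
  stopifnot(n_cycles >= 1)
  if (any(freqs >= epochs$sampling_rate / 2))
    stop("frequencies at or above Nyquist (",
         epochs$sampling_rate / 2, " Hz)")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  d <- dim(epochs$data)
  n_time <- d[3L]
  stims <- sort(unique(epochs$stimulus_id))
  wl <- lapply(freqs, morlet_wavelet_fft, n_cycles = n_cycles,
               sampling_rate = epochs$sampling_rate,
               n_fft = stats::nextn(n_time + 1L +
                                      2L * ceiling(5 * n_cycles /
                                                     (2 * pi * min(freqs)) *
                                                     epochs$sampling_rate),
                                    2L))
  n_fft <- length(wl[[1L]]$fft)
  pow <- array(0, c(length(stims), d[2L], length(freqs), n_time),
               dimnames = list(stims, epochs$channel_names, freqs, NULL))
  counts <- integer(length(stims))
  for (tr in seq_len(d[1L])) {
    si <- match(epochs$stimulus_id[tr], stims)
    x <- matrix(0, n_fft, d[2L])
    x[seq_len(n_time), ] <- t(matrix(epochs$data[tr, , ], d[2L], n_time))
    X <- stats::mvfft(x)
    for (fi in seq_along(freqs)) {
      conv <- stats::mvfft(X * wl[[fi]]$fft, inverse = TRUE) / n_fft
      # wavelet peak sits at index half+1: take the aligned segment
      seg <- conv[wl[[fi]]$half + seq_len(n_time), , drop = FALSE]
      pow[si, , fi, ] <- pow[si, , fi, ] + t(Mod(seg)^2)
    }
    counts[si] <- counts[si] + 1L
  }
  if (any(counts == 0L))
    stop("no trials for stimulus ", paste(stims[counts == 0L], collapse = ", "))
  for (si in seq_along(stims))
    pow[si, , , ] <- pow[si, , , ] / counts[si]
  edges <- matrix(FALSE, length(freqs), n_time,
                  dimnames = list(freqs, NULL))
  for (fi in seq_along(freqs)) {
    h <- wl[[fi]]$edge_half
    if (h >= 1 && h < n_time)
      edges[fi, c(seq_len(h), n_time - seq_len(h) + 1L)] <- TRUE
    else if (h >= n_time) edges[fi, ] <- TRUE
  }
  structure(list(data = pow, stimulus_ids = stims,
                 channel_names = epochs$channel_names, freqs = freqs,
                 times = epochs$times, sampling_rate = epochs$sampling_rate,
                 edges = edges, baseline_corrected = FALSE),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tf_power> %d stimuli x %d channels x %d freqs x %d samples%s\n",
    d[1L], d[2L], d[3L], d[4L],
    if (x$baseline_corrected) " (log-ratio baseline-corrected)" else ""))
  invisible(x)
}

#' Log-ratio baseline correction of time-frequency power
#'
#' For each stimulus, channel and frequency, expresses power as the natural
#' log of its ratio to the mean power over the pre-stimulus baseline window.
#' The log base only rescales the maps globally and cancels in
#' correlation-based RSA.
#'
#' @param power a `tf_power` with raw (nonnegative) power.
#' @param baseline length-2 window in ms (default c(-350, -100)).
#' @return The baseline-corrected `tf_power`.
#' @export
log_ratio_baseline <- function(power, baseline = c(-350, -100)) {
  if (isTRUE(power$baseline_corrected))
    stop("power is already baseline-corrected")
  bidx <- which(power$times >= baseline[1L] & power$times <= baseline[2L])
  if (!length(bidx)) stop("baseline window contains no samples")
  bmean <- apply(power$data[, , , bidx, drop = FALSE], 1:3, mean)
  if (any(bmean <= 0))
    stop("nonpositive baseline mean power; cannot take log ratio")
  power$data <- log(sweep(power$data, 1:3, bmean, `/`))
  power$baseline_corrected <- TRUE
  power
}

#' Select channels with a reliable post-stimulus power response
#'
#' Given baseline-corrected power observations for each channel across
#' participants (or trials), retains a channel if a right-sided one-sample
#' t-test exceeds threshold at any post-stimulus time/frequency bin
#' (uncorrected, deliberately liberal: this is a sensor pre-selection step,
#' not an inference).
#'
#' @param power_obs numeric array observations x channels x frequencies x
#'   time of baseline-corrected power.
#' @param times time axis (ms) matching the last dimension.
#' @param alpha uncorrected threshold (default 1e-4).
#' @return Integer vector of retained channel indices; attribute `p_min`
#'   gives each channel's smallest post-stimulus p-value.
#' @export
select_responsive_channels <- function(power_obs, times, alpha = 1e-4) {
  stopifnot(length(dim(power_obs)) == 4L, dim(power_obs)[1L] >= 2L)
  post <- which(times > 0)
  if (!length(post)) stop("no post-stimulus samples")
  x <- power_obs[, , , post, drop = FALSE]
  n <- dim(x)[1L]
  m <- apply(x, 2:4, mean)
  s <- apply(x, 2:4, stats::sd)
  tval <- m / (s / sqrt(n))
  tval[s == 0] <- 0
  p <- stats::pt(tval, df = n - 1L, lower.tail = FALSE)
  p_min <- apply(p, 1L, min)
  keep <- which(p_min < alpha)
  attr(keep, "p_min") <- p_min
  keep
}
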