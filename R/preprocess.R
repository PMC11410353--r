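scalp_channels <- function(epochs) {
  lay <- epochs$layout
  lay$channels$name[lay$channels$type == "scalp"]
}

# subtract an (n_trial x n_channel) matrix from every sample of the array
sweep_epochs <- function(data, m) {
  # array is [trial, channel, sample]; c(m) recycles over samples
  data - c(m)
}

#' Re-reference epochs to the mean of reference channels
#'
#' Subtracts the samplewise mean of `ref_channels` (typically the two
#' mastoids) from every channel, reference channels included, so the
#' operation is idempotent: after the first pass the reference mean is
#' identically zero. Reference channels are retained and flagged in the
#' provenance log.
#'
#' @param epochs An `eeg_epochs` object.
#' @param ref_channels Channel names to average as the reference.
#' @return Re-referenced `eeg_epochs`.
#' @export
rereference <- function(epochs, ref_channels = c("M1", "M2")) {
  ch <- dimnames(epochs$data)[[2]]
  i <- chan_idx(ch, ref_channels)
  refm <- 0
  for (j in i) refm <- refm + epochs$data[, j, ]
  refm <- refm / length(i)  # n_trial x n_sample
  d <- dim(epochs$data)
  epochs$data <- epochs$data -
    aperm(array(refm, dim = d[c(1, 3, 2)]), c(1, 3, 2))
  add_step(epochs, "rereference", ref_channels = ref_channels)
}

#' Remove each epoch's whole-epoch mean per channel
#'
#' @param epochs An `eeg_epochs` object.
#' @return Demeaned `eeg_epochs`: every channel x epoch has exactly zero
#'   mean over the full epoch.
#' @export
demean_epochs <- function(epochs) {
  m <- rowMeans(epochs$data, dims = 2)
  epochs$data <- sweep_epochs(epochs$data, m)
  add_step(epochs, "demean")
}

#' Baseline-correct epochs
#'
#' Subtracts, per channel and epoch, the mean over the pre-stimulus
#' baseline window (half-open, default \[-100, 0) ms).
#'
#' @param epochs An `eeg_epochs` object.
#' @param window_ms Baseline window in ms.
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  sel <- epochs$times >= window_ms[1] & epochs$times < window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  m <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- sweep_epochs(epochs$data, m)
  add_step(epochs, "baseline", window_ms = window_ms)
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' A trial is removed iff any scalp channel's absolute amplitude exceeds
#' `threshold_uv` at any sample inside `window_ms` (closed interval,
#' default 150 ms before to 600 ms after onset). Reference channels are
#' not consulted. Every decision is logged with the peak amplitude and,
#' for removed trials, the offending channel and sample time.
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold_uv Rejection threshold in microvolts (default 75).
#' @param window_ms Scan window in ms.
#' @return A list: `epochs` (kept trials) and `log` (data frame of class
#'   `rejection_log`: `trial`, `kept`, `peak_uv`, `channel`, `time_ms`).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75,
                             window_ms = c(-150, 600)) {
  stopifnot(threshold_uv > 0)
  if (window_ms[1] < min(epochs$times) ||
      window_ms[2] > max(epochs$times) + 1)
    stop("rejection window extends outside the epoch")
  sel <- in_window(epochs$times, window_ms)
  ch <- dimnames(epochs$data)[[2]]
  sc <- chan_idx(ch, scalp_channels(epochs))
  x <- abs(epochs$data[, sc, sel, drop = FALSE])
  n_tr <- dim(x)[1]
  dim(x) <- c(n_tr, dim(x)[2] * dim(x)[3])
  peak_at <- max.col(x, ties.method = "first")
  peak <- x[cbind(seq_len(n_tr), peak_at)]
  kept <- peak <= threshold_uv
  chan_i <- (peak_at - 1) %% length(sc) + 1
  samp_i <- (peak_at - 1) %/% length(sc) + 1
  log <- data.frame(trial = seq_len(n_tr), kept = kept, peak_uv = peak,
                    channel = ifelse(kept, NA, ch[sc][chan_i]),
                    time_ms = ifelse(kept, NA, epochs$times[sel][samp_i]))
  class(log) <- c("rejection_log", "data.frame")
  out <- subset_epochs(epochs, kept)
  out <- add_step(out, "reject", threshold_uv = threshold_uv,
                  window_ms = window_ms, n_removed = sum(!kept))
  list(epochs = out, log = log)
}

#' Design a zero-phase windowed-sinc low-pass FIR filter
#'
#' Hamming-windowed sinc with transition bandwidth
#' `min(max(cutoff / 4, 2), cutoff)` Hz (so 7.5 Hz at a 30 Hz cutoff),
#' filter order `3.3 / (tb / fs)` rounded up to even, and -6 dB point at
#' `cutoff + tb / 2`. The impulse response is symmetric, hence exactly
#' zero-phase when applied centred.
#'
#' @param cutoff_hz Passband edge in Hz.
#' @param fs Sampling rate in Hz.
#' @param transition_bw Optional transition bandwidth override in Hz.
#' @return A list of class `fir_filter`: `h` (coefficients), `order`,
#'   `fc` (-6 dB frequency), `transition_bw`, `fs`.
#' @export
#' @examples
#' f <- design_lowpass(30, 1000)
#' filter_gain_db(f, c(0, 30, 60))
design_lowpass <- function(cutoff_hz, fs, transition_bw = NULL) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  tb <- transition_bw %||% min(max(cutoff_hz * 0.25, 2), cutoff_hz)
  m <- ceiling(3.3 / (tb / fs))
  m <- m + m %% 2  # even order, odd length, symmetric
  fc <- cutoff_hz + tb / 2
  k <- -(m / 2):(m / 2)
  x <- 2 * fc * k / fs
  h <- 2 * fc / fs * ifelse(k == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * (k + m / 2) / m)
  h <- h * w
  h <- h / sum(h)  # unit DC gain
  structure(list(h = h, order = m, fc = fc, transition_bw = tb, fs = fs),
            class = "fir_filter")
}

#' Frequency response of an FIR filter in dB
#'
#' @param filt A `fir_filter` from [design_lowpass()].
#' @param freq_hz Frequencies at which to evaluate the gain.
#' @return Gain in dB (0 dB = unity) at each frequency.
#' @export
filter_gain_db <- function(filt, freq_hz) {
  k <- seq_along(filt$h) - 1
  g <- vapply(freq_hz, function(f)
    Mod(sum(filt$h * exp(-2i * pi * f * k / filt$fs))), 0)
  20 * log10(g)
}

#' Zero-phase low-pass filter epoched data
#'
#' Applies the [design_lowpass()] FIR per channel and epoch via centred
#' (zero-phase) convolution. Because epochs are short, each signal is
#' reflect-padded by one filter length before filtering. The designed
#' filter's passband ripple and stopband attenuation are recorded in the
#' provenance log.
#'
#' @param epochs An `eeg_epochs` object.
#' @param cutoff_hz Passband edge in Hz (default 30).
#' @param transition_bw Optional transition bandwidth override in Hz.
#' @return Filtered `eeg_epochs`.
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 30, transition_bw = NULL) {
  fs <- epochs$params$sampling_rate %||%
    (1000 / diff(epochs$times[1:2]))
  filt <- design_lowpass(cutoff_hz, fs, transition_bw)
  d <- dim(epochs$data)
  dn <- dimnames(epochs$data)
  n_sp <- d[3]
  # samples x (trial*channel) matrix
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_sp)
  y <- filtfilt_matrix(x, filt$h)
  epochs$data <- aperm(array(y, dim = c(n_sp, d[1], d[2])), c(2, 3, 1))
  dimnames(epochs$data) <- dn

  resp <- filter_gain_db(filt, seq(0, fs / 2, length.out = 512))
  f_axis <- seq(0, fs / 2, length.out = 512)
  pass <- f_axis <= cutoff_hz - filt$transition_bw / 2
  stopb <- f_axis >= cutoff_hz + filt$transition_bw / 2
  add_step(epochs, "lowpass", cutoff_hz = cutoff_hz,
           order = filt$order, fc_6db = filt$fc,
           passband_ripple_db = max(abs(resp[pass])),
           stopband_attenuation_db = -max(resp[stopb]))
}

# zero-phase convolution of every column with symmetric FIR h,
# reflect-padded; FFT-based (mixed radix, two real signals packed per
# complex transform) and chunked to bound memory
filtfilt_matrix <- function(x, h) {
  n_sp <- nrow(x)
  L <- length(h)
  half <- (L - 1) / 2
  p <- min(L, n_sp - 1)
  xp <- rbind(x[(p + 1):2, , drop = FALSE], x,
              x[(n_sp - 1):(n_sp - p), , drop = FALSE])
  P <- nrow(xp)
  N <- stats::nextn(P + L, c(2, 3, 5))
  H <- stats::fft(c(h, rep(0, N - L)))
  nc <- ncol(xp)
  if (nc %% 2) xp <- cbind(xp, 0)  # pair columns for packing
  odd <- seq(1, ncol(xp), 2)
  out <- matrix(0, n_sp, ncol(xp))
  idx <- (p + half + 1):(p + half + n_sp)
  chunk <- max(1L, floor(4e6 / N))
  for (start in seq(1, length(odd), by = chunk)) {
    cols <- odd[start:min(start + chunk - 1, length(odd))]
    # h is real, so convolving the complex packing a + ib filters both
    # packed signals at once
    Xc <- rbind(xp[, cols, drop = FALSE] +
                  1i * xp[, cols + 1, drop = FALSE],
                matrix(0, N - P, length(cols)))
    y <- stats::mvfft(H * stats::mvfft(Xc), inverse = TRUE) / N
    out[, cols] <- Re(y[idx, , drop = FALSE])
    out[, cols + 1] <- Im(y[idx, , drop = FALSE])
  }
  out[, seq_len(nc), drop = FALSE]
}

#' Zero-phase low-pass filter an averaged waveform
#'
#' Applies the same FIR as [lowpass_filter()] to a channels x samples
#' waveform. Because the filter is linear, time-invariant and identical
#' for every epoch, filtering an average equals averaging filtered
#' epochs; the pipeline driver uses this to filter ERPs instead of every
#' single epoch.
#'
#' @param wave An `erp_waveform` or `difference_wave`.
#' @param cutoff_hz Passband edge in Hz (default 30).
#' @param fs Sampling rate in Hz (default inferred from the time grid).
#' @param transition_bw Optional transition bandwidth override in Hz.
#' @return The filtered waveform (class and attributes preserved).
#' @export
lowpass_waveform <- function(wave, cutoff_hz = 30, fs = NULL,
                             transition_bw = NULL) {
  times <- attr(wave, "times")
  fs <- fs %||% (1000 / diff(times[1:2]))
  filt <- design_lowpass(cutoff_hz, fs, transition_bw)
  out <- t(filtfilt_matrix(t(unclass(wave)), filt$h))
  attributes(out) <- attributes(wave)
  out
}

#' Interpolate bad channels from their neighbours
#'
#' Replaces each bad channel, samplewise, by the inverse-distance-weighted
#' mean of its good spatial neighbours (from the layout neighbour graph).
#' At most three channels may be interpolated per participant.
#'
#' @param epochs An `eeg_epochs` object.
#' @param bad Character vector of bad channel names (length <= 3).
#' @param layout Layout providing neighbours; defaults to the epochs'.
#' @return `eeg_epochs` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(epochs, bad, layout = epochs$layout) {
  if (length(bad) == 0) return(epochs)
  if (length(bad) > 3)
    stop("at most three channels may be interpolated per participant")
  ch <- dimnames(epochs$data)[[2]]
  adj <- layout$adjacency
  pos <- layout$channels
  for (b in bad) {
    if (!b %in% rownames(adj)) stop("not a scalp channel: ", b)
    nb <- colnames(adj)[adj[b, ]]
    nb <- setdiff(nb, bad)
    if (!length(nb)) stop("bad channel has no good neighbour: ", b)
    bi <- chan_idx(pos$name, b)
    di <- sqrt((pos$x[chan_idx(pos$name, nb)] - pos$x[bi])^2 +
                 (pos$y[chan_idx(pos$name, nb)] - pos$y[bi])^2)
    w <- (1 / di) / sum(1 / di)
    acc <- 0
    for (j in seq_along(nb))
      acc <- acc + w[j] * epochs$data[, chan_idx(ch, nb[j]), ]
    epochs$data[, chan_idx(ch, b), ] <- acc
  }
  add_step(epochs, "interpolate", bad = bad)
}

#' Run the standard epoch preprocessing chain
#'
#' Fixed order matching the study pipeline: optional bad-channel
#' interpolation, re-referencing to the mastoid mean, whole-epoch
#' demeaning, a logged no-op where ICA ocular-component removal would sit
#' (synthetic data carry no ocular components), pre-stimulus baseline
#' correction, amplitude-based artifact rejection, and zero-phase low-pass
#' filtering. Reordering requires an explicit `order` override, which is
#' logged.
#'
#' @param epochs An `eeg_epochs` object.
#' @param ref_channels Reference channels, or `NULL` to skip.
#' @param bad_channels Channels to interpolate first (<= 3).
#' @param baseline_ms Baseline window.
#' @param reject_uv,reject_window_ms Rejection threshold and window;
#'   `reject_uv = NULL` skips rejection.
#' @param cutoff_hz Low-pass edge; `NULL` skips filtering.
#' @param order Optional character vector reordering the stages (logged).
#' @return A list: `epochs` (preprocessed) and `rejection_log`.
#' @export
preprocess <- function(epochs, ref_channels = c("M1", "M2"),
                       bad_channels = character(0),
                       baseline_ms = c(-100, 0),
                       reject_uv = 75, reject_window_ms = c(-150, 600),
                       cutoff_hz = 30, order = NULL) {
  stages <- order %||% c("interpolate", "rereference", "demean", "ica",
                         "baseline", "reject", "filter")
  if (!is.null(order))
    warning("non-default preprocessing order: ",
            paste(order, collapse = " -> "))
  log <- NULL
  for (s in stages) {
    epochs <- switch(s,
      interpolate = interpolate_bad_channels(epochs, bad_channels),
      rereference = if (is.null(ref_channels)) epochs else
        rereference(epochs, ref_channels),
      demean = demean_epochs(epochs),
      ica = add_step(epochs, "ica", status = "skipped"),
      baseline = baseline_correct(epochs, baseline_ms),
      reject = if (is.null(reject_uv)) epochs else {
        r <- reject_artifacts(epochs, reject_uv, reject_window_ms)
        log <- r$log
        r$epochs
      },
      filter = if (is.null(cutoff_hz)) epochs else
        lowpass_filter(epochs, cutoff_hz),
      stop("unknown preprocessing stage: ", s)
    )
  }
  list(epochs = epochs, rejection_log = log)
}
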