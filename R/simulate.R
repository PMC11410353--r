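#' Simulation parameters for synthetic epoched EEG
#'
#' The generative model has two variance levels: a participant-level
#' deviant-minus-standard effect drawn once per participant and contrast
#' from Normal(`mu_subj`, `sigma_subj`) (microvolts), and single-trial
#' Gaussian noise with standard deviation `sigma_trial` at every channel
#' and sample, white in time and space. `sigma_trial` has no published
#' reference value and is therefore a required argument; 10 microvolts per
#' sample is a workable example for white noise (see the package vignette
#' for why white-noise amplitudes sit below the RMS of real, temporally
#' correlated EEG). Occasional high-amplitude artifact trials are injected
#' at rate `artifact_rate` as square pulses of `artifact_amplitude`.
#'
#' @param sigma_trial Single-trial noise SD in microvolts (required).
#' @param mu_subj Mean participant-level effect in microvolts
#'   (default -0.84, the reference MMN amplitude at Cz over 200-400 ms).
#' @param sigma_subj Between-participant SD of the effect (default 2.28).
#' @param artifact_rate Probability that a trial receives an artifact.
#' @param artifact_amplitude Artifact pulse amplitude in microvolts.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param epoch_window_ms Epoch limits in ms relative to stimulus onset;
#'   the window is half-open, so the default (-150, 750) yields 900
#'   samples at 1000 Hz with onset at sample 151.
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' sim_params(sigma_trial = 10)
sim_params <- function(sigma_trial, mu_subj = -0.84, sigma_subj = 2.28,
                       artifact_rate = 0, artifact_amplitude = 120,
                       sampling_rate = 1000,
                       epoch_window_ms = c(-150, 750)) {
  if (missing(sigma_trial))
    stop("sigma_trial has no published default and must be supplied")
  stopifnot(sigma_trial >= 0, sigma_subj >= 0,
            artifact_rate >= 0, artifact_rate <= 1,
            sampling_rate > 0, diff(epoch_window_ms) > 0)
  structure(list(sigma_trial = sigma_trial, mu_subj = mu_subj,
                 sigma_subj = sigma_subj, artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 sampling_rate = sampling_rate,
                 epoch_window_ms = epoch_window_ms),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params>: effect %g +/- %g uV (participant),",
                     " trial noise %g uV, artifacts %g%% at %g uV\n"),
              x$mu_subj, x$sigma_subj, x$sigma_trial,
              100 * x$artifact_rate, x$artifact_amplitude))
  invisible(x)
}

epoch_times <- function(params) {
  step <- 1000 / params$sampling_rate
  seq(params$epoch_window_ms[1], params$epoch_window_ms[2] - step,
      by = step)
}

#' Spatiotemporal effect kernel
#'
#' Describes where and when the simulated MMN effect lives: a spatial
#' topography with weight 1 at `peak_channel` and Gaussian falloff with
#' distance on the layout schematic, and a unit-peak temporal window
#' (raised cosine or boxcar) over `window_ms`, zero outside it. The
#' default peaks at Cz over 200-400 ms, the reference measurement window.
#'
#' @param layout An `eeg_layout`.
#' @param peak_channel Scalp channel at which the topography equals 1.
#' @param window_ms Onset/offset of the temporal window in ms.
#' @param shape `"cosine"` (raised cosine, default) or `"boxcar"`.
#' @param spatial_sd Gaussian falloff scale in layout units.
#' @param amplitude_scale Multiplier applied on top of the drawn
#'   participant effect (default 1).
#' @return An object of class `effect_kernel`.
#' @export
#' @examples
#' k <- effect_kernel(make_layout("grid64"))
#' k$topography["Cz"]  # 1
effect_kernel <- function(layout, peak_channel = "Cz",
                          window_ms = c(200, 400),
                          shape = c("cosine", "boxcar"),
                          spatial_sd = 2, amplitude_scale = 1) {
  shape <- match.arg(shape)
  stopifnot(inherits(layout, "eeg_layout"), spatial_sd > 0,
            diff(window_ms) > 0)
  scalp <- layout$channels[layout$channels$type == "scalp", ]
  i <- chan_idx(scalp$name, peak_channel)
  d2 <- (scalp$x - scalp$x[i])^2 + (scalp$y - scalp$y[i])^2
  topo <- exp(-d2 / (2 * spatial_sd^2))
  names(topo) <- scalp$name
  structure(list(peak_channel = peak_channel, topography = topo,
                 window_ms = window_ms, shape = shape,
                 spatial_sd = spatial_sd,
                 amplitude_scale = amplitude_scale),
            class = "effect_kernel")
}

#' Evaluate a kernel's temporal window function
#'
#' @param kernel An `effect_kernel`.
#' @param times_ms Sample times in ms.
#' @return Numeric vector of unit-peak weights, zero outside the window.
#' @export
kernel_time_course <- function(kernel, times_ms) {
  w <- kernel$window_ms
  inside <- times_ms >= w[1] & times_ms <= w[2]
  out <- numeric(length(times_ms))
  if (kernel$shape == "boxcar") {
    out[inside] <- 1
  } else {
    out[inside] <- 0.5 * (1 - cos(2 * pi * (times_ms[inside] - w[1]) /
                                    (w[2] - w[1])))
  }
  out * kernel$amplitude_scale
}

new_epochs <- function(data, info, times, layout, params = NULL,
                       effects = NULL, steps = list()) {
  stopifnot(length(dim(data)) == 3, nrow(info) == dim(data)[1],
            dim(data)[3] == length(times))
  structure(list(data = data, info = info, times = times, layout = layout,
                 params = params, effects = effects, steps = steps),
            class = "eeg_epochs")
}

add_step <- function(epochs, name, ...) {
  epochs$steps <- c(epochs$steps, list(c(list(step = name), list(...))))
  epochs
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs>: %d trials x %d channels x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  if (length(x$steps))
    cat("  steps:", paste(vapply(x$steps, `[[`, "", "step"),
                          collapse = " -> "), "\n")
  invisible(x)
}

#' Subset epochs by trial
#'
#' @param epochs An `eeg_epochs` object.
#' @param i Trial indices or logical mask.
#' @return The subsetted `eeg_epochs`.
#' @export
subset_epochs <- function(epochs, i) {
  epochs$data <- epochs$data[i, , , drop = FALSE]
  epochs$info <- epochs$info[i, , drop = FALSE]
  rownames(epochs$info) <- NULL
  epochs
}

#' Simulate epoched EEG for one participant
#'
#' One epoch per plan trial: i.i.d. Gaussian noise scaled by
#' `params$sigma_trial` on every channel and sample; deviant trials
#' additionally receive the kernel (spatial topography x temporal window)
#' multiplied by the participant's effect, drawn once per contrast from
#' Normal(`mu_subj`, `sigma_subj`). With probability `artifact_rate` a
#' trial gains a square pulse of +/- `artifact_amplitude` microvolts on
#' one random scalp channel inside -150..600 ms. Trial metadata carries
#' the ground truth (drawn effect, artifact flag).
#'
#' @param plan A `session_plan` (ideally after [mark_analyzable()]).
#' @param params A [sim_params()] object.
#' @param kernel An [effect_kernel()] on `layout`.
#' @param layout An `eeg_layout`.
#' @param seed Optional integer seed.
#' @param blocks Optional integer indices restricting which plan blocks to
#'   simulate (the plan itself is unchanged); default all.
#' @return An `eeg_epochs` object; `$effects` holds the per-contrast drawn
#'   effects, `$info` the per-trial metadata.
#' @export
#' @examples
#' plan <- mark_analyzable(build_session(1))
#' lay <- make_layout("grid12")
#' ep <- simulate_participant_epochs(plan, sim_params(sigma_trial = 10),
#'   effect_kernel(lay, peak_channel = "E06"), lay, seed = 2, blocks = 1)
simulate_participant_epochs <- function(plan, params, kernel, layout,
                                        seed = NULL, blocks = NULL) {
  stopifnot(inherits(plan, "session_plan"), inherits(params, "sim_params"),
            inherits(kernel, "effect_kernel"),
            inherits(layout, "eeg_layout"))
  blocks <- blocks %||% seq_along(plan$blocks)
  if (!length(blocks)) stop("no blocks selected")
  if (!all(kernel$peak_channel %in% layout$channels$name))
    stop("kernel peak channel missing from layout")

  info <- do.call(rbind, lapply(blocks, function(i) {
    tr <- plan$blocks[[i]]$trials
    data.frame(participant = plan$participant_id, block = i,
               block_type = plan$blocks[[i]]$block_type,
               contrast = plan$blocks[[i]]$contrast,
               trial = tr$index, role = tr$role, segment = tr$segment,
               token = tr$token, iti_ms = tr$iti_ms,
               analyzable = if ("analyzable" %in% names(tr))
                 tr$analyzable else NA)
  }))
  rownames(info) <- NULL

  times <- epoch_times(params)
  ch <- layout$channels$name
  n_tr <- nrow(info); n_ch <- length(ch); n_sp <- length(times)

  with_seed(seed, {
    effects <- stats::rnorm(3, params$mu_subj, params$sigma_subj)
    names(effects) <- c("tense", "voicing", "vot")

    data <- array(stats::rnorm(n_tr * n_ch * n_sp, sd = params$sigma_trial),
                  dim = c(n_tr, n_ch, n_sp), dimnames = list(NULL, ch, NULL))

    # deviants: add kernel x participant effect on scalp channels
    topo <- numeric(n_ch)
    topo[match(names(kernel$topography), ch)] <- kernel$topography
    tc <- kernel_time_course(kernel, times)
    signal <- outer(topo, tc)  # n_ch x n_sp
    dev <- which(info$role == "deviant")
    for (t in dev)
      data[t, , ] <- data[t, , ] + effects[[info$contrast[t]]] * signal

    # artifact trials: square pulse on one random scalp channel
    info$artifact <- stats::runif(n_tr) < params$artifact_rate
    scalp <- which(ch %in%
                     layout$channels$name[layout$channels$type == "scalp"])
    art_window <- range(times[in_window(times, c(-150, 600))])
    for (t in which(info$artifact)) {
      chan <- scalp[sample.int(length(scalp), 1)]
      dur <- 100
      onset <- stats::runif(1, art_window[1], art_window[2] - dur)
      sel <- times >= onset & times < onset + dur
      data[t, chan, sel] <- data[t, chan, sel] +
        sample(c(-1, 1), 1) * params$artifact_amplitude
    }
    info$true_effect <- ifelse(info$role == "deviant",
                               effects[info$contrast], 0)

    ep <- new_epochs(data, info, times, layout, params = params,
                     effects = effects)
    add_step(ep, "simulate", seed = seed, blocks = blocks)
  })
}

#' Simulate a stack of participant difference waves
#'
#' ERP-level shortcut generator for calibration and power studies: instead
#' of simulating every single trial, each participant's identity-MMN
#' difference wave is drawn directly as kernel x effect plus white
#' residual noise with SD `sigma_resid` (the participant-level ERP noise
#' left after trial averaging). Distributionally this matches the full
#' trial-level pipeline when `sigma_resid` is set to the aggregated trial
#' noise, at a small fraction of the cost.
#'
#' @param n_participants Number of participants.
#' @param layout An `eeg_layout`.
#' @param times_ms Sample times of the simulated grid in ms.
#' @param kernel An [effect_kernel()] on `layout`.
#' @param mu_subj,sigma_subj Participant-effect distribution (microvolts).
#' @param sigma_resid Residual ERP noise SD per channel/sample.
#' @param seed Optional integer seed.
#' @return An object of class `diff_stack`: list with `data` (array
#'   participants x channels x samples), `channels`, `times`, `layout`,
#'   and `effects` (the drawn ground truth).
#' @export
#' @examples
#' lay <- make_layout("grid12")
#' st <- simulate_diff_stack(8, lay, seq(0, 490, 10),
#'   effect_kernel(lay, "E06"), -0.84, 2.28, 0.5, seed = 1)
simulate_diff_stack <- function(n_participants, layout, times_ms, kernel,
                                mu_subj = -0.84, sigma_subj = 2.28,
                                sigma_resid = 0.5, seed = NULL) {
  stopifnot(n_participants >= 1, inherits(layout, "eeg_layout"),
            sigma_subj >= 0, sigma_resid >= 0)
  scalp <- layout$channels$name[layout$channels$type == "scalp"]
  n_ch <- length(scalp); n_sp <- length(times_ms)
  topo <- kernel$topography[scalp]
  tc <- kernel_time_course(kernel, times_ms)
  signal <- outer(topo, tc)
  with_seed(seed, {
    effects <- stats::rnorm(n_participants, mu_subj, sigma_subj)
    data <- array(stats::rnorm(n_participants * n_ch * n_sp,
                               sd = sigma_resid),
                  dim = c(n_participants, n_ch, n_sp),
                  dimnames = list(NULL, scalp, NULL))
    for (p in seq_len(n_participants))
      data[p, , ] <- data[p, , ] + effects[p] * signal
    structure(list(data = data, channels = scalp, times = times_ms,
                   layout = layout, effects = effects),
              class = "diff_stack")
  })
}

#' @export
print.diff_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<diff_stack>: %d participants x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  invisible(x)
}
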