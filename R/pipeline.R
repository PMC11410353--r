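#' Build a full pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Defaults reproduce the study pipeline: grid64
#' layout, mastoid reference, 100 ms baseline, 75 microvolt rejection
#' over -150..600 ms, 30 Hz zero-phase low-pass, the relaxed >= 30-trial
#' inclusion profile, and a negative-tail cluster permutation test with
#' cluster-forming p < 0.1, minnbchan = 2 and 1000 permutations over the
#' post-stimulus epoch.
#'
#' @param n_participants Number of simulated participants.
#' @param master_seed Master seed; every participant and stage draws from
#'   a derived substream.
#' @param sigma_trial Single-trial noise SD in microvolts (required; see
#'   [sim_params()]).
#' @param contrast `"tense"`, `"voicing"` or `"vot"`.
#' @param condition Deviant condition analysed; defaults to the
#'   pre-registered direction for the contrast (present-tense, voiced,
#'   unaspirated deviants).
#' @param layout Layout preset name or `eeg_layout`.
#' @param blocks `"contrast"` (simulate only the analysed contrast's
#'   blocks), `"all"` (the full 18-block session), or `"pair"` (the first
#'   block of each analysed condition; the cheapest design that still
#'   yields an identity MMN).
#' @param mu_subj,sigma_subj,artifact_rate,artifact_amplitude Passed to
#'   [sim_params()].
#' @param kernel_peak,kernel_window_ms,kernel_shape Effect kernel.
#' @param inclusion_profile `"relaxed"` (>= 30 trials per condition) or
#'   `"original"` (>= 50).
#' @param n_perm,cluster_alpha,minnbchan,stat_window_ms,tail Cluster-test
#'   settings.
#' @param cutoff_hz Low-pass edge (`NULL` disables filtering).
#' @param out Optional path for the JSON run report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 5, master_seed = 1,
                            sigma_trial,
                            contrast = c("tense", "voicing", "vot"),
                            condition = NULL,
                            layout = "grid64",
                            blocks = c("contrast", "all", "pair"),
                            mu_subj = -0.84, sigma_subj = 2.28,
                            artifact_rate = 0, artifact_amplitude = 120,
                            kernel_peak = "Cz",
                            kernel_window_ms = c(200, 400),
                            kernel_shape = "cosine",
                            inclusion_profile = c("relaxed", "original"),
                            n_perm = 1000, cluster_alpha = 0.1,
                            minnbchan = 2, stat_window_ms = c(0, 750),
                            tail = "negative", cutoff_hz = 30,
                            out = NULL) {
  contrast <- match.arg(contrast)
  blocks <- match.arg(blocks)
  inclusion_profile <- match.arg(inclusion_profile)
  condition <- condition %||% switch(contrast, tense = "present",
                                     voicing = "+voi", vot = "-asp")
  if (!identical(token_inventory(condition)$contrast, contrast))
    stop(sprintf("condition '%s' does not belong to contrast '%s'",
                 condition, contrast))
  if (is.character(layout)) layout <- make_layout(layout)
  structure(list(
    n_participants = n_participants, master_seed = master_seed,
    contrast = contrast, condition = condition, layout = layout,
    blocks = blocks,
    sim = sim_params(sigma_trial = sigma_trial, mu_subj = mu_subj,
                     sigma_subj = sigma_subj,
                     artifact_rate = artifact_rate,
                     artifact_amplitude = artifact_amplitude),
    kernel = effect_kernel(layout, peak_channel = kernel_peak,
                           window_ms = kernel_window_ms,
                           shape = kernel_shape),
    inclusion_profile = inclusion_profile,
    min_trials = if (inclusion_profile == "relaxed") 30 else 50,
    stats = list(n_perm = n_perm, cluster_alpha = cluster_alpha,
                 minnbchan = minnbchan, window_ms = stat_window_ms,
                 tail = tail),
    cutoff_hz = cutoff_hz, out = out
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end simulation and analysis pipeline
#'
#' For each simulated participant: builds the 18-block session plan,
#' flags analyzable trials, simulates epoched EEG for the analysed blocks,
#' preprocesses them (reference, demean, baseline, rejection, filter),
#' averages the condition ERPs and forms the identity-MMN difference
#' wave. Participants passing the minimum-trial inclusion rule enter the
#' spatiotemporal cluster-based permutation test. Every stage draws from
#' a named substream of the master seed, so equal configurations rerun
#' identically.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return A list of class `pipeline_report`: per-stage counts (trials
#'   simulated/rejected/analyzable, participants included), per-
#'   participant summaries, the cluster-test summary, the stack of
#'   difference waves, the full `cluster_result`, and a config echo.
#'   Written as JSON to `config$out` when set (timestamps excluded from
#'   the reproducible payload).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_participants = 2, master_seed = 7,
#'                        sigma_trial = 10, contrast = "vot",
#'                        layout = "grid12", kernel_peak = "E06",
#'                        n_perm = 100)
#' rep <- run_pipeline(cfg)
#' rep
#' }
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  lay <- config$layout
  have_refs <- all(c("M1", "M2") %in% lay$channels$name)
  conds <- c(config$condition, partner_condition(config$condition))

  waves <- list()
  participants <- list()
  counts_df <- NULL
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("sim%02d", i)
    p_seed <- derive_seed(config$master_seed, 1000 + i)
    plan <- tryCatch(
      mark_analyzable(build_session(p_seed, pid)),
      error = function(e) stop("stage simulate-plan failed: ",
                               conditionMessage(e)))
    idx <- switch(config$blocks,
      all = seq_along(plan$blocks),
      contrast = which(plan$block_order %in% conds),
      pair = vapply(conds, function(ct)
        which(plan$block_order == ct)[1], 0L))
    ep <- tryCatch(
      simulate_participant_epochs(plan, config$sim, config$kernel, lay,
                                  seed = derive_seed(p_seed, 1),
                                  blocks = idx),
      error = function(e) stop("stage simulate-eeg failed: ",
                               conditionMessage(e)))
    n_sim <- nrow(ep$info)
    # the low-pass is linear and identical per epoch, so it commutes with
    # trial averaging: filter the averaged ERPs, not every epoch
    pre <- tryCatch(
      preprocess(ep,
                 ref_channels = if (have_refs) c("M1", "M2") else NULL,
                 cutoff_hz = NULL),
      error = function(e) stop("stage preprocess failed: ",
                               conditionMessage(e)))
    ep <- pre$epochs
    n_rej <- if (is.null(pre$rejection_log)) 0L else
      sum(!pre$rejection_log$kept)
    erps <- tryCatch(
      compute_condition_erps(ep, config$condition),
      error = function(e) stop("stage immn failed: ",
                               conditionMessage(e)))
    if (!is.null(config$cutoff_hz))
      erps <- lapply(erps, lowpass_waveform, cutoff_hz = config$cutoff_hz)
    wave <- compute_immn(erps$deviant, erps$standard)
    waves[[pid]] <- wave
    counts_df <- rbind(counts_df,
      data.frame(participant = pid,
                 condition = c("deviant", "standard"),
                 n = c(attr(wave, "n_deviant_trials"),
                       attr(wave, "n_standard_trials"))))
    participants[[pid]] <- list(
      participant = pid, seed = p_seed,
      blocks_planned = length(plan$blocks),
      trials_planned = sum(vapply(plan$blocks,
                                  function(b) nrow(b$trials), 0L)),
      blocks_simulated = length(idx),
      trials_simulated = n_sim, trials_rejected = n_rej,
      n_deviant_trials = attr(wave, "n_deviant_trials"),
      n_standard_trials = attr(wave, "n_standard_trials"),
      true_effect = unname(ep$effects[config$contrast]))
  }

  included <- tryCatch(
    filter_participants(counts_df, config$min_trials),
    error = function(e) stop("stage inclusion failed: ",
                             conditionMessage(e)))
  if (length(included) < 2)
    stop("stage cluster-test failed: fewer than 2 participants included")
  stack <- diff_stack(waves[included], lay)
  result <- tryCatch(
    permutation_test(stack, n_perm = config$stats$n_perm,
                     seed = derive_seed(config$master_seed, 2),
                     cluster_alpha = config$stats$cluster_alpha,
                     minnbchan = config$stats$minnbchan,
                     window_ms = config$stats$window_ms,
                     tail = config$stats$tail),
    error = function(e) stop("stage cluster-test failed: ",
                             conditionMessage(e)))

  report <- structure(list(
    version = as.character(utils::packageVersion("oddwave")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_participants = config$n_participants,
    participants_included = included,
    blocks_planned = participants[[1]]$blocks_planned,
    trials_planned_per_session = participants[[1]]$trials_planned,
    total_trials_simulated = sum(vapply(participants, `[[`, 0,
                                        "trials_simulated")),
    total_trials_rejected = sum(vapply(participants, `[[`, 0,
                                       "trials_rejected")),
    participants = participants,
    clusters = summary(result),
    min_cluster_p = min_cluster_p(result),
    config_echo = list(
      contrast = config$contrast, condition = config$condition,
      layout = lay$preset, blocks = config$blocks,
      master_seed = config$master_seed,
      sim = unclass(config$sim),
      inclusion_profile = config$inclusion_profile,
      min_trials = config$min_trials, stats = config$stats,
      cutoff_hz = config$cutoff_hz),
    stack = stack, cluster_result = result
  ), class = "pipeline_report")

  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' Serialize a pipeline report to JSON
#'
#' Writes every scalar/tabular report field (the arrays and the full
#' cluster object stay in R); the timestamp is written but excluded from
#' [report_digest()].
#'
#' @param report A `pipeline_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- setdiff(names(report), c("stack", "cluster_result"))
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Reproducibility digest of a report
#'
#' Serializes the report without its timestamp (and without the heavy R
#' objects); equal configurations plus seeds yield identical digests.
#'
#' @param report A `pipeline_report`.
#' @return A character scalar (serialized JSON).
#' @export
report_digest <- function(report) {
  keep <- setdiff(names(report),
                  c("stack", "cluster_result", "timestamp"))
  jsonlite::toJSON(report[keep], auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report>: %d participants (%d included), %d blocks planned each\n",
              x$n_participants, length(x$participants_included),
              x$blocks_planned))
  cat(sprintf("  trials: %d planned/session, %d simulated total, %d rejected\n",
              x$trials_planned_per_session, x$total_trials_simulated,
              x$total_trials_rejected))
  cat(sprintf("  contrast %s ('%s' deviants): min cluster p = %s\n",
              x$config_echo$contrast, x$config_echo$condition,
              format(x$min_cluster_p)))
  invisible(x)
}
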