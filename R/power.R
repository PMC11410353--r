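#' Cohen's d from a mean and standard deviation
#'
#' The assumed effect size of the design is the participant-level mean
#' MMN amplitude divided by its between-participant SD; the reference
#' values -0.84 / 2.28 microvolts give d = -0.37.
#'
#' @param mean_uv Mean effect in microvolts.
#' @param sd_uv Between-participant SD in microvolts (> 0).
#' @return `mean_uv / sd_uv`.
#' @export
#' @examples
#' round(effect_size_d(-0.84, 2.28), 2)  # -0.37
effect_size_d <- function(mean_uv, sd_uv) {
  if (!is.numeric(sd_uv) || any(sd_uv <= 0))
    stop("sd_uv must be positive")
  mean_uv / sd_uv
}

#' Closed-form power of the paired t test
#'
#' Noncentral-t benchmark for the zero-trial-noise limit of the power
#' simulation: with effect size `d` and `n` participants, the one-tailed
#' paired-t power is `1 - F_nct(t_crit; df = n - 1, ncp = |d| sqrt(n))`,
#' where `t_crit` is the central-t critical value at `alpha`.
#'
#' @param d Effect size (mean / SD of the paired differences).
#' @param n Number of participants (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param tail `"one_sided"` (default) or `"two_sided"`.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' analytic_power(0.3684, 60)
analytic_power <- function(d, n, alpha = 0.05,
                           tail = c("one_sided", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(n >= 2)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  if (tail == "one_sided") {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(crit, df, ncp)) + stats::pt(-crit, df, ncp)
  }
}

#' Simulate power for one (participants, deviants) design cell
#'
#' Each simulation draws per-participant effects from
#' Normal(`mu_subj`, `sigma_subj`); a participant's deviant-trial mean is
#' the effect plus Normal(0, `sigma_trial` / sqrt(n_deviants)) noise and
#' the standard-trial mean is pure noise with the standard count set by
#' the standard:deviant `ratio` (85:15 by default, so 120 deviants face
#' 680 standards). Participant-level deviant and standard means are
#' compared by a one-tailed paired t test (deviants more negative) at
#' `alpha`; power is the significant fraction of `n_sims` simulations.
#'
#' With `trial_profile = "reduced"`, each participant's analyzable
#' deviant count is drawn uniformly between `min_trials` and
#' `n_deviants`, approximating a sample in which some participants just
#' clear the relaxed 30-trial inclusion floor.
#'
#' @param n_participants Participants per simulated study (>= 2).
#' @param n_deviants Analyzable deviant trials per participant.
#' @param params A [sim_params()] object (here `sigma_trial` is the SD of
#'   the single-trial amplitude measure, in microvolts).
#' @param ratio Standard:deviant ratio as a length-2 vector (85, 15).
#' @param alpha One-tailed significance level (0.05).
#' @param n_sims Number of simulated studies.
#' @param seed Optional integer seed.
#' @param trial_profile `"nominal"` or `"reduced"` (see above).
#' @param min_trials Inclusion floor used by the reduced profile (30).
#' @return An object of class `power_cell`: list with the design, the
#'   `power` estimate, and its Monte-Carlo `se`.
#' @export
#' @examples
#' simulate_power_cell(20, 100, sim_params(sigma_trial = 15),
#'                     n_sims = 200, seed = 1)
simulate_power_cell <- function(n_participants, n_deviants, params,
                                ratio = c(85, 15), alpha = 0.05,
                                n_sims = 1000, seed = NULL,
                                trial_profile = c("nominal", "reduced"),
                                min_trials = 30) {
  trial_profile <- match.arg(trial_profile)
  stopifnot(n_participants >= 2, n_deviants >= 1, n_sims >= 1,
            inherits(params, "sim_params"))
  if (length(ratio) != 2 || any(ratio <= 0))
    stop("degenerate standard:deviant ratio")
  with_seed(seed, {
    P <- n_participants
    total <- P * n_sims
    nd <- if (trial_profile == "reduced") {
      if (min_trials > n_deviants)
        stop("min_trials exceeds n_deviants")
      sample(min_trials:n_deviants, total, replace = TRUE)
    } else rep(n_deviants, total)
    ns <- pmax(1, round(nd * ratio[1] / ratio[2]))
    eff <- stats::rnorm(total, params$mu_subj, params$sigma_subj)
    dmean <- eff + stats::rnorm(total, 0, params$sigma_trial / sqrt(nd))
    smean <- stats::rnorm(total, 0, params$sigma_trial / sqrt(ns))
    d <- matrix(dmean - smean, P, n_sims)
    m <- colMeans(d)
    s <- sqrt((colSums(d^2) - P * m^2) / (P - 1))
    tt <- m / (s / sqrt(P))
    sig <- tt < stats::qt(alpha, P - 1)
    p <- mean(sig)
    structure(list(n_participants = P, n_deviants = n_deviants,
                   ratio = ratio, alpha = alpha, n_sims = n_sims,
                   trial_profile = trial_profile,
                   power = p, se = sqrt(p * (1 - p) / n_sims)),
              class = "power_cell")
  })
}

#' @export
print.power_cell <- function(x, ...) {
  cat(sprintf("<power_cell>: n = %d, deviants = %d -> power %.3f (MC SE %.3f, %d sims)\n",
              x$n_participants, x$n_deviants, x$power, x$se, x$n_sims))
  invisible(x)
}

#' Simulated power over a (participants x deviants) grid
#'
#' One [simulate_power_cell()] per combination, each on its own seeded
#' substream of `seed`.
#'
#' @param n_participants_list,n_deviants_list Grid margins.
#' @param params A [sim_params()] object.
#' @param n_sims Simulations per cell.
#' @param seed Optional integer master seed.
#' @param ... Passed to [simulate_power_cell()].
#' @return An object of class `power_grid`: data frame with columns
#'   `n_participants`, `n_deviants`, `power`, `mc_se`.
#' @export
power_grid <- function(n_participants_list, n_deviants_list, params,
                       n_sims = 1000, seed = NULL, ...) {
  stopifnot(length(n_participants_list) >= 1,
            length(n_deviants_list) >= 1)
  cells <- expand.grid(n_participants = n_participants_list,
                       n_deviants = n_deviants_list)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cell_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    simulate_power_cell(cells$n_participants[i], cells$n_deviants[i],
                        params, n_sims = n_sims, seed = cell_seed, ...)
  })
  out <- data.frame(n_participants = cells$n_participants,
                    n_deviants = cells$n_deviants,
                    power = vapply(res, `[[`, 0, "power"),
                    mc_se = vapply(res, `[[`, 0, "se"))
  class(out) <- c("power_grid", "data.frame")
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "n_sims") <- n_sims
  out
}

#' Plot a power grid
#'
#' Power against deviant count, one line per participant count.
#'
#' @param x A `power_grid`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.power_grid <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x)[, 1:3], direction = "wide",
                         idvar = "n_deviants",
                         timevar = "n_participants")
  graphics::matplot(wide$n_deviants, wide[, -1], type = "b", pch = 16,
                    xlab = "deviants per condition", ylab = "power",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", bty = "n",
                   legend = paste0("n = ", unique(x$n_participants)),
                   col = seq_along(unique(x$n_participants)),
                   lty = seq_along(unique(x$n_participants)))
  invisible(x)
}
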