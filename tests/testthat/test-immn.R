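# noiseless vot session on a 2-channel chain: every deviant epoch equals
# effect x kernel, so the whole iMMN chain is exactly checkable
noiseless_vot <- function(seed = 31, mu = -0.84) {
  lay <- make_layout("chain-2")
  k <- effect_kernel(lay, "A")
  plan <- mark_analyzable(build_session(seed))
  idx <- which(plan$block_order %in% c("+asp", "-asp"))
  ep <- simulate_participant_epochs(
    plan, sim_params(sigma_trial = 0, mu_subj = mu, sigma_subj = 0),
    k, lay, seed = seed + 1, blocks = idx)
  list(ep = ep, k = k, lay = lay)
}

test_that("condition ERPs pool the right cells with the right counts", {
  s <- noiseless_vot()
  erps <- compute_condition_erps(s$ep, "-asp")
  # 3 blocks x 39 analyzable deviants, no artifacts
  expect_equal(attr(erps$deviant, "n_trials"), 117)
  # standards: same token ('ba') in the mirror (+asp) blocks,
  # 232 analyzable standards per block x 3 blocks
  expect_equal(attr(erps$standard, "n_trials"), 696)
  expect_equal(attr(erps$deviant, "tokens"), "ba")
  expect_equal(attr(erps$standard, "tokens"), "ba")
  # noiseless: deviant ERP = effect x kernel; standard ERP = 0
  tc <- kernel_time_course(s$k, s$ep$times)
  expect_equal(unname(erps$deviant["A", ]),
               unname(s$ep$effects["vot"] * tc), tolerance = 1e-12)
  expect_true(all(erps$standard == 0))
  expect_error(compute_condition_erps(s$ep, "past"),
               "no qualifying")
})

test_that("a single-epoch ERP equals that epoch", {
  s <- noiseless_vot()
  dev <- which(s$ep$info$role == "deviant" & s$ep$info$analyzable &
                 s$ep$info$block_type == "-asp")
  one <- subset_epochs(s$ep, c(dev[1],
    which(s$ep$info$block_type == "+asp" & s$ep$info$role == "standard" &
            s$ep$info$analyzable)[1]))
  erps <- compute_condition_erps(one, "-asp")
  expect_equal(unclass(erps$deviant), one$data[1, , ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(erps$deviant, "n_trials"), 1)
})

test_that("the iMMN is deviant minus standard and antisymmetric", {
  s <- noiseless_vot()
  erps <- compute_condition_erps(s$ep, "-asp")
  w <- compute_immn(erps$deviant, erps$standard)
  expect_s3_class(w, "difference_wave")
  expect_equal(unclass(w), unclass(erps$deviant) - unclass(erps$standard),
               ignore_attr = TRUE)
  expect_equal(attr(w, "n_deviant_trials"), 117)
  back <- compute_immn(erps$standard, erps$deviant)
  expect_equal(unclass(back), -unclass(w), ignore_attr = TRUE)
  # identical inputs cancel exactly
  zero <- compute_immn(erps$deviant, erps$deviant)
  expect_true(all(zero == 0))
  # mismatched token sets refuse to difference
  other <- compute_condition_erps(s$ep, "+asp")
  expect_error(compute_immn(erps$deviant, other$standard),
               "different token sets")
})

test_that("noiseless iMMN recovers the drawn effect to machine precision", {
  s <- noiseless_vot(seed = 77, mu = -1.3)
  w <- immn_for_condition(s$ep, "-asp")
  expect_equal(matched_amplitude(w, s$k), unname(s$ep$effects["vot"]),
               tolerance = 1e-12)
  # boxcar kernel: the plain window mean recovers it too
  lay <- s$lay
  kb <- effect_kernel(lay, "A", shape = "boxcar")
  plan <- mark_analyzable(build_session(78))
  idx <- which(plan$block_order %in% c("+asp", "-asp"))
  ep <- simulate_participant_epochs(
    plan, sim_params(sigma_trial = 0, mu_subj = -0.84, sigma_subj = 2.28),
    kb, lay, seed = 79, blocks = idx)
  w2 <- immn_for_condition(ep, "-asp")
  expect_equal(window_mean(w2, "A", c(200, 400)),
               unname(ep$effects["vot"]), tolerance = 1e-12)
})

test_that("participant inclusion applies the minimum-trial floor", {
  counts <- data.frame(
    participant = rep(c("p1", "p2", "p3"), each = 2),
    condition = rep(c("deviant", "standard"), 3),
    n = c(35, 60, 29, 80, 30, 30))
  expect_setequal(filter_participants(counts), c("p1", "p3"))
  expect_setequal(filter_participants(counts, min_trials = 50),
                  character(0))
  expect_error(filter_participants(counts[-1, ]), "missing counts")
  counts$n[1] <- NA
  expect_error(filter_participants(counts), "missing trial counts")
})

test_that("grand-average iMMN converges on the population effect", {
  lay <- make_layout("grid12")
  k <- effect_kernel(lay, "E06")
  st <- simulate_diff_stack(200, lay, seq(0, 495, 5), k,
                            mu_subj = -0.84, sigma_subj = 2.28,
                            sigma_resid = 1, seed = 41)
  tc <- kernel_time_course(k, st$times)
  amps <- apply(st$data[, "E06", ], 1, function(w)
    sum(w * tc) / sum(tc^2))
  expect_lt(abs(mean(amps) - (-0.84)), 3 * 2.28 / sqrt(200))
})
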