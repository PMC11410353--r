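grid12_epochs <- function(fill = 0, n_trials = 1, times = seq(-150, 749)) {
  lay <- make_layout("grid12")
  data <- array(fill, dim = c(n_trials, 14, length(times)))
  make_epochs(data, lay, times)
}

test_that("mastoid re-referencing does the arithmetic and is idempotent", {
  ep <- grid12_epochs()
  ep$data[, 1:12, ] <- 10
  ep$data[, "M1", ] <- 2
  ep$data[, "M2", ] <- 4
  r1 <- rereference(ep)
  expect_true(all(r1$data[, 1:12, ] == 7))
  expect_true(all(r1$data[, "M1", ] == -1))
  r2 <- rereference(r1)
  expect_equal(r2$data, r1$data)

  # zero references leave data untouched
  ep2 <- grid12_epochs()
  ep2$data[, 1:12, ] <- 3
  expect_equal(rereference(ep2)$data, ep2$data)
  expect_error(rereference(ep, "M9"), "not found")
  # purity: the input object is unchanged
  expect_true(all(ep$data[, 1:12, ] == 10))
})

test_that("demeaning and baseline correction satisfy their definitions", {
  ep <- grid12_epochs(fill = 5)
  expect_true(all(demean_epochs(ep)$data == 0))
  expect_true(all(abs(baseline_correct(ep)$data) < 1e-12))

  set.seed(1)
  ep$data[] <- rnorm(length(ep$data))
  dm <- demean_epochs(ep)
  expect_lt(max(abs(rowMeans(dm$data, dims = 2))), 1e-12)
  dm2 <- demean_epochs(dm)
  expect_equal(dm2$data, dm$data)

  # linear ramp: baseline-window mean becomes exactly zero
  ep2 <- grid12_epochs()
  ramp <- seq_along(ep2$times) / 100
  for (c in 1:14) ep2$data[1, c, ] <- ramp
  bc <- baseline_correct(ep2, c(-100, 0))
  sel <- ep2$times >= -100 & ep2$times < 0
  expect_lt(max(abs(rowMeans(bc$data[, , sel, drop = FALSE], dims = 2))),
            1e-12)
  # zero-mean baseline leaves post-stimulus data unchanged
  ep3 <- grid12_epochs()
  post <- ep3$times >= 0
  ep3$data[, , post] <- 2
  expect_equal(baseline_correct(ep3)$data, ep3$data)
  expect_error(baseline_correct(ep3, c(2000, 2100)), "no samples")
})

test_that("amplitude rejection takes boundary decisions exactly", {
  ep <- grid12_epochs(n_trials = 3)
  ep$data[1, 3, ep$times == 300] <- 80    # inside window -> removed
  ep$data[2, 3, ep$times == 700] <- -80   # outside window -> kept
  ep$data[3, , ] <- 74.9                  # below threshold -> kept
  r <- reject_artifacts(ep, 75, c(-150, 600))
  expect_equal(r$log$kept, c(FALSE, TRUE, TRUE))
  expect_equal(nrow(r$epochs$info), 2)
  expect_equal(r$log$channel[1], "E03")
  expect_equal(r$log$time_ms[1], 300)
  expect_equal(sum(!r$log$kept) + sum(r$log$kept), 3)

  # threshold is strict: exactly 75 survives, reference channels ignored
  ep2 <- grid12_epochs(n_trials = 2)
  ep2$data[1, 5, 500] <- 75
  ep2$data[2, "M1", 500] <- 300
  r2 <- reject_artifacts(ep2)
  expect_true(all(r2$log$kept))
  expect_error(reject_artifacts(ep2, window_ms = c(-500, 600)),
               "outside the epoch")
})

test_that("rejection separates injected artifacts from clean trials", {
  lay <- make_layout("grid12")
  plan <- mark_analyzable(build_session(21))
  p <- sim_params(sigma_trial = 10, mu_subj = 0, sigma_subj = 0,
                  artifact_rate = 0.05, artifact_amplitude = 120)
  ep <- simulate_participant_epochs(plan, p, effect_kernel(lay, "E06"),
                                    lay, seed = 13, blocks = 1:6)
  r <- reject_artifacts(ep)
  injected <- ep$info$artifact
  expect_gt(sum(injected), 50)
  expect_gte(mean(!r$log$kept[injected]), 0.99)
  expect_lt(mean(!r$log$kept[!injected]), 0.01)
})

test_that("low-pass filter is zero-phase with the designed band behaviour", {
  f <- design_lowpass(30, 1000)
  expect_equal(f$order, 440)
  expect_equal(f$transition_bw, 7.5)
  gains <- filter_gain_db(f, c(0, 10, 20, 60, 100))
  expect_equal(gains[1], 0, tolerance = 1e-10)  # exact unit DC gain
  expect_lt(max(abs(gains[2:3])), 0.05)         # passband ripple, dB
  expect_lt(gains[4], -20)                            # 60 Hz attenuated
  expect_lt(abs(filter_gain_db(f, f$fc) - 20 * log10(0.5)), 0.2)
  expect_error(design_lowpass(600, 1000), "Nyquist")

  # DC epoch passes unchanged to within 0.1%
  ep <- grid12_epochs(fill = 1)
  lp <- lowpass_filter(ep, 30)
  expect_lt(max(abs(lp$data - 1)), 0.001)

  # 60 Hz sinusoid attenuated by >= 20 dB (central samples, edges excluded)
  ep2 <- grid12_epochs()
  s <- sin(2 * pi * 60 * (ep2$times / 1000))
  for (c in 1:14) ep2$data[1, c, ] <- s
  lp2 <- lowpass_filter(ep2, 30)
  mid <- 200:700
  atten <- 20 * log10(sqrt(mean(lp2$data[1, 1, mid]^2)) /
                        sqrt(mean(s[mid]^2)))
  expect_lt(atten, -20)

  # symmetric pulse stays symmetric about the same sample (zero phase)
  ep3 <- grid12_epochs()
  ep3$data[1, , 450] <- 1
  lp3 <- lowpass_filter(ep3, 30)
  y <- lp3$data[1, 1, ]
  expect_equal(which.max(y), 450)
  k <- 1:100
  expect_equal(y[450 + k], y[450 - k], tolerance = 1e-12)
})

test_that("bad-channel interpolation averages good neighbours", {
  lay <- make_layout("chain-3")
  data <- array(0, dim = c(1, 3, 10))
  data[1, 1, ] <- 2
  data[1, 3, ] <- 4
  data[1, 2, ] <- 99
  ep <- make_epochs(data, lay, times = 0:9)
  fixed <- interpolate_bad_channels(ep, "B")
  expect_true(all(fixed$data[1, 2, ] == 3))
  expect_equal(fixed$data[1, 1, ], ep$data[1, 1, ])
  expect_equal(interpolate_bad_channels(ep, character(0))$data, ep$data)
  expect_error(interpolate_bad_channels(ep, c("A", "B", "C", "D")),
               "at most three")
  expect_error(interpolate_bad_channels(ep, c("A", "B", "C")),
               "no good neighbour")
})

test_that("the preprocessing driver enforces the canonical stage order", {
  lay <- make_layout("grid12")
  plan <- mark_analyzable(build_session(22))
  ep <- simulate_participant_epochs(
    plan, sim_params(sigma_trial = 5), effect_kernel(lay, "E06"), lay,
    seed = 14, blocks = 1)
  out <- preprocess(ep)
  steps <- vapply(out$epochs$steps, `[[`, "", "step")
  expect_equal(steps, c("simulate", "rereference", "demean", "ica",
                        "baseline", "reject", "lowpass"))
  ica <- out$epochs$steps[[which(steps == "ica")]]
  expect_equal(ica$status, "skipped")
  expect_s3_class(out$rejection_log, "rejection_log")
  expect_warning(
    preprocess(ep, order = c("demean", "baseline"), cutoff_hz = NULL),
    "non-default preprocessing order")
})
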