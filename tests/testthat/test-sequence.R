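test_that("run-length sampler respects bounds, total, and feasibility", {
  x <- sample_run_lengths(40, 271, 4, 9, seed = 1)
  expect_length(x, 40)
  expect_equal(sum(x), 271)
  expect_true(all(x >= 4 & x <= 9))

  expect_equal(sample_run_lengths(1, 5, 4, 9), 5L)
  expect_error(sample_run_lengths(2, 20, 4, 9), "\\[8, 18\\]")
  expect_error(sample_run_lengths(2, 7, 4, 9), "infeasible")

  expect_identical(sample_run_lengths(40, 271, 4, 9, seed = 7),
                   sample_run_lengths(40, 271, 4, 9, seed = 7))
  expect_false(identical(sample_run_lengths(40, 271, 4, 9, seed = 7),
                         sample_run_lengths(40, 271, 4, 9, seed = 8)))
})

test_that("composition sampling is uniform over all bounded compositions", {
  # small instances checked against exhaustive enumeration
  cases <- list(c(2, 10, 4, 9), c(3, 15, 4, 9), c(3, 12, 2, 6))
  set.seed(42)
  for (cs in cases) {
    all_comp <- enumerate_compositions(cs[1], cs[2], cs[3], cs[4])
    keys <- vapply(all_comp, paste, "", collapse = ",")
    draws <- replicate(6000, paste(
      sample_run_lengths(cs[1], cs[2], cs[3], cs[4]), collapse = ","))
    expect_true(all(draws %in% keys))
    observed <- table(factor(draws, levels = keys))
    p <- stats::chisq.test(observed)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("blocks have the published trial structure", {
  b <- build_block("past", seed = 3)
  tr <- b$trials
  expect_equal(nrow(tr), 328)
  expect_equal(sum(tr$role == "deviant"), 40)
  expect_equal(sum(tr$segment == "habituation"), 16)
  expect_equal(sum(tr$segment == "pseudorandom" & tr$role == "standard"),
               271)
  expect_equal(sum(tr$segment == "final"), 1)
  expect_equal(tr$role[nrow(tr)], "standard")
  expect_true(all(tr$role[tr$segment == "habituation"] == "standard"))

  # every deviant preceded by an unbroken run of 4-9 standards
  # (habituation trials not counted towards the first run)
  pseudo <- tr[tr$segment != "habituation" & tr$segment != "final", ]
  runs <- integer(0)
  count <- 0
  for (i in seq_len(nrow(pseudo))) {
    if (pseudo$role[i] == "standard") count <- count + 1
    else { runs <- c(runs, count); count <- 0 }
  }
  expect_length(runs, 40)
  expect_true(all(runs >= 4 & runs <= 9))
  expect_equal(sum(runs), 271)
  expect_equal(runs, b$run_lengths)

  expect_true(all(tr$iti_ms >= 900 & tr$iti_ms <= 1100))
  expect_true(all(tr$iti_ms == as.integer(tr$iti_ms)))
})

test_that("block tokens come from the right inventories, roughly evenly", {
  inv <- token_inventory("past")
  expect_equal(inv$deviant_tokens, c("gave", "met", "sank"))
  expect_length(inv$standard_tokens, 12)
  expect_length(intersect(inv$deviant_tokens, inv$standard_tokens), 0)
  expect_length(token_inventory("+voi")$deviant_tokens, 5)
  expect_length(token_inventory("+asp")$standard_tokens, 1)
  expect_error(token_inventory("nope"), "unknown block type")

  b <- build_block("past", seed = 11)
  dev_tok <- b$trials$token[b$trials$role == "deviant"]
  std_tok <- b$trials$token[b$trials$role == "standard"]
  expect_true(all(dev_tok %in% inv$deviant_tokens))
  expect_true(all(std_tok %in% inv$standard_tokens))
  # deviant tokens chosen with similar frequency (chi-square GOF)
  observed <- table(factor(dev_tok, levels = inv$deviant_tokens))
  expect_gt(stats::chisq.test(observed)$p.value, 0.01)

  expect_error(build_block("past", inventory = token_inventory("present")),
               "not 'past'")
})

test_that("sessions contain 18 blocks, 6 types x 3, no adjacent repeats", {
  for (seed in c(1, 202, 4040)) {
    plan <- build_session(seed)
    expect_length(plan$blocks, 18)
    expect_true(all(table(plan$block_order) == 3))
    expect_false(any(plan$block_order[-1] ==
                       plan$block_order[-18]))
    expect_equal(nrow(as.data.frame(plan)), 5904)
  }
  expect_identical(build_session(5), build_session(5))
  expect_false(identical(build_session(5), build_session(6)))
})

test_that("analyzable flags implement the pre-registered exclusions", {
  plan <- mark_analyzable(build_session(9))
  for (b in plan$blocks) {
    tr <- b$trials
    expect_equal(sum(tr$analyzable & tr$role == "deviant"), 39)
    expect_false(any(tr$analyzable[tr$segment == "habituation"]))
    dev <- which(tr$role == "deviant")
    expect_false(tr$analyzable[dev[1]])
    expect_true(all(tr$analyzable[dev[-1]]))
    post <- dev + 1
    post <- post[post <= nrow(tr)]
    expect_false(any(tr$analyzable[post]))
    expect_false(tr$analyzable[nrow(tr)])  # final standard follows deviant
    expect_equal(sum(tr$analyzable & tr$role == "standard"), 271 - 39)
  }
  # per condition: 3 blocks x 39 analyzable deviants = 117
  df <- as.data.frame(plan)
  counts <- table(df$block_type[df$analyzable & df$role == "deviant"])
  expect_true(all(counts == 117))
  # deviants presented (not just analyzable): 40 x 3 = 120 per condition
  presented <- table(df$block_type[df$role == "deviant"])
  expect_true(all(presented == 120))
})
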