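stack_from_array <- function(data, layout, times = NULL) {
  ch <- layout$channels$name[layout$channels$type == "scalp"]
  dimnames(data) <- list(NULL, ch, NULL)
  structure(list(data = data, channels = ch,
                 times = times %||% (seq_len(dim(data)[3]) - 1),
                 layout = layout, effects = NULL),
            class = "diff_stack")
}

test_that("the paired t map matches a hand computation", {
  lay <- make_layout("chain-2")
  d <- array(0, dim = c(3, 2, 3))
  d[, 1, 1] <- c(-1, -2, -3)
  d[, 1, 2:3] <- rnorm(6)
  d[, 2, ] <- rnorm(9)
  tm <- paired_t_map(stack_from_array(d, lay))
  # mean -2, sd 1 -> t = -2 / (1 / sqrt(3)) = -3.4641, df = 2
  expect_equal(unname(tm$t[1, 1]), -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tm$df, 2)
  expect_error(paired_t_map(stack_from_array(
    array(0, dim = c(1, 2, 3)), lay)), "at least 2")
})

test_that("degenerate zero-variance cells follow the declared rules", {
  lay <- make_layout("chain-2")
  d <- array(rnorm(3 * 2 * 3), dim = c(3, 2, 3))
  d[, 1, 1] <- 0          # identically zero -> t = 0
  d[, 2, 2] <- -1         # zero variance, nonzero mean -> -Inf
  expect_warning(tm <- paired_t_map(stack_from_array(d, lay)),
                 "zero-variance")
  expect_equal(unname(tm$t[1, 1]), 0)
  expect_equal(unname(tm$t[2, 2]), -Inf)
  # infinite cells never enter clusters
  cl <- extract_clusters(tm, cluster_alpha = 0.1, minnbchan = 0)
  for (x in cl)
    expect_false(any(x$members$channel == "B" & x$members$sample == 2))
})

test_that("adding a constant shifts the t statistic monotonically", {
  lay <- make_layout("chain-2")
  set.seed(2)
  base <- array(rnorm(6 * 2 * 2), dim = c(6, 2, 2))
  tvals <- vapply(c(-1, 0, 1, 2), function(cc) {
    d <- base
    d[, 1, 1] <- d[, 1, 1] + cc
    paired_t_map(stack_from_array(d, lay))$t[1, 1]
  }, 0)
  expect_true(all(diff(tvals) > 0))
})

test_that("pruning and flood fill reproduce the worked micro examples", {
  # chain A-B-C-D, one sample, all masked, minnbchan = 2:
  # A and D have one masked neighbour each -> pruned; {B, C} remain
  lay <- make_layout("chain-4")
  t4 <- matrix(c(-3, -4, -5, -6), 4, 1,
               dimnames = list(LETTERS[1:4], NULL))
  cl <- extract_clusters(make_tmap(t4, lay), 0.1, 2)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members$channel, c("B", "C"))
  expect_equal(cl[[1]]$mass, -9)
  expect_equal(cl[[1]]$sign, -1)

  # complete-3 triangle: every node keeps 2 masked neighbours
  k3 <- make_layout("complete-3")
  t3 <- matrix(c(-3, -3, -3), 3, 1, dimnames = list(LETTERS[1:3], NULL))
  cl3 <- extract_clusters(make_tmap(t3, k3), 0.1, 2)
  expect_length(cl3, 1)
  expect_equal(nrow(cl3[[1]]$members), 3)
  expect_equal(cl3[[1]]$mass, -9)

  # nothing above threshold -> no clusters
  cl0 <- extract_clusters(make_tmap(matrix(0, 4, 1,
    dimnames = list(LETTERS[1:4], NULL)), lay), 0.1, 2)
  expect_length(cl0, 0)
})

test_that("cluster extraction agrees with the brute-force oracle", {
  set.seed(3)
  configs <- list(list(lay = make_layout("chain-5"), S = 6),
                  list(lay = make_layout("complete-4"), S = 4),
                  list(lay = make_layout("grid12"), S = 5))
  for (cfg in configs) {
    lay <- cfg$lay
    C <- nrow(lay$adjacency)
    for (mnb in c(0, 1, 2)) {
      for (rep in 1:60) {
        mask <- matrix(runif(C * cfg$S) < 0.45, C, cfg$S)
        tmat <- matrix(0, C, cfg$S,
                       dimnames = list(rownames(lay$adjacency), NULL))
        tmat[mask] <- -runif(sum(mask), 2, 5)  # all beyond the threshold
        tm <- make_tmap(tmat, lay, df = 10)
        got <- pkg_clusters_canon(extract_clusters(tm, 0.1, mnb),
                                  rownames(tmat))
        want <- canon_clusters(oracle_clusters(tmat, mask,
                                               lay$adjacency, mnb))
        expect_equal(got, want)
      }
    }
  }
})

test_that("minnbchan = 0 pruning is the identity", {
  lay <- make_layout("chain-5")
  set.seed(4)
  tmat <- matrix(-3 * (runif(5 * 4) < 0.5), 5, 4,
                 dimnames = list(LETTERS[1:5], NULL))
  got0 <- pkg_clusters_canon(
    extract_clusters(make_tmap(tmat, lay), 0.1, 0), rownames(tmat))
  want <- canon_clusters(oracle_clusters(tmat, tmat != 0,
                                         lay$adjacency, 0))
  expect_equal(got0, want)
})

test_that("permutation p-values follow the (r + 1) / (n + 1) convention", {
  lay <- make_layout("grid12")
  k <- effect_kernel(lay, "E06")
  # overwhelming effect: observed mass beyond every permutation extreme
  st <- simulate_diff_stack(20, lay, seq(0, 490, 10), k,
                            mu_subj = -6, sigma_subj = 0.05,
                            sigma_resid = 0.05, seed = 51)
  res <- permutation_test(st, n_perm = 999, seed = 52)
  expect_equal(min_cluster_p(res), 1 / 1000)
  ps <- vapply(res$clusters, `[[`, 0, "monte_carlo_p")
  expect_true(all(ps >= 1 / 1000 & ps <= 1))
  expect_length(res$null_extremes$negative, 999)

  res2 <- permutation_test(st, n_perm = 999, seed = 52)
  expect_identical(summary(res), summary(res2))
  res3 <- permutation_test(st, n_perm = 999, seed = 53)
  expect_false(identical(res$null_extremes, res3$null_extremes))
})

test_that("two-sided mode finds positive clusters with doubled p", {
  lay <- make_layout("grid12")
  k <- effect_kernel(lay, "E06")
  st <- simulate_diff_stack(20, lay, seq(0, 490, 10), k,
                            mu_subj = 6, sigma_subj = 0.05,
                            sigma_resid = 0.05, seed = 61)
  res <- permutation_test(st, n_perm = 199, seed = 62,
                          tail = "two_sided")
  top <- res$clusters[[1]]
  expect_equal(top$sign, 1)
  expect_equal(top$monte_carlo_p, 2 / 200)
  # the negative tail alone finds nothing this extreme
  resn <- permutation_test(st, n_perm = 199, seed = 62,
                           tail = "negative")
  expect_true(is.na(min_cluster_p(resn)) || min_cluster_p(resn) > 0.5)
})

test_that("analysis windows restrict the tested samples", {
  lay <- make_layout("grid12")
  k <- effect_kernel(lay, "E06")
  st <- simulate_diff_stack(15, lay, seq(0, 745, 5), k,
                            mu_subj = -3, sigma_subj = 0.1,
                            sigma_resid = 0.1, seed = 71)
  # exploratory-style window excluding the effect -> no effect cluster
  res_out <- permutation_test(st, n_perm = 99, seed = 72,
                              window_ms = c(450, 745))
  expect_true(is.na(min_cluster_p(res_out)) ||
                min_cluster_p(res_out) > 0.1)
  res_in <- permutation_test(st, n_perm = 99, seed = 72,
                             window_ms = c(100, 400))
  expect_lte(min_cluster_p(res_in), 0.05)
  expect_true(all(res_in$tmap$times >= 100 & res_in$tmap$times <= 400))
})
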