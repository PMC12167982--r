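test_that("dichotomization follows the unit median and the tie policy", {
  expect_equal(dichotomize(c(10, 20, 30, 40)), c(0L, 0L, 1L, 1L))
  # (1, 5, 3): median 3; the middle value ties and is dropped by default
  expect_equal(dichotomize(c(1, 5, 3)), c(0L, 1L))
  expect_equal(dichotomize(c(1, 5, 3), tie = "assign_low"), c(0L, 1L, 0L))
  expect_equal(dichotomize(c(1, 5, 3), tie = "assign_high"), c(0L, 1L, 1L))
  # all-equal trajectory: everything ties, nothing retained
  expect_length(dichotomize(rep(2, 5)), 0)
  expect_equal(dichotomize(c(0, 1, 1), rule = "as-is"), c(0L, 1L, 1L))
  expect_error(dichotomize(c(0.2, 1), rule = "as-is"), "binary")
})

test_that("run counting matches the block definition and its symmetries", {
  expect_equal(count_runs(c(0, 0, 1, 1, 1)), 2L)
  expect_equal(count_runs(c(0, 1, 0, 1)), 4L)
  expect_equal(count_runs(integer(0)), 0L)
  expect_equal(count_runs(1L), 1L)
  set.seed(10)
  for (i in 1:30) {
    s <- rand_binary(sample(1:40, 1))
    expect_equal(count_runs(rev(s)), count_runs(s))     # reversal
    expect_equal(count_runs(1L - s), count_runs(s))     # relabel 0 <-> 1
  }
})

test_that("pooled runs sums retained records and ignores short ones", {
  p <- panel(list(c(0L, 0L, 1L), c(1L, 0L, 1L)), kind = "binary")
  expect_equal(pooled_runs(p), 5L)
  p2 <- panel(list(c(0L, 0L, 1L), c(1L, 0L)), kind = "binary")
  expect_equal(pooled_runs(p2), 2L)   # the length-2 record contributes nothing
  p3 <- panel(list(c(1L, 0L), c(0L, 1L)), kind = "binary")
  expect_error(pooled_runs(p3), "min_len")
  # invariant under unit ordering
  p_rev <- panel(rev(p$records), kind = "binary")
  expect_equal(pooled_runs(p_rev), pooled_runs(p))
})

test_that("permutation test is reproducible and reports valid p-values", {
  pan <- mixture_simulate(20, 25, make_rng(61))
  r1 <- permutation_runs_test(pan, n_perm = 400, rng = make_rng(62),
                              keep_perm_sums = TRUE)
  r2 <- permutation_runs_test(pan, n_perm = 400, rng = make_rng(62),
                              keep_perm_sums = TRUE)
  expect_identical(r1$perm_sums, r2$perm_sums)
  expect_gt(r1$p_two_sided, 0)
  expect_lte(r1$p_two_sided, 1)
  expect_equal(r1$observed_runs, pooled_runs(pan))
  # chunking is a memory knob only
  r3 <- permutation_runs_test(pan, n_perm = 400, rng = make_rng(62),
                              keep_perm_sums = TRUE, chunk_size = 37)
  expect_identical(r1$perm_sums, r3$perm_sums)
})

test_that("degenerate constant panels report a bound, not a p-value", {
  pan <- panel(list(rep(0L, 6), rep(0L, 5)), kind = "binary")
  r <- permutation_runs_test(pan, n_perm = 200, rng = make_rng(63))
  expect_true(r$p_is_bound)
  expect_equal(r$p_two_sided, 2 / 200)
})

test_that("urn-generated panels pass the runs test: the urn is exchangeable", {
  # conditional on its counts, every ordering of an urn sequence is equally
  # likely (the draws are exchangeable), so the within-unit shuffle null
  # holds exactly and the test must NOT flag urn panels: reinforcement on
  # the cumulative average leaves no streak signature
  pvals <- vapply(1:30, function(i) {
    pan <- polya_simulate(30, 30, make_rng(600 + i))
    permutation_runs_test(pan, n_perm = 200, rng = make_rng(700 + i))$p_two_sided
  }, 0)
  expect_gt(mean(pvals > 0.05), 0.8)
  expect_gt(median(pvals), 0.2)
})

test_that("exchangeable mixture panels are not flagged", {
  pvals <- vapply(1:20, function(i) {
    pan <- mixture_simulate(20, 30, make_rng(800 + i))
    permutation_runs_test(pan, n_perm = 200, rng = make_rng(900 + i))$p_two_sided
  }, 0)
  expect_gt(mean(pvals > 0.01), 0.8)
})

test_that("residual-variance profile tracks the predicted decay on twin data", {
  t <- twin_params(0, 1, 5)
  pan <- q_twin_simulate(t, 4000, 8, make_rng(66))
  prof <- conditional_variance_profile(pan, t)
  expect_equal(prof$n, 1:7)
  expect_true(all(abs(prof$observed_var / prof$predicted_var - 1) < 0.15))
  # definition at n = 1: sample variance of Y2 - (c a + Y1)/(1 + c)
  y1 <- vapply(pan$records, `[`, 0, 1)
  y2 <- vapply(pan$records, `[`, 0, 2)
  expect_equal(prof$observed_var[1], var(y2 - (5 * 0 + y1) / (1 + 5)),
               tolerance = 1e-12)
})

test_that("flat-variance data contradict the predicted decay", {
  # i.i.d. observations with constant variance: the one-step residual
  # variance does not fall at the predicted rate
  t <- twin_params(0, 1, 1)
  iid <- panel(lapply(1:4000, function(i) rnorm(8, 0, sqrt(2))),
               kind = "real")
  prof <- conditional_variance_profile(iid, t)
  expect_true(all(prof$observed_var > prof$predicted_var * 1.2))
})
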