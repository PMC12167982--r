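test_that("likelihood equality check passes for twins, fails when perturbed", {
  seqs <- all_bin_seqs(8)
  rep_polya <- likelihood_equality_check(polya_model(), polya_mixture_model(),
                                         seqs, rel_tol = 1e-12)
  expect_true(rep_polya$pass)

  q <- q_params(0, 0.2, 1)
  t <- map_q_to_twin(q)
  set.seed(9)
  trajs <- lapply(1:100, function(i) rnorm(sample(1:50, 1), 0, 1.5))
  expect_true(likelihood_equality_check(q_model(q), q_twin_model(t),
                                        trajs)$pass)
  t_bad <- twin_params(t$a, t$b, t$c + 0.5)
  expect_false(likelihood_equality_check(q_model(q), q_twin_model(t_bad),
                                         trajs)$pass)

  p <- contact_params()
  ev <- contact_twin_simulate(p, 10, 25, make_rng(41))
  expect_true(likelihood_equality_check(snm_model(p), contact_twin_model(p),
                                        ev$records)$pass)
  p_bad <- contact_params(alpha = 1.3)
  expect_false(likelihood_equality_check(snm_model(p),
                                         contact_twin_model(p_bad),
                                         ev$records)$pass)
  # kind mismatch is an error, not a failed report
  expect_error(likelihood_equality_check(polya_model(), q_model(q), seqs),
               "kind")
})

test_that("marginal comparison accepts twins and detects inflated noise", {
  q <- q_params(0, 0.2, 1)
  t <- map_q_to_twin(q)
  n <- 20000
  pa <- q_simulate(q, n, 10, make_rng(43))
  pb <- q_twin_simulate(t, n, 10, make_rng(44))
  expect_true(marginal_compare(pa, pb, indices = 1:10)$pass)
  # same model against itself
  pc <- q_simulate(q, n, 10, make_rng(45))
  expect_true(marginal_compare(pa, pc, indices = 1:10)$pass)
  # doubling b inflates every marginal variance: detected
  t_bad <- twin_params(t$a, 2 * t$b, t$c)
  pd <- q_twin_simulate(t_bad, n, 10, make_rng(46))
  expect_false(marginal_compare(pa, pd, indices = 1:10)$pass)
  expect_error(marginal_compare(pa, pb, indices = integer(0)), "empty")
})

test_that("cross-moment comparison matches theory and flags independence", {
  q <- q_params(0, 0.2, 1)
  t <- map_q_to_twin(q)
  n <- 20000
  pa <- q_simulate(q, n, 5, make_rng(47))
  pb <- q_twin_simulate(t, n, 5, make_rng(48))
  expect_true(cross_moment_compare(pa, pb)$pass)
  expect_true(cross_moment_compare(
    pb, NULL, moments_b = q_joint_moments(q, 5))$pass)
  # i.i.d. N(a, b + b/c) has the right marginals but zero covariance
  iid <- panel(lapply(1:n, function(i) rnorm(5, 0, sqrt(1.2))), kind = "real")
  expect_false(cross_moment_compare(pb, iid)$pass)
  # ragged panels are rejected for this check
  ragged <- panel(list(rnorm(3), rnorm(5)), kind = "real")
  expect_error(cross_moment_compare(ragged, iid), "rectangular")
})

test_that("hybrid mixtures preserve the law when components share it", {
  pol <- polya_model(); mix <- polya_mixture_model()
  seqs <- all_bin_seqs(7)
  # q = 1 reduces to the first component
  m1 <- mixture_model(pol, mix, 1)
  expect_true(likelihood_equality_check(m1, pol, seqs, rel_tol = 1e-12)$pass)
  # mixing a model with itself changes nothing
  m_self <- mixture_model(pol, pol, 0.5)
  expect_true(likelihood_equality_check(m_self, pol, seqs,
                                        rel_tol = 1e-12)$pass)
  # mixing the two twins at any q is indistinguishable from either
  for (qq in c(0, 0.3, 0.8)) {
    mq <- mixture_model(pol, mix, qq)
    expect_true(likelihood_equality_check(mq, pol, seqs,
                                          rel_tol = 1e-12)$pass)
  }
  expect_error(mixture_model(pol, mix, 1.2), "probability")
  expect_error(mixture_model(pol, q_model(q_params(0, 1, 1)), 0.5), "kinds")
  # simulation respects the mixing probability and stays reproducible
  g <- mixture_model(q_model(q_params(0, 0.2, 1)),
                     q_twin_model(twin_params(0, 1, 5)), 0.5)
  pa <- simulate_panel(g, 12, 6, make_rng(51))
  pb <- simulate_panel(g, 12, 6, make_rng(51))
  expect_true(panel_equal(pa, pb))
})

test_that("bundled pair reports pass end to end", {
  rep_g <- twin_pair_report("gaussian", seed = 3, n_units = 8000)
  expect_true(rep_g$pass)
  rep_p <- twin_pair_report("polya", seed = 3, n_units = 8000)
  expect_true(rep_p$pass)
  rep_c <- twin_pair_report("contact", seed = 3, n_units = 4000)
  expect_true(rep_c$pass)
  expect_true(jsonlite::validate(report_to_json(rep_g)))
})
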