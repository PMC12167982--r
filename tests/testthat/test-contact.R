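cp_default <- function() contact_params(alpha = 1, pi0 = 0.25,
                                         scale = 0.25, rho = 0.5)

test_that("twin intensity matches its closed form on an empty history", {
  p <- cp_default()
  for (t in c(0.5, 2, 7))
    expect_equal(contact_twin_intensity(p, numeric(0), t),
                 0.25 * 1 / (0.25 * t + 1), tolerance = 1e-14)
})

test_that("intensity denominator telescopes to exposure at event times", {
  p <- contact_params(alpha = 1.4, pi0 = 0.3, scale = 0.2, rho = 0.7)
  set.seed(5)
  for (rep in 1:20) {
    times <- sort(runif(sample(1:8, 1), 0, 10))
    m <- length(times)
    pis <- vapply(0:m, function(j) if (j == 0) 0.3 else 0.2 * j^0.7, 0)
    A_m <- 1.4 + sum(pis[seq_len(m)] * diff(c(0, times)))
    # lambda at t -> t_m+ equals pi_m (m + alpha) / A_m
    lam <- contact_twin_intensity(p, times, times[m] + 1e-12)
    expect_equal(lam, pis[m + 1] * (m + 1.4) / A_m, tolerance = 1e-6)
  }
})

test_that("intensity decays between events and jumps up at an event", {
  p <- cp_default()
  hist <- c(1, 2.5)
  tt <- seq(2.6, 8, length.out = 50)
  lam <- contact_twin_intensity(p, hist, tt)
  expect_true(all(diff(lam) < 0))
  # just after a third event the rate exceeds the rate just before it
  lam_before <- contact_twin_intensity(p, hist, 4)
  lam_after <- contact_twin_intensity(p, c(hist, 4), 4 + 1e-9)
  expect_gt(lam_after, lam_before)
  # recency: same count, later events => higher current rate
  lam_recent <- contact_twin_intensity(p, c(3, 3.9), 4)
  lam_old <- contact_twin_intensity(p, c(0.5, 1), 4)
  expect_gt(lam_recent, lam_old)
})

test_that("time-change inverse is the inverse of the integrated intensity", {
  p <- cp_default()
  # k = 0: s_1(z) = (e^z - 1) / 0.25 * alpha with alpha = 1 => 4 (e^z - 1)
  z <- 0.7
  tau <- 1 * expm1(z / (0 + 1)) / 0.25
  expect_equal(tau, 4 * (exp(0.7) - 1))
  expect_equal(oracle_compensator(p, numeric(0), tau), z, tolerance = 1e-8)
  # randomized histories: Lambda(s(z)) = z
  set.seed(6)
  for (rep in 1:20) {
    times <- sort(runif(sample(1:6, 1), 0, 8))
    k <- length(times)
    pis <- vapply(0:k, function(j) if (j == 0) 0.25 else 0.25 * sqrt(j), 0)
    A_k <- 1 + sum(pis[seq_len(k)] * diff(c(0, times)))
    z <- rexp(1)
    tau <- A_k * expm1(z / (k + 1)) / pis[k + 1]
    expect_equal(oracle_compensator(p, times, times[k] + tau), z,
                 tolerance = 1e-7)
  }
})

test_that("frailty and twin likelihoods agree exactly and with quadrature", {
  p <- cp_default()
  pan <- contact_twin_simulate(p, 10, 30, make_rng(31))
  for (r in pan$records) {
    la <- snm_log_lik(p, r)
    lb <- contact_twin_log_lik(p, r)
    expect_equal(la, lb, tolerance = 1e-10)
  }
  # numeric integration over the frailty as a third, independent route
  for (r in pan$records[1:10])
    expect_equal(snm_log_lik(p, r), snm_log_lik_quadrature(p, r),
                 tolerance = 1e-6)
  # empty trajectory: survival of the first event under Gamma mixing
  empty <- event_trajectory(numeric(0), 5)
  expect_equal(snm_log_lik(p, empty), -1 * log(1 + 0.25 * 5 / 1),
               tolerance = 1e-12)
  expect_equal(contact_twin_log_lik(p, empty), -log(1 + 0.25 * 5),
               tolerance = 1e-12)
})

test_that("constant-rate frailty counts are negative binomial", {
  # pi_j constant: Gamma-mixed Poisson => NB(size alpha, mean pi t)
  alpha <- 2; pi_c <- 0.5; t_end <- 6
  p <- contact_params(alpha = alpha, pi_fun = function(j) rep(pi_c, length(j)))
  n_units <- 20000
  pan <- snm_simulate(p, t_end, n_units, make_rng(33))
  counts <- vapply(pan$records, function(r) length(r$times), 0L)
  kmax <- max(counts)
  expected <- dnbinom(0:kmax, size = alpha,
                      prob = alpha / (alpha + pi_c * t_end))
  expected[kmax + 1] <- expected[kmax + 1] +
    pnbinom(kmax, size = alpha, prob = alpha / (alpha + pi_c * t_end),
            lower.tail = FALSE)
  obs <- tabulate(counts + 1, kmax + 1)
  keep <- expected * n_units >= 5
  pval <- chisq.test(c(obs[keep], sum(obs[!keep])),
                     p = c(expected[keep], sum(expected[!keep])))$p.value
  expect_gt(pval, 0.01)
})

test_that("frailty and twin count distributions are indistinguishable", {
  p <- cp_default()
  cd_a <- count_distribution(p, c(5, 10), 4000, make_rng(35), which = "snm")
  cd_b <- count_distribution(p, c(5, 10), 4000, make_rng(36), which = "twin")
  for (j in 1:2) {
    expect_equal(sum(cd_a$pmf[[j]]), 1, tolerance = 1e-12)
    expect_equal(sum(cd_b$pmf[[j]]), 1, tolerance = 1e-12)
  }
  ks <- suppressWarnings(ks.test(cd_a$counts[, 2], cd_b$counts[, 2]))$p.value
  expect_gt(ks, 0.01)
})

test_that("event input validation rejects bad trajectories", {
  p <- cp_default()
  expect_error(snm_simulate(p, -1, 3, make_rng(0)), "positive")
  expect_error(event_trajectory(c(2, 2), 5), "strictly increasing")
  expect_error(contact_twin_intensity(p, c(3, 1), 4), "increasing")
  expect_error(contact_twin_intensity(p, c(1, 3), 2), "exceed")
})
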