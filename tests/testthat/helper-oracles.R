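# Independent oracles used across the suite.  These deliberately avoid the
# package's own likelihood code paths.

# Posterior predictive of the Gaussian latent-factor model by conjugate
# updating: prior T ~ N(mu_T, var_T), observations y | T ~ N(T, var_X).
oracle_posterior_predictive <- function(q, history) {
  n <- length(history)
  post_prec <- 1 / q$var_T + n / q$var_X
  post_var <- 1 / post_prec
  post_mean <- post_var * (q$mu_T / q$var_T + sum(history) / q$var_X)
  c(mean = post_mean, variance = post_var + q$var_X)
}

# Beta-binomial count probability by brute-force numeric integration over
# the latent success probability.
oracle_count_prob <- function(n, k) {
  stats::integrate(function(p) choose(n, k) * p^k * (1 - p)^(n - k),
                   0, 1, rel.tol = 1e-12)$value
}

# Numeric integral of the twin conditional intensity from the last event
# (or 0) to t, by quadrature on the intensity itself.
oracle_compensator <- function(p, history, t) {
  lo <- if (length(history)) max(history) else 0
  stats::integrate(function(u) contact_twin_intensity(p, history, u),
                   lo, t, rel.tol = 1e-10)$value
}

# All 2^n binary sequences of length n as a list of integer vectors.
all_bin_seqs <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

# Random binary sequence of given length.
rand_binary <- function(n) sample(c(0L, 1L), n, replace = TRUE)

panel_lengths_of <- function(p) lengths(p$records)

first_event_times <- function(pan) {
  vapply(pan$records,
         function(r) if (length(r$times)) r$times[1] else NA_real_, 0)
}
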