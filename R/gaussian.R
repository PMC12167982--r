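#' Parameters of the Gaussian latent-factor (Q-)model and of its twin
#'
#' On the log scale, the Q-model of citation careers writes the impact of a
#' scientist's n-th paper as `Y[n] = T + X[n]`, with a fixed latent talent
#' `T ~ N(mu_T, var_T)` per scientist and i.i.d. luck `X[n] ~ N(0, var_X)`.
#' Its reinforcement twin has no latent variable: given the unit's history,
#' the next value is normal with mean `(c*a + sum(history)) / (n + c)` and
#' variance `b * (1 + 1/(n + c))`.
#'
#' `q_params()` and `twin_params()` validate the two parameterizations;
#' `map_q_to_twin()` and `map_twin_to_q()` convert between them via
#' `a = mu_T`, `b = var_X`, `c = var_X / var_T` (an exact bijection).
#'
#' @param mu_T Mean of the latent factor `T = log Q`.
#' @param var_T,var_X Positive variances of `T` and of the noise `X[n]`.
#' @return `q_params()`: an object of class `q_params`.
#' @examples
#' map_q_to_twin(q_params(0, 0.2, 1))   # a=0, b=1, c=5
#' @export
q_params <- function(mu_T, var_T, var_X) {
  stopifnot(is.finite(mu_T), is.finite(var_T), is.finite(var_X))
  if (var_T <= 0 || var_X <= 0)
    stop("'var_T' and 'var_X' must be positive", call. = FALSE)
  structure(list(mu_T = as.numeric(mu_T), var_T = as.numeric(var_T),
                 var_X = as.numeric(var_X)), class = "q_params")
}

#' @rdname q_params
#' @param a Long-run mean of the twin recursion.
#' @param b Positive limiting innovation variance.
#' @param c Positive prior weight on `a` (pseudo-observations).
#' @return `twin_params()`: an object of class `twin_params`.
#' @export
twin_params <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (b <= 0 || c <= 0) stop("'b' and 'c' must be positive", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            class = "twin_params")
}

#' @rdname q_params
#' @param q A `q_params` object.
#' @export
map_q_to_twin <- function(q) {
  q <- as_q_params(q)
  twin_params(a = q$mu_T, b = q$var_X, c = q$var_X / q$var_T)
}

#' @rdname q_params
#' @param t A `twin_params` object.
#' @export
map_twin_to_q <- function(t) {
  t <- as_twin_params(t)
  q_params(mu_T = t$a, var_T = t$b / t$c, var_X = t$b)
}

as_q_params <- function(q) {
  if (inherits(q, "q_params")) return(q)
  if (is.numeric(q) && length(q) == 3) return(q_params(q[1], q[2], q[3]))
  stop("expected q_params(mu_T, var_T, var_X)", call. = FALSE)
}

as_twin_params <- function(t) {
  if (inherits(t, "twin_params")) return(t)
  if (is.numeric(t) && length(t) == 3) return(twin_params(t[1], t[2], t[3]))
  stop("expected twin_params(a, b, c)", call. = FALSE)
}

#' Simulate the Q-model: latent factor plus i.i.d. noise
#'
#' Per unit, draws `T ~ N(mu_T, var_T)` once, then `Y[n] = T + X[n]` with
#' `X[n]` i.i.d. `N(0, var_X)`; `T` is discarded (latent).
#'
#' @param q A [q_params()] object.
#' @param n_units Number of units.
#' @param n_obs Observations per unit (>= 1).
#' @param rng A [make_rng()] handle or integer seed.
#' @return A real-valued [panel()].
#' @export
q_simulate <- function(q, n_units, n_obs, rng) {
  q <- as_q_params(q)
  stopifnot(n_obs >= 1, n_units >= 1)
  recs <- map_units(rng, n_units, function(i) {
    T_i <- stats::rnorm(1, q$mu_T, sqrt(q$var_T))
    T_i + stats::rnorm(n_obs, 0, sqrt(q$var_X))
  })
  panel(recs, kind = "real")
}

#' One-step-ahead law of the reinforcement twin
#'
#' Given a history of length `n`, the next observation is normal with mean
#' `(c*a + sum(history)) / (n + c)` and variance `b * (1 + 1/(n + c))`.
#' With an empty history this is the unconditional first-observation law
#' `N(a, b + b/c)`.  The same pair is, by conjugate-normal updating, the
#' posterior predictive of the Q-model given the history — every past
#' observation is equally informative about the latent factor, which is why
#' the mean weights all past values equally and the variance decreases to
#' `b` at the specific rate `1/(n + c)`.
#'
#' @param t A [twin_params()] object.
#' @param history Numeric vector of past values (may be empty).
#' @return Named numeric vector `c(mean, variance)`.
#' @export
q_twin_conditional <- function(t, history = numeric()) {
  t <- as_twin_params(t)
  n <- length(history)
  c(mean = (t$c * t$a + sum(history)) / (n + t$c),
    variance = t$b * (1 + 1 / (n + t$c)))
}

#' Simulate the reinforcement twin of the Q-model
#'
#' Sequential draws from [q_twin_conditional()]; no latent variable is used
#' anywhere — each value is endogenously determined by the unit's past
#' values plus noise.
#'
#' @inheritParams q_simulate
#' @param t A [twin_params()] object.
#' @export
q_twin_simulate <- function(t, n_units, n_obs, rng) {
  t <- as_twin_params(t)
  stopifnot(n_obs >= 1, n_units >= 1)
  recs <- map_units(rng, n_units, function(i) {
    y <- numeric(n_obs)
    s <- 0
    for (n in seq_len(n_obs)) {
      mu <- (t$c * t$a + s) / (n - 1 + t$c)
      sd <- sqrt(t$b * (1 + 1 / (n - 1 + t$c)))
      y[n] <- stats::rnorm(1, mu, sd)
      s <- s + y[n]
    }
    y
  })
  panel(recs, kind = "real")
}

#' Closed-form joint moments of the Q-model
#'
#' Mean vector `mu_T * 1` and compound-symmetric covariance
#' `var_T * J + var_X * I`: the shared latent factor contributes `var_T` to
#' every cross-time covariance.
#'
#' @inheritParams q_simulate
#' @param n_obs Trajectory length.
#' @return List with components `mean` (length `n_obs`) and `cov`
#'   (`n_obs x n_obs`).
#' @export
q_joint_moments <- function(q, n_obs) {
  q <- as_q_params(q)
  stopifnot(n_obs >= 1)
  list(mean = rep(q$mu_T, n_obs),
       cov = matrix(q$var_T, n_obs, n_obs) + diag(q$var_X, n_obs))
}

#' Exact log-densities of a trajectory under the Q-model and under its twin
#'
#' `q_log_pdf()` evaluates the multivariate-normal density with the
#' closed-form joint moments; `q_twin_log_pdf()` sums the chain of
#' conditional normal log-densities of the twin recursion.  Under the
#' parameter map the two are equal for every trajectory — the twins share
#' one law — but the code paths are fully independent.
#'
#' @inheritParams q_simulate
#' @param traj Non-empty finite numeric vector.
#' @return Log density.
#' @export
q_log_pdf <- function(q, traj) {
  q <- as_q_params(q)
  traj <- as.numeric(traj)
  if (length(traj) == 0) stop("'traj' must be non-empty", call. = FALSE)
  mom <- q_joint_moments(q, length(traj))
  dmvnorm_log(traj, mom$mean, mom$cov)
}

#' @rdname q_log_pdf
#' @param t A [twin_params()] object.
#' @export
q_twin_log_pdf <- function(t, traj) {
  t <- as_twin_params(t)
  traj <- as.numeric(traj)
  n <- length(traj)
  if (n == 0) stop("'traj' must be non-empty", call. = FALSE)
  idx <- seq_len(n)
  prior_sum <- c(0, cumsum(traj))[idx]
  mu <- (t$c * t$a + prior_sum) / (idx - 1 + t$c)
  v <- t$b * (1 + 1 / (idx - 1 + t$c))
  sum(stats::dnorm(traj, mu, sqrt(v), log = TRUE))
}

# MVN log density via Cholesky.
dmvnorm_log <- function(y, mean, sigma) {
  L <- chol(sigma)
  z <- backsolve(L, y - mean, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' One step of the settled-dispositions twin recursion
#'
#' The attitude-panel special case (`a = 0`, `b = 1`, `c = 1`) of the twin
#' recursion, written as an explicit update: with `n = length(history) + 1`,
#' `y_n = ((n-1)/n) * mean(history) + sqrt(1 + 1/n) * v`.  The innovation
#' `v` (standard normal in the model) is supplied by the caller so the
#' recursion is testable deterministically; the shrinking noise coefficient
#' `sqrt(1 + 1/n)` is forced by consistency with the general twin variance
#' at `b = c = 1`.
#'
#' @param history Numeric vector of past values (may be empty).
#' @param v Period innovation.
#' @return The next value `y_n`.
#' @export
sdm_twin_step <- function(history, v) {
  n <- length(history) + 1
  m <- if (n == 1) 0 else mean(history)
  (n - 1) / n * m + sqrt(1 + 1 / n) * v
}

#' Generative-model wrappers for the Gaussian twin pair
#'
#' @param q A [q_params()] object.
#' @return A [generative_model()] of kind `"real"`.
#' @export
q_model <- function(q) {
  q <- as_q_params(q)
  generative_model(
    name = "q_model", kind = "real",
    simulate = function(n_units, size, rng) q_simulate(q, n_units, size, rng),
    log_lik = function(traj) q_log_pdf(q, traj))
}

#' @rdname q_model
#' @param t A [twin_params()] object.
#' @export
q_twin_model <- function(t) {
  t <- as_twin_params(t)
  generative_model(
    name = "q_twin", kind = "real",
    simulate = function(n_units, size, rng)
      q_twin_simulate(t, n_units, size, rng),
    log_lik = function(traj) q_twin_log_pdf(t, traj))
}
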