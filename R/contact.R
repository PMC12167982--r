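#' Parameters of the Gamma-frailty contact process and of its twin
#'
#' The heterogeneity side is a mixed pure-birth process for cumulative
#' numbers of (e.g. sexual) partners: a unit-specific frailty
#' `kappa ~ Gamma(shape = alpha, scale = 1/alpha)` (mean 1, variance
#' `1/alpha`) is drawn once, and conditional on `kappa` the process moves
#' from state `j` to `j + 1` at rate `kappa * pi_j`.  The reinforcement
#' twin is a self-exciting point process whose conditional intensity after
#' `m` events at times `t_1 < ... < t_m` is
#' \deqn{\lambda_{m+1}(t) = \frac{\pi_m (m + \alpha)}{\pi_m t -
#'   \sum_{j=1}^m (\pi_j - \pi_{j-1}) t_j + \alpha},}
#' which depends on the history alone — no frailty — yet generates the
#' identical joint law.
#'
#' The default state-rate rule is the power family `pi_0` free and
#' `pi_j = scale * j^rho` for `j >= 1`; an arbitrary rule can be supplied
#' as `pi_fun(j)` returning a positive rate for each state `j = 0, 1, ...`.
#'
#' @param alpha Positive frailty shape; the frailty has mean 1 and variance
#'   `1/alpha`, so large `alpha` means little heterogeneity.
#' @param pi0 Rate out of state 0 (default 0.25).
#' @param scale,rho Power-family parameters for `j >= 1` (defaults 0.25 and
#'   0.5: sublinear reinforcement).
#' @param pi_fun Optional vectorized function `j -> pi_j` overriding the
#'   power family.
#' @return Object of class `contact_params`.
#' @export
contact_params <- function(alpha = 1, pi0 = 0.25, scale = 0.25, rho = 0.5,
                           pi_fun = NULL) {
  stopifnot(is.finite(alpha), alpha > 0)
  if (is.null(pi_fun)) {
    stopifnot(pi0 > 0, scale > 0)
    pi_fun <- function(j) ifelse(j == 0, pi0, scale * j^rho)
  }
  structure(list(alpha = as.numeric(alpha), pi_fun = pi_fun,
                 pi0 = pi0, scale = scale, rho = rho),
            class = "contact_params")
}

# pi_0 .. pi_m as a vector, validated positive.
pi_values <- function(p, m) {
  v <- as.numeric(p$pi_fun(0:m))
  if (anyNA(v) || any(v <= 0))
    stop("pi rule must return positive rates", call. = FALSE)
  v
}

# single pi_j, validated positive.
pi_value <- function(p, j) {
  v <- as.numeric(p$pi_fun(j))
  if (is.na(v) || v <= 0)
    stop("pi rule must return positive rates", call. = FALSE)
  v
}

as_contact_params <- function(p) {
  if (inherits(p, "contact_params")) return(p)
  stop("expected a contact_params object", call. = FALSE)
}

#' Simulate the frailty contact process
#'
#' Per unit, draws `kappa` from Gamma(shape `alpha`, scale `1/alpha`), then
#' successive waiting times as independent exponentials with rates
#' `kappa * pi_0, kappa * pi_1, ...`; events beyond the horizon are
#' discarded and `kappa` itself is discarded (latent).
#'
#' @param p A [contact_params()] object.
#' @param horizon Positive observation end time.
#' @param n_units Number of units.
#' @param rng A [make_rng()] handle or integer seed.
#' @param max_events Safety cap on events per unit.
#' @return An event [panel()].
#' @export
snm_simulate <- function(p, horizon, n_units, rng, max_events = 100000L) {
  p <- as_contact_params(p)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("'horizon' must be positive", call. = FALSE)
  recs <- map_units(rng, n_units, function(i) {
    kappa <- stats::rgamma(1, shape = p$alpha, scale = 1 / p$alpha)
    times <- numeric(0)
    t_cur <- 0
    j <- 0
    while (t_cur <= horizon && j < max_events) {
      tau <- stats::rexp(1, rate = kappa * pi_value(p, j))
      t_cur <- t_cur + tau
      if (t_cur > horizon) break
      times <- c(times, t_cur)
      j <- j + 1
    }
    if (j >= max_events)
      stop("event cap reached; increase 'max_events' or shorten 'horizon'",
           call. = FALSE)
    event_trajectory(times, horizon)
  })
  panel(recs, kind = "event")
}

#' Conditional intensity of the reinforcement twin
#'
#' Evaluates the twin's instantaneous event rate at time `t` given the
#' event history, straight from the history-weighted form: with `m` past
#' events, `pi_m * (m + alpha) / (pi_m * t - sum_j (pi_j - pi_{j-1}) t_j +
#' alpha)`.  The denominator is provably positive along any history the
#' twin itself can generate; a non-positive value indicates an invalid
#' history and raises an error.  For `pi` nondecreasing the intensity
#' decays between events and jumps up at each event: the more recent the
#' events, the higher the current rate.
#'
#' @param p A [contact_params()] object.
#' @param history Numeric vector of past event times (may be empty), or an
#'   `event_trajectory`.
#' @param t Evaluation time(s), each `> max(history)`.
#' @return Intensity value(s).
#' @export
contact_twin_intensity <- function(p, history, t) {
  p <- as_contact_params(p)
  if (inherits(history, "event_trajectory")) history <- history$times
  history <- as.numeric(history)
  m <- length(history)
  if (m && is.unsorted(history, strictly = TRUE))
    stop("'history' must be strictly increasing", call. = FALSE)
  if (any(t <= if (m) history[m] else 0))
    stop("'t' must exceed the last event time", call. = FALSE)
  pis <- pi_values(p, m)                     # pi_0 .. pi_m
  hist_term <- if (m) sum(diff(c(pis[1], pis[-1])) * history) else 0
  denom <- pis[m + 1] * t - hist_term + p$alpha
  if (any(denom <= 0))
    stop("internal invariant violated: non-positive intensity denominator",
         call. = FALSE)
  pis[m + 1] * (m + p$alpha) / denom
}

# A_k = alpha + sum_{j=0}^{k-1} pi_j * (t_{j+1} - t_j), the twin intensity
# denominator evaluated at t_k (telescoped form used by the simulator).
compensator_base <- function(p, times) {
  m <- length(times)
  pis <- pi_values(p, max(m - 1, 0))
  p$alpha + if (m) sum(pis[seq_len(m)] * diff(c(0, times))) else 0
}

#' Simulate the reinforcement twin by the time-change method
#'
#' Draws i.i.d. unit-rate exponentials `z_1, z_2, ...` and maps each
#' through the inverse integrated intensity: after `k` events the next
#' waiting time is `tau = A_k * (exp(z / (k + alpha)) - 1) / pi_k`, where
#' `A_k = alpha + sum_{j<k} pi_j * (t_{j+1} - t_j)` accumulates the
#' compensator along the trajectory.  Stops at the horizon.
#'
#' @inheritParams snm_simulate
#' @export
contact_twin_simulate <- function(p, horizon, n_units, rng,
                                  max_events = 100000L) {
  p <- as_contact_params(p)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("'horizon' must be positive", call. = FALSE)
  recs <- map_units(rng, n_units, function(i) {
    times <- numeric(0)
    t_cur <- 0
    A <- p$alpha
    k <- 0
    while (t_cur <= horizon && k < max_events) {
      stopifnot(A > 0)  # invariant: compensator base stays positive
      z <- stats::rexp(1)
      pik <- pi_value(p, k)
      tau <- A * expm1(z / (k + p$alpha)) / pik
      t_new <- t_cur + tau
      if (t_new > horizon) break
      times <- c(times, t_new)
      A <- A + pik * tau
      t_cur <- t_new
      k <- k + 1
    }
    if (k >= max_events)
      stop("event cap reached; increase 'max_events' or shorten 'horizon'",
           call. = FALSE)
    event_trajectory(times, horizon)
  })
  panel(recs, kind = "event")
}

#' Simulate the twin's next event by Ogata thinning
#'
#' An independent route to the same law, used to validate the time-change
#' simulator: between events the twin intensity is decreasing, so the
#' intensity at the current time bounds it from above and rejection
#' sampling applies.  Returns the time of the first event after an empty
#' history (or `Inf` beyond `t_max`).
#'
#' @param p A [contact_params()] object.
#' @param n Number of independent first-event draws.
#' @param rng A [make_rng()] handle or integer seed.
#' @param t_max Give up beyond this time (returned as `Inf`).
#' @return Numeric vector of `n` first-event times.
#' @export
contact_twin_first_event_thinning <- function(p, n, rng, t_max = 1e6) {
  p <- as_contact_params(p)
  unlist(map_units(rng, n, function(i) {
    t_cur <- 0
    repeat {
      lam_bound <- contact_twin_intensity(p, numeric(0), t_cur + 1e-12)
      t_cur <- t_cur + stats::rexp(1, rate = lam_bound)
      if (t_cur > t_max) return(Inf)
      if (stats::runif(1) <=
          contact_twin_intensity(p, numeric(0), t_cur) / lam_bound)
        return(t_cur)
    }
  }))
}

#' Exact log-likelihoods of an event trajectory under the two models
#'
#' `snm_log_lik()` integrates the frailty out of the conditional
#' exponential-waiting-time density analytically: with `m` events, waiting
#' times `tau_j` and censored tail `T - t_m`,
#' \deqn{\log L = \sum_{j=0}^{m-1}\log\pi_j + \alpha\log\alpha -
#'   \log\Gamma(\alpha) + \log\Gamma(m+\alpha) - (m+\alpha)\log D,}
#' where `D = alpha + sum_j pi_j tau_{j+1} + pi_m (T - t_m)`.
#' `contact_twin_log_lik()` instead uses the standard point-process
#' likelihood `sum_i log lambda(t_i) - int_0^T lambda`, with the integral
#' in closed form interval by interval, all terms evaluated through
#' [contact_twin_intensity()]'s history-weighted denominator.  The two
#' agree exactly for every trajectory; [snm_log_lik_quadrature()] provides
#' a third, numeric route for validation.
#'
#' @param p A [contact_params()] object.
#' @param traj An [event_trajectory()] (times + horizon).
#' @return Log-likelihood (density of event times, right-censored at the
#'   horizon).
#' @export
snm_log_lik <- function(p, traj) {
  p <- as_contact_params(p)
  traj <- as_event_traj(traj)
  times <- traj$times
  m <- length(times)
  pis <- pi_values(p, m)
  D <- p$alpha +
    (if (m) sum(pis[seq_len(m)] * diff(c(0, times))) else 0) +
    pis[m + 1] * (traj$horizon - if (m) times[m] else 0)
  sum(log(pis[seq_len(m)])) + p$alpha * log(p$alpha) - lgamma(p$alpha) +
    lgamma(m + p$alpha) - (m + p$alpha) * log(D)
}

#' @rdname snm_log_lik
#' @export
contact_twin_log_lik <- function(p, traj) {
  p <- as_contact_params(p)
  traj <- as_event_traj(traj)
  times <- traj$times
  m <- length(times)
  ll <- 0
  # event terms: intensity just at each event, given the strict past
  for (i in seq_len(m))
    ll <- ll + log(contact_twin_intensity(p, times[seq_len(i - 1)], times[i]))
  # compensator: integral of the intensity over each inter-event interval
  pis <- pi_values(p, m)
  bounds <- c(0, times, traj$horizon)
  for (k in 0:m) {
    lo <- bounds[k + 1]; hi <- bounds[k + 2]
    if (hi <= lo) next
    hist_term <- if (k) sum(diff(c(pis[1], pis[seq_len(k) + 1])) *
                              times[seq_len(k)]) else 0
    d_lo <- pis[k + 1] * lo - hist_term + p$alpha
    d_hi <- pis[k + 1] * hi - hist_term + p$alpha
    ll <- ll - (k + p$alpha) * (log(d_hi) - log(d_lo))
  }
  ll
}

#' @rdname snm_log_lik
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @export
snm_log_lik_quadrature <- function(p, traj, rel_tol = 1e-10) {
  p <- as_contact_params(p)
  traj <- as_event_traj(traj)
  times <- traj$times
  m <- length(times)
  pis <- pi_values(p, m)
  S <- (if (m) sum(pis[seq_len(m)] * diff(c(0, times))) else 0) +
    pis[m + 1] * (traj$horizon - if (m) times[m] else 0)
  # log f(kappa) = prior + m rate terms + exponential exposure, scaled at mode
  log_f <- function(kappa)
    stats::dgamma(kappa, shape = p$alpha, scale = 1 / p$alpha, log = TRUE) +
      m * log(kappa) + sum(log(pis[seq_len(m)])) - kappa * S
  mode <- (m + p$alpha - 1) / (p$alpha + S)
  scale_at <- log_f(max(mode, 1e-8))
  val <- stats::integrate(function(k) exp(vapply(k, log_f, 0) - scale_at),
                          0, Inf, rel.tol = rel_tol)$value
  scale_at + log(val)
}

as_event_traj <- function(traj) {
  if (inherits(traj, "event_trajectory")) return(traj)
  if (is.list(traj) && !is.null(traj$times) && !is.null(traj$horizon))
    return(event_trajectory(traj$times, traj$horizon))
  stop("expected an event_trajectory (times + horizon)", call. = FALSE)
}

#' Monte-Carlo count distributions at a grid of times
#'
#' Simulates either model and tabulates the empirical distribution of the
#' cumulative event count at each grid time.
#'
#' @inheritParams snm_simulate
#' @param t_grid Increasing times within the horizon.
#' @param which `"snm"` or `"twin"`.
#' @return List with `counts` (units x times matrix) and `pmf` (per-time
#'   list of named probability vectors, each summing to 1).
#' @export
count_distribution <- function(p, t_grid, n_units, rng,
                               which = c("snm", "twin")) {
  which <- match.arg(which)
  t_grid <- as.numeric(t_grid)
  stopifnot(length(t_grid) >= 1, all(t_grid > 0), !is.unsorted(t_grid))
  horizon <- max(t_grid)
  pan <- if (which == "snm") snm_simulate(p, horizon, n_units, rng)
         else contact_twin_simulate(p, horizon, n_units, rng)
  counts <- t(vapply(pan$records, function(r)
    vapply(t_grid, function(tt) sum(r$times <= tt), 0L),
    integer(length(t_grid))))
  counts <- matrix(counts, nrow = n_units)
  pmf <- lapply(seq_along(t_grid), function(j) {
    tab <- table(counts[, j])
    stats::setNames(as.numeric(tab) / n_units, names(tab))
  })
  names(pmf) <- paste0("t=", t_grid)
  list(counts = counts, pmf = pmf)
}

#' Generative-model wrappers for the contact-process twin pair
#'
#' `size` in [simulate_panel()] is interpreted as the horizon.
#'
#' @param p A [contact_params()] object.
#' @return A [generative_model()] of kind `"event"`.
#' @export
snm_model <- function(p) {
  p <- as_contact_params(p)
  generative_model(
    name = "snm_frailty", kind = "event",
    simulate = function(n_units, size, rng) snm_simulate(p, size, n_units, rng),
    log_lik = function(traj) snm_log_lik(p, traj))
}

#' @rdname snm_model
#' @export
contact_twin_model <- function(p) {
  p <- as_contact_params(p)
  generative_model(
    name = "contact_twin", kind = "event",
    simulate = function(n_units, size, rng)
      contact_twin_simulate(p, size, n_units, rng),
    log_lik = function(traj) contact_twin_log_lik(p, traj))
}
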