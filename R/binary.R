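#' Pólya urn reinforcement model and its Bernoulli-mixture twin
#'
#' An urn starts with `n_black` black and `n_red` red balls (1 and 1 by
#' default).  At each step a ball is drawn at random and returned together
#' with another ball of the same colour; `Y[n] = 1` records a black draw.
#' The draw recursion used by the simulator writes the urn as a pure
#' reinforcement rule: `Y[n] = 1` iff `X[n] < (n_black + sum(Y[1..n-1])) /
#' (n_black + n_red + n - 1)` with `X[n]` i.i.d. uniform on `[0, 1]` — for
#' the default urn, `(1 + sum) / (n + 1)`.
#'
#' Its heterogeneity twin first draws a latent success probability
#' `p ~ Beta(n_black, n_red)` (uniform on `[0, 1]` for the default urn) once
#' per unit and then draws i.i.d. Bernoulli(`p`) outcomes.  The two models
#' have identical joint distributions over whole sequences, which
#' [polya_log_prob()] / [mixture_log_prob()] expose exactly.
#'
#' @param n_draws Number of draws per unit (>= 1).
#' @param n_units Number of independent sequences.
#' @param rng A [make_rng()] handle or integer seed.
#' @param n_black,n_red Initial urn composition (positive; default 1 and 1).
#' @return A binary [panel()].
#' @examples
#' p <- polya_simulate(10, 4, make_rng(1))
#' q <- mixture_simulate(10, 4, make_rng(1))
#' polya_log_prob(c(1, 1, 0))    # log(1/12)
#' mixture_log_prob(c(1, 1, 0))  # identical
#' @export
polya_simulate <- function(n_draws, n_units, rng, n_black = 1, n_red = 1) {
  check_draws(n_draws, n_units, n_black, n_red)
  recs <- map_units(rng, n_units, function(i) {
    x <- stats::runif(n_draws)
    y <- integer(n_draws)
    nb <- n_black
    for (n in seq_len(n_draws)) {
      y[n] <- as.integer(x[n] < nb / (n_black + n_red + n - 1))
      nb <- nb + y[n]
    }
    y
  })
  panel(recs, kind = "binary")
}

#' @rdname polya_simulate
#' @export
mixture_simulate <- function(n_draws, n_units, rng, n_black = 1, n_red = 1) {
  check_draws(n_draws, n_units, n_black, n_red)
  recs <- map_units(rng, n_units, function(i) {
    p <- stats::rbeta(1, n_black, n_red)
    as.integer(stats::runif(n_draws) < p)
  })
  panel(recs, kind = "binary")
}

check_draws <- function(n_draws, n_units, n_black, n_red) {
  if (!is.numeric(n_draws) || n_draws < 1)
    stop("'n_draws' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_units) || n_units < 1)
    stop("'n_units' must be a positive integer", call. = FALSE)
  if (n_black <= 0 || n_red <= 0)
    stop("initial urn composition must be positive", call. = FALSE)
}

#' Exact log sequence probabilities of the urn and its mixture twin
#'
#' `polya_log_prob()` multiplies the sequential urn draw probabilities
#' (in log space); `mixture_log_prob()` integrates the Bernoulli likelihood
#' against the Beta latent distribution, `log B(n_black + k, n_red + n - k) -
#' log B(n_black, n_red)` for `k` ones in `n` draws, via log-gamma.  The two
#' agree to machine precision on every sequence; they are computed by
#' entirely different routes, so their agreement is a nontrivial check of
#' the urn/mixture equivalence.
#'
#' @param seq Binary vector (0/1), non-empty.
#' @inheritParams polya_simulate
#' @return Log probability of the exact sequence.
#' @export
polya_log_prob <- function(seq, n_black = 1, n_red = 1) {
  seq <- as_binary_seq(seq)
  n <- length(seq)
  # blacks in urn before draw n, totals before draw n
  nb <- n_black + c(0, cumsum(seq))[seq_len(n)]
  tot <- n_black + n_red + seq_len(n) - 1
  p_black <- nb / tot
  sum(log(ifelse(seq == 1L, p_black, 1 - p_black)))
}

#' @rdname polya_log_prob
#' @export
mixture_log_prob <- function(seq, n_black = 1, n_red = 1) {
  seq <- as_binary_seq(seq)
  k <- sum(seq)
  n <- length(seq)
  lbeta(n_black + k, n_red + n - k) - lbeta(n_black, n_red)
}

as_binary_seq <- function(seq) {
  seq <- as.integer(seq)
  if (length(seq) == 0L) stop("'seq' must be non-empty", call. = FALSE)
  if (anyNA(seq) || !all(seq %in% c(0L, 1L)))
    stop("'seq' must contain only 0/1", call. = FALSE)
  seq
}

#' Exact distribution of the number of black draws
#'
#' Sums the (exchangeable) sequence probability over the `choose(n, k)`
#' orderings with `k` ones.  For the default 1-black/1-red urn this is the
#' uniform distribution on `{0, ..., n_draws}` — initial luck is never
#' washed out.
#'
#' @inheritParams polya_simulate
#' @return Numeric vector of length `n_draws + 1`; entry `k + 1` is
#'   `P(sum(Y) = k)`.  Sums to 1.
#' @export
black_count_pmf <- function(n_draws, n_black = 1, n_red = 1) {
  if (n_draws < 1) stop("'n_draws' must be a positive integer", call. = FALSE)
  k <- 0:n_draws
  # one representative ordering per count; exchangeability supplies the rest
  logp <- vapply(k, function(ki) {
    mixture_log_prob(rep(c(1L, 0L), c(ki, n_draws - ki)),
                     n_black = n_black, n_red = n_red)
  }, 0)
  exp(lchoose(n_draws, k) + logp)
}

#' Generative-model wrappers for the binary twin pair
#'
#' @inheritParams polya_simulate
#' @return A [generative_model()] of kind `"binary"`.
#' @export
polya_model <- function(n_black = 1, n_red = 1) {
  generative_model(
    name = "polya_urn", kind = "binary",
    simulate = function(n_units, size, rng)
      polya_simulate(size, n_units, rng, n_black, n_red),
    log_lik = function(traj) polya_log_prob(traj, n_black, n_red))
}

#' @rdname polya_model
#' @export
polya_mixture_model <- function(n_black = 1, n_red = 1) {
  generative_model(
    name = "bernoulli_mixture", kind = "binary",
    simulate = function(n_units, size, rng)
      mixture_simulate(size, n_units, rng, n_black, n_red),
    log_lik = function(traj) mixture_log_prob(traj, n_black, n_red))
}
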