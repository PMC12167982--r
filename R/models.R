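#' Generative model contract
#'
#' A `generative_model` bundles a simulator and an exact log-likelihood under
#' one name, so panels can be simulated from, and scored under, any model
#' interchangeably.  Heterogeneity models draw a latent per-unit variable
#' internally and discard it; reinforcement models condition only on the
#' unit's own past observations.  Both faces are hidden behind the same
#' interface, which is the point: twins are compared purely through their
#' observable laws.
#'
#' @param name Identifier string.
#' @param kind Trajectory kind produced/scored: `"binary"`, `"real"`,
#'   `"event"`.
#' @param simulate `function(n_units, size, rng)` returning a [panel()];
#'   `size` is the number of observations (indexed kinds) or the horizon
#'   (event kind).
#' @param log_lik `function(traj)` returning the exact log probability /
#'   log density of one trajectory (an `event_trajectory` for event models).
#' @return Object of class `generative_model`.
#' @seealso [polya_model()], [q_model()], [snm_model()], [mixture_model()]
#' @export
generative_model <- function(name, kind, simulate, log_lik) {
  stopifnot(is.character(name), length(name) == 1L,
            kind %in% c("binary", "real", "event"),
            is.function(simulate), is.function(log_lik))
  structure(list(name = name, kind = kind,
                 simulate = simulate, log_lik = log_lik),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf("<generative_model '%s' (%s)>\n", x$name, x$kind))
  invisible(x)
}

#' Simulate a panel from a generative model
#'
#' @param model A [generative_model()].
#' @param n_units Number of units (trajectories).
#' @param size Observations per unit, or the horizon for event models.
#' @param rng A [make_rng()] handle or integer seed.
#' @return A [panel()].
#' @export
simulate_panel <- function(model, n_units, size, rng) {
  stopifnot(inherits(model, "generative_model"))
  model$simulate(n_units, size, as_twin_rng(rng))
}

#' Exact log-likelihood of a trajectory or panel under a model
#'
#' For a panel the per-unit log-likelihoods are returned as a vector (units
#' are independent, so the panel log-likelihood is their sum).
#'
#' @param model A [generative_model()].
#' @param x A trajectory (numeric vector or `event_trajectory`) or a
#'   [panel()] of matching kind.
#' @return Numeric scalar (single trajectory) or vector (panel).
#' @export
log_likelihood <- function(model, x) {
  stopifnot(inherits(model, "generative_model"))
  if (inherits(x, "twin_panel")) {
    if (x$kind != model$kind)
      stop("panel kind '", x$kind, "' does not match model kind '",
           model$kind, "'", call. = FALSE)
    return(vapply(x$records, model$log_lik, 0))
  }
  model$log_lik(x)
}

# All 2^n binary sequences of length n, as rows of a 0/1 matrix.
all_binary_sequences <- function(n) {
  stopifnot(n >= 1, n <= 20)
  m <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
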