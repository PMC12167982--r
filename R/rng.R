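#' Seeded random stream with reproducible per-unit substreams
#'
#' All simulators in the package draw randomness through a `twin_rng` handle
#' rather than the global RNG state.  The handle wraps a L'Ecuyer-CMRG seed;
#' per-unit substreams are derived deterministically with
#' [parallel::nextRNGStream()], so a panel simulated for units `1..n` is
#' bit-identical no matter in which order the units are visited, and
#' trajectories of different units are statistically independent.
#'
#' @param seed Non-negative integer seed.
#' @return An object of class `twin_rng`.
#' @examples
#' r <- make_rng(42)
#' p1 <- polya_simulate(10, 5, make_rng(1))
#' p2 <- polya_simulate(10, 5, make_rng(1))
#' identical(p1, p2)
#' @export
make_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0 ||
      seed != trunc(seed)) {
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  }
  state <- local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_rng_state(old))
    suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
    get(".Random.seed", globalenv())
  })
  structure(list(seed = as.integer(seed), state = state), class = "twin_rng")
}

#' @export
print.twin_rng <- function(x, ...) {
  cat("<twin_rng seed=", x$seed, ">\n", sep = "")
  invisible(x)
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

as_twin_rng <- function(rng) {
  if (inherits(rng, "twin_rng")) return(rng)
  if (is.numeric(rng)) return(make_rng(rng))
  stop("'rng' must be a twin_rng handle (see make_rng) or an integer seed",
       call. = FALSE)
}

#' Derive independent substream states from a stream handle
#'
#' Returns `n` L'Ecuyer-CMRG states; state `i` depends only on the seed and
#' on `i`, never on how many draws were taken from other substreams.
#'
#' @param rng A `twin_rng` handle.
#' @param n Number of substreams.
#' @param offset Skip this many substreams first (used to reserve stream 0
#'   for unit-independent draws of a simulator).
#' @return List of `.Random.seed`-compatible integer vectors.
#' @keywords internal
rng_substreams <- function(rng, n, offset = 0L) {
  rng <- as_twin_rng(rng)
  s <- rng$state
  for (i in seq_len(offset)) s <- parallel::nextRNGStream(s)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

# Evaluate fn() with the global RNG temporarily set to `state`.
with_rng_state <- function(state, fn) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng_state(old))
  assign(".Random.seed", state, envir = globalenv())
  fn()
}

# Evaluate fn() with the global RNG seeded from the handle's main stream
# (substream "0", before any per-unit substream).
with_rng <- function(rng, fn) {
  rng <- as_twin_rng(rng)
  with_rng_state(rng$state, fn)
}

# Loop over units, evaluating fn(i) under unit i's own substream.
# Returns a list of the n results, independent of evaluation order.
map_units <- function(rng, n, fn, offset = 0L) {
  states <- rng_substreams(rng, n, offset = offset)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- with_rng_state(states[[i]], function() fn(i))
  out
}
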