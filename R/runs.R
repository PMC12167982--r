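#' Dichotomize a trajectory around its own median
#'
#' Converts a real trajectory to 0/1 by comparing each value to the unit's
#' own median: 1 above, 0 below.  Values exactly equal to the median are
#' handled by the tie policy: `"drop"` (default) removes them, keeping
#' strictly the two categories; `"assign_low"` / `"assign_high"` map them
#' to 0 / 1.  With `rule = "as-is"` already-binary data pass through
#' unchanged (download-style panels).
#'
#' @param traj Numeric vector, length >= 1.
#' @param rule `"median"` or `"as-is"`.
#' @param tie Tie policy for values equal to the median.
#' @return Integer 0/1 vector (possibly shorter than the input when ties
#'   are dropped).
#' @export
dichotomize <- function(traj, rule = c("median", "as-is"),
                        tie = c("drop", "assign_low", "assign_high")) {
  rule <- match.arg(rule)
  tie <- match.arg(tie)
  traj <- as.numeric(traj)
  if (length(traj) < 1) stop("'traj' must be non-empty", call. = FALSE)
  if (rule == "as-is") {
    if (!all(traj %in% c(0, 1)))
      stop("rule 'as-is' requires binary 0/1 data", call. = FALSE)
    return(as.integer(traj))
  }
  med <- stats::median(traj)
  out <- ifelse(traj > med, 1L, ifelse(traj < med, 0L, NA_integer_))
  if (anyNA(out)) {
    out <- switch(tie,
      drop = out[!is.na(out)],
      assign_low = ifelse(is.na(out), 0L, out),
      assign_high = ifelse(is.na(out), 1L, out))
  }
  as.integer(out)
}

#' Count runs in a binary sequence
#'
#' A run is a maximal block of consecutive equal symbols; `(0,0,1,1,1)` has
#' 2 runs.  The empty sequence has 0 runs; a length-1 sequence has 1.
#'
#' @param seq Binary 0/1 vector.
#' @return Non-negative integer.
#' @export
count_runs <- function(seq) {
  n <- length(seq)
  if (n == 0L) return(0L)
  1L + sum(seq[-1] != seq[-n])
}

#' Pooled runs statistic of a binary panel
#'
#' Sums [count_runs()] over all records with at least `min_len` retained
#' observations.  Shorter records are excluded: below three observations a
#' reshuffle cannot change the run count, so they carry no signal.
#'
#' @param panel A binary [panel()].
#' @param min_len Minimum retained record length (default 3).
#' @return Integer pooled run count.
#' @export
pooled_runs <- function(panel, min_len = 3L) {
  stopifnot(inherits(panel, "twin_panel"))
  if (panel$kind != "binary")
    stop("pooled_runs expects a binary panel (dichotomize first)",
         call. = FALSE)
  keep <- panel_lengths(panel) >= min_len
  if (!any(keep)) stop("no record has >= min_len observations", call. = FALSE)
  sum(vapply(panel$records[keep], count_runs, 0L))
}

#' Permutation runs test of exchangeability for a panel
#'
#' Tests whether each unit's observations are exchangeable in order.  Real
#' panels are first dichotomized around each unit's own median (see
#' [dichotomize()]); records with fewer than `min_len` retained
#' observations are excluded.  The observed pooled run count (sum over
#' retained records) is compared with `n_perm` replicates in which every
#' record is independently reshuffled.  With `x` the proportion of
#' permuted sums strictly below the observed one, the two-sided p-value is
#' `2 * min(x, 1 - x)`; when `x` is 0 or 1 the p-value is reported as the
#' upper bound `2 / n_perm` with `p_is_bound` set.  Systematically fewer
#' runs than the shuffle null (small `x`) means streaky, order-dependent
#' records — evidence against any stationary latent-trait explanation.
#'
#' @param panel A real or binary [panel()].
#' @param n_perm Number of permutation replicates (>= 1; default 10000).
#' @param rng A [make_rng()] handle or integer seed.
#' @param rule,tie Passed to [dichotomize()] (real panels).
#' @param min_len Minimum retained record length (default 3).
#' @param smoothed Use the add-one-smoothed proportion
#'   `(#below + 1) / (n_perm + 1)` instead of the raw one (non-default).
#' @param keep_perm_sums Retain the permuted pooled sums in the result.
#' @param chunk_size Permutations processed per vectorized block (memory
#'   knob; does not affect results).
#' @return Object of class `runs_test_result`.
#' @export
permutation_runs_test <- function(panel, n_perm = 10000L, rng = make_rng(0),
                                  rule = c("median", "as-is"),
                                  tie = c("drop", "assign_low", "assign_high"),
                                  min_len = 3L, smoothed = FALSE,
                                  keep_perm_sums = FALSE,
                                  chunk_size = 1000L) {
  stopifnot(inherits(panel, "twin_panel"), n_perm >= 1)
  rule <- if (panel$kind == "binary") "as-is" else match.arg(rule)
  tie <- match.arg(tie)
  rng <- as_twin_rng(rng)
  seqs <- lapply(panel$records, dichotomize, rule = rule, tie = tie)
  seqs <- seqs[lengths(seqs) >= min_len]
  if (length(seqs) == 0)
    stop("no record has >= min_len retained observations", call. = FALSE)
  observed <- sum(vapply(seqs, count_runs, 0L))
  n_units <- length(seqs)
  lens <- lengths(seqs)
  v <- unlist(seqs, use.names = FALSE)

  # per-unit substreams supply each record's permutation keys for all
  # replicates, so results do not depend on unit iteration order
  keys <- map_units(rng, n_units, function(i)
    matrix(stats::runif(lens[i] * n_perm), nrow = lens[i]))

  perm_sums <- integer(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk_size, n_perm - done)
    cols <- done + seq_len(b)
    # stacked layout: unit-major, then replicate, positions contiguous
    key_vec <- unlist(lapply(seq_len(n_units), function(u)
      as.vector(keys[[u]][, cols, drop = FALSE])), use.names = FALSE)
    grp <- unlist(lapply(seq_len(n_units), function(u)
      rep((u - 1L) * b + seq_len(b), each = lens[u])), use.names = FALSE)
    pid <- unlist(lapply(seq_len(n_units), function(u)
      rep(seq_len(b), each = lens[u])), use.names = FALSE)
    vrep <- unlist(lapply(seq_len(n_units), function(u)
      rep(v[sum(lens[seq_len(u - 1L)]) + seq_len(lens[u])], b)),
      use.names = FALSE)
    ord <- order(grp, key_vec)      # uniform shuffle within each (unit, rep)
    x <- vrep[ord]
    nn <- length(x)
    changes <- (x[-1] != x[-nn]) & (grp[-1] == grp[-nn])
    sums <- rowsum(as.numeric(changes), pid[-1])
    perm_sums[cols] <- as.integer(sums[order(as.integer(rownames(sums))), 1]) +
      n_units
    done <- done + b
  }

  n_below <- sum(perm_sums < observed)
  x_prop <- if (smoothed) (n_below + 1) / (n_perm + 1) else n_below / n_perm
  p <- 2 * min(x_prop, 1 - x_prop)
  p_is_bound <- FALSE
  if (x_prop <= 0 || x_prop >= 1) {
    p <- 2 / n_perm
    p_is_bound <- TRUE
  }
  p <- min(p, 1)
  structure(list(observed_runs = observed, n_perm = as.integer(n_perm),
                 x = x_prop, p_two_sided = p, p_is_bound = p_is_bound,
                 n_units_retained = n_units,
                 n_obs_retained = sum(lens),
                 perm_mean = mean(perm_sums),
                 perm_sums = if (keep_perm_sums) perm_sums else NULL,
                 rule = rule, tie = tie, min_len = as.integer(min_len),
                 seed = rng$seed),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat(sprintf(
    "Permutation runs test: observed = %d, permuted mean = %.1f (%d units, %d perms)\n",
    x$observed_runs, x$perm_mean, x$n_units_retained, x$n_perm))
  cat(sprintf("  x = %.4f, two-sided p %s %.4g\n",
              x$x, if (x$p_is_bound) "<=" else "=", x$p_two_sided))
  invisible(x)
}

#' Residual-variance profile against the twin's predicted decay
#'
#' The twin recursion predicts that the variance of `Y[n+1]` around its
#' history-conditional mean is `b * (1 + 1/(n + c))` — shrinking in `n` at
#' a specific rate.  This diagnostic estimates, for each history length
#' `n`, the across-unit sample variance of the one-step-ahead residual
#' `Y[n+1] - mu[n+1](history)` and sets it beside the predicted curve.  A
#' flat empirical profile on data that a latent-trait model fits flags
#' that the shrinking-variance prediction (shared by both twins) fails in
#' the data.
#'
#' @param panel A real [panel()] (ragged allowed; each `n` uses the units
#'   long enough).
#' @param t A [twin_params()] object.
#' @param max_n Largest history length to profile (default: longest
#'   usable).
#' @return Data frame with columns `n`, `n_units`, `observed_var`,
#'   `predicted_var`.  History lengths with fewer than 2 units are skipped
#'   with a warning.
#' @export
conditional_variance_profile <- function(panel, t, max_n = NULL) {
  stopifnot(inherits(panel, "twin_panel"))
  if (panel$kind != "real")
    stop("expected a real-valued panel", call. = FALSE)
  t <- as_twin_params(t)
  lens <- panel_lengths(panel)
  if (is.null(max_n)) max_n <- max(lens) - 1L
  rows <- list()
  skipped <- integer(0)
  for (n in seq_len(max_n)) {
    units <- which(lens >= n + 1L)
    if (length(units) < 2L) { skipped <- c(skipped, n); next }
    resid <- vapply(panel$records[units], function(y) {
      y[n + 1] - (t$c * t$a + sum(y[seq_len(n)])) / (n + t$c)
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, n_units = length(units),
      observed_var = stats::var(resid),
      predicted_var = t$b * (1 + 1 / (n + t$c)))
  }
  if (length(skipped))
    warning("skipped history lengths with < 2 units: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rows)) stop("no history length has >= 2 units", call. = FALSE)
  do.call(rbind, rows)
}
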