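#' Comparison report for model-equivalence checks
#'
#' Each check contributes a row (name, statistic, threshold, pass); the
#' overall verdict is the conjunction.  Reports print as a table and
#' serialize to JSON via [report_to_json()].
#'
#' @param checks Data frame with columns `check`, `statistic`, `threshold`,
#'   `pass`.
#' @param meta Optional named list recorded with the report (seeds, sample
#'   sizes), so stochastic failures are reproducible.
#' @return Object of class `comparison_report`.
#' @export
comparison_report <- function(checks, meta = list()) {
  stopifnot(is.data.frame(checks),
            all(c("check", "statistic", "threshold", "pass") %in%
                  names(checks)))
  structure(list(checks = checks, pass = all(checks$pass), meta = meta),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  df <- x$checks
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  cat(if (x$pass) "overall: PASS\n" else "overall: FAIL\n")
  invisible(x)
}

#' @rdname comparison_report
#' @param report A `comparison_report`.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(list(checks = report$checks, pass = report$pass,
                        meta = report$meta),
                   auto_unbox = TRUE, digits = NA)
}

#' Check that two models assign equal likelihood to shared trajectories
#'
#' The operational meaning of "statistically indistinguishable": the two
#' models assign the same probability/density to every trajectory.  The
#' check scores each supplied trajectory under both models and reports the
#' maximum relative log-likelihood discrepancy
#' `|ll_a - ll_b| / max(1, |ll_a|)`.
#'
#' @param model_a,model_b [generative_model()]s of the same kind.
#' @param trajectories A [panel()] or list of trajectories to score.
#' @param rel_tol Pass threshold on the maximum relative discrepancy.
#' @return A [comparison_report()].
#' @export
likelihood_equality_check <- function(model_a, model_b, trajectories,
                                      rel_tol = 1e-8) {
  stopifnot(inherits(model_a, "generative_model"),
            inherits(model_b, "generative_model"))
  if (model_a$kind != model_b$kind)
    stop("models score different trajectory kinds", call. = FALSE)
  trajs <- if (inherits(trajectories, "twin_panel")) trajectories$records
           else trajectories
  la <- vapply(trajs, model_a$log_lik, 0)
  lb <- vapply(trajs, model_b$log_lik, 0)
  stat <- max(abs(la - lb) / pmax(1, abs(la)))
  comparison_report(
    data.frame(check = "max_rel_loglik_diff", statistic = stat,
               threshold = rel_tol, pass = stat <= rel_tol),
    meta = list(n_trajectories = length(trajs),
                model_a = model_a$name, model_b = model_b$name))
}

#' Compare marginal distributions of two panels index by index
#'
#' Equality of the twins' joint laws implies equality of every marginal;
#' this check tests the marginals directly on simulated output.  Real
#' panels use two-sample Kolmogorov-Smirnov tests, binary panels a
#' chi-square test on the 2x2 table, at each requested index, with Holm
#' adjustment across indices at family level `alpha`.
#'
#' @param panel_a,panel_b Panels of the same kind with equal unit counts.
#' @param indices Observation indices to compare (defaults to those present
#'   in both panels).
#' @param alpha Family-wise level (default 0.01).
#' @return A [comparison_report()]; a check passes when its Holm-adjusted
#'   p-value exceeds `alpha` (no detectable difference).
#' @export
marginal_compare <- function(panel_a, panel_b, indices = NULL, alpha = 0.01) {
  stopifnot(inherits(panel_a, "twin_panel"), inherits(panel_b, "twin_panel"))
  if (panel_a$kind != panel_b$kind) stop("panel kinds differ", call. = FALSE)
  if (panel_a$kind == "event")
    stop("use count_distribution() for event panels", call. = FALSE)
  if (is.null(indices))
    indices <- seq_len(min(min(panel_lengths(panel_a)),
                           min(panel_lengths(panel_b))))
  if (length(indices) == 0) stop("empty index set", call. = FALSE)
  at_index <- function(p, i) {
    v <- vapply(p$records, function(r) if (length(r) >= i) r[i] else NA_real_,
                0)
    v[!is.na(v)]
  }
  pvals <- vapply(indices, function(i) {
    xa <- at_index(panel_a, i); xb <- at_index(panel_b, i)
    if (panel_a$kind == "binary") {
      tab <- rbind(c(sum(xa == 1), sum(xa == 0)),
                   c(sum(xb == 1), sum(xb == 0)))
      suppressWarnings(stats::chisq.test(tab)$p.value)
    } else {
      suppressWarnings(stats::ks.test(xa, xb)$p.value)
    }
  }, 0)
  padj <- stats::p.adjust(pvals, method = "holm")
  comparison_report(
    data.frame(check = paste0("marginal_index_", indices),
               statistic = padj, threshold = alpha, pass = padj > alpha),
    meta = list(alpha = alpha, method = "holm",
                n_a = length(panel_a), n_b = length(panel_b)))
}

#' Compare means and cross-time covariances of two real panels
#'
#' Twins share all cross-time moments.  The check compares the mean vector
#' and every entry of the cross-time covariance matrix of two rectangular
#' panels, declaring a mismatch when an entry differs by more than
#' `n_se` combined Monte-Carlo standard errors (element-wise SEs of the
#' moment estimators, combined in quadrature).
#'
#' @param panel_a,panel_b Rectangular real panels.
#' @param max_lag Restrict to the leading `max_lag + 1` observations
#'   (default: full length).
#' @param n_se Standard-error multiple defining a detected difference
#'   (default 3).
#' @param moments_b Optional closed-form `list(mean, cov)` replacing
#'   `panel_b` (compare sample moments against theory); then `panel_b` may
#'   be `NULL`.
#' @return A [comparison_report()] with the maximum |z|-score over mean and
#'   covariance entries.
#' @export
cross_moment_compare <- function(panel_a, panel_b, max_lag = NULL, n_se = 3,
                                 moments_b = NULL) {
  ma <- panel_matrix(panel_a)
  n_keep <- if (is.null(max_lag)) ncol(ma) else min(ncol(ma), max_lag + 1)
  ma <- ma[, seq_len(n_keep), drop = FALSE]
  sa <- moment_estimates(ma)
  if (is.null(moments_b)) {
    mb <- panel_matrix(panel_b)[, seq_len(n_keep), drop = FALSE]
    sb <- moment_estimates(mb)
  } else {
    sb <- list(mean = moments_b$mean[seq_len(n_keep)],
               cov = moments_b$cov[seq_len(n_keep), seq_len(n_keep),
                                   drop = FALSE],
               se_mean = 0 * sa$se_mean, se_cov = 0 * sa$se_cov)
  }
  z_mean <- abs(sa$mean - sb$mean) /
    sqrt(sa$se_mean^2 + sb$se_mean^2)
  z_cov <- abs(sa$cov - sb$cov) / sqrt(sa$se_cov^2 + sb$se_cov^2)
  stat <- c(max_z_mean = max(z_mean), max_z_cov = max(z_cov))
  comparison_report(
    data.frame(check = names(stat), statistic = as.numeric(stat),
               threshold = n_se, pass = as.numeric(stat) <= n_se),
    meta = list(n_obs_compared = n_keep))
}

# Rectangular panel -> units x time matrix; errors on ragged input.
panel_matrix <- function(p) {
  stopifnot(inherits(p, "twin_panel"))
  if (p$kind == "event")
    stop("event panels have no observation grid", call. = FALSE)
  lens <- panel_lengths(p)
  if (length(unique(lens)) != 1)
    stop("panel is ragged; this check requires rectangular panels",
         call. = FALSE)
  do.call(rbind, p$records)
}

moment_estimates <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  centred <- sweep(m, 2, mu)
  cv <- crossprod(centred) / (n - 1)
  # SE of each covariance entry from the spread of the per-unit products
  se_cov <- matrix(0, ncol(m), ncol(m))
  for (i in seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) {
      prod_ij <- centred[, i] * centred[, j]
      se_cov[i, j] <- stats::sd(prod_ij) / sqrt(n)
    }
  list(mean = mu, cov = cv,
       se_mean = apply(m, 2, stats::sd) / sqrt(n), se_cov = se_cov)
}

#' Hybrid mixture of two generative models
#'
#' Each unit's whole trajectory is drawn from `model_a` with probability
#' `q` and from `model_b` otherwise; the likelihood is the corresponding
#' two-component mixture, computed by log-sum-exp.  Mixing a heterogeneity
#' model with its reinforcement twin at any `q` yields a model
#' indistinguishable from both — the hybrid family interpolates the
#' mechanisms without changing the observable law.
#'
#' @param model_a,model_b [generative_model()]s of the same kind.
#' @param q Mixing probability in `[0, 1]` of drawing from `model_a`.
#' @return A [generative_model()].
#' @export
mixture_model <- function(model_a, model_b, q) {
  stopifnot(inherits(model_a, "generative_model"),
            inherits(model_b, "generative_model"))
  if (model_a$kind != model_b$kind)
    stop("cannot mix models of different trajectory kinds", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > 1)
    stop("'q' must be a probability in [0, 1]", call. = FALSE)
  generative_model(
    name = sprintf("mixture(%s, %s, q=%g)", model_a$name, model_b$name, q),
    kind = model_a$kind,
    simulate = function(n_units, size, rng) {
      rng <- as_twin_rng(rng)
      # stream 0: component labels; streams 1..n: per-unit trajectories
      labels <- with_rng(rng, function() stats::runif(n_units) < q)
      states <- rng_substreams(rng, n_units, offset = 1L)
      recs <- vector("list", n_units)
      for (i in seq_len(n_units)) {
        m <- if (labels[i]) model_a else model_b
        seed_i <- with_rng_state(states[[i]], function()
          sample.int(.Machine$integer.max, 1))
        one <- m$simulate(1, size, make_rng(seed_i))
        recs[[i]] <- one$records[[1]]
      }
      panel(recs, kind = model_a$kind)
    },
    log_lik = function(traj) {
      la <- model_a$log_lik(traj)
      lb <- model_b$log_lik(traj)
      if (q == 1) return(la)
      if (q == 0) return(lb)
      logsumexp(c(log(q) + la, log(1 - q) + lb))
    })
}
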