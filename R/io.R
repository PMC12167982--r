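#' Read a long-format panel from CSV
#'
#' The only accepted layout is long (tidy) CSV with a header, UTF-8,
#' comma-separated, `.` decimal.  Indexed panels need columns `unit_id`,
#' `index` (integer >= 1) and `value` (real, or 0/1 for binary panels),
#' plus an optional `item_id`; event panels need `unit_id`, `event_time`
#' and a per-unit `horizon` column or a global `horizon` argument.  Rows
#' may appear in any order; they are sorted by index/time per unit, and
#' duplicate `(unit, item, index)` keys or duplicate event times within a
#' unit are rejected with an error naming the key.  Wide files are not
#' read: reshape to long first (e.g. `stats::reshape` or `tidyr`).
#'
#' @param path CSV file path.
#' @param kind Trajectory kind; `"auto"` infers from the columns
#'   (`event_time` => event, 0/1 values => binary, else real).
#' @param horizon Global horizon for event panels without a `horizon`
#'   column.
#' @param log_transform Apply `log()` to strictly positive raw values on
#'   read (e.g. raw citation counts; the Gaussian models are defined on
#'   logs).  Zero or negative values are an error — no silent
#'   pseudo-counts.
#' @return A [panel()].
#' @export
read_panel <- function(path, kind = c("auto", "real", "binary", "event"),
                       horizon = NULL, log_transform = FALSE) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_from_df(df, kind = kind, horizon = horizon,
                log_transform = log_transform)
}

#' @rdname read_panel
#' @param df A data frame already in the long layout.
#' @export
panel_from_df <- function(df, kind = c("auto", "real", "binary", "event"),
                          horizon = NULL, log_transform = FALSE) {
  kind <- match.arg(kind)
  if (!"unit_id" %in% names(df))
    stop("missing required column 'unit_id'", call. = FALSE)
  if (!"item_id" %in% names(df)) df$item_id <- NA_character_
  df$item_id <- as.character(df$item_id)
  df$unit_id <- as.character(df$unit_id)
  is_event <- "event_time" %in% names(df)
  if (kind == "auto" && is_event) kind <- "event"

  if (kind == "event") {
    if (!is_event) stop("missing required column 'event_time'", call. = FALSE)
    if (!"horizon" %in% names(df)) {
      if (is.null(horizon))
        stop("event data need a 'horizon' column or a global 'horizon'",
             call. = FALSE)
      df$horizon <- horizon
    }
    key <- paste(df$unit_id, df$item_id, sep = "\r")
    split_idx <- split(seq_len(nrow(df)), key)
    recs <- list(); uid <- character(0); iid <- character(0)
    for (k in names(split_idx)) {
      idx <- split_idx[[k]]
      tms <- sort(df$event_time[idx])
      if (anyDuplicated(tms))
        stop("duplicate event times within unit '", df$unit_id[idx[1]], "'",
             call. = FALSE)
      h <- unique(df$horizon[idx])
      if (length(h) != 1)
        stop("conflicting horizons for unit '", df$unit_id[idx[1]], "'",
             call. = FALSE)
      recs[[length(recs) + 1L]] <- event_trajectory(tms, h)
      uid <- c(uid, df$unit_id[idx[1]]); iid <- c(iid, df$item_id[idx[1]])
    }
    return(panel(recs, kind = "event", unit_id = uid, item_id = iid))
  }

  for (col in c("index", "value"))
    if (!col %in% names(df))
      stop("missing required column '", col, "'", call. = FALSE)
  if (any(df$index < 1) || any(df$index != trunc(df$index)))
    stop("'index' must be integers >= 1", call. = FALSE)
  key <- paste(df$unit_id, df$item_id, df$index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate key (unit '%s', item '%s', index %d)",
                 d$unit_id, d$item_id, as.integer(d$index)), call. = FALSE)
  }
  if (log_transform) {
    if (any(df$value <= 0))
      stop("log transform requires strictly positive values ",
           "(no pseudo-count is added)", call. = FALSE)
    df$value <- log(df$value)
  }
  if (kind == "auto") kind <- if (all(df$value %in% c(0, 1))) "binary"
                              else "real"
  ukey <- paste(df$unit_id, df$item_id, sep = "\r")
  split_idx <- split(seq_len(nrow(df)), ukey)
  recs <- list(); uid <- character(0); iid <- character(0)
  for (k in names(split_idx)) {
    idx <- split_idx[[k]]
    o <- order(df$index[idx])
    recs[[length(recs) + 1L]] <- df$value[idx][o]
    uid <- c(uid, df$unit_id[idx[1]]); iid <- c(iid, df$item_id[idx[1]])
  }
  panel(recs, kind = kind, unit_id = uid, item_id = iid)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_panel()]: deterministic row order (unit, item,
#' index/time), header always written, binary values written as integers.
#' Event units with zero observed events are written as a single row with
#' an empty `event_time`, so the unit and its horizon round-trip.
#'
#' @param panel A [panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "twin_panel"))
  df <- as.data.frame(panel)
  if (panel$kind == "event") {
    lens <- panel_lengths(panel)
    if (any(lens == 0)) {
      empty <- data.frame(unit_id = panel$unit_id[lens == 0],
                          item_id = panel$item_id[lens == 0],
                          event_time = NA_real_,
                          horizon = vapply(panel$records[lens == 0],
                                           `[[`, 0, "horizon"))
      df <- rbind(df, empty)
    }
    df <- df[order(df$unit_id, df$item_id, df$event_time), , drop = FALSE]
  } else {
    df <- df[order(df$unit_id, df$item_id, df$index), , drop = FALSE]
    if (panel$kind == "binary") df$value <- as.integer(df$value)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Simulate a named benchmark scenario
#'
#' Reproduces the package's reference simulation settings: the Gaussian
#' career scenarios at `mu_T = 0`, `var_T = 0.2`, `var_X = 1` (30 units,
#' 10 observations), the attitude-panel special case at unit variances
#' (10 units, 20 waves), the contact process at `alpha = 1`, `pi_0 =
#' 0.25`, `pi_j = 0.25 * j^0.5`, horizon 10 (30 units), binary urn /
#' mixture panels for runs-test calibration (30 units, 20 draws), and a
#' 50/50 hybrid of the Gaussian pair.  Counts and lengths are
#' configurable; parameters are returned alongside the panel so every
#' fixture is self-describing.
#'
#' @param scenario One of `"polya"`, `"mixture"`, `"q_model"`, `"q_twin"`,
#'   `"sdm"`, `"sdm_twin"`, `"snm"`, `"snm_twin"`, `"hybrid"`.
#' @param seed Integer seed (or [make_rng()] handle).
#' @param n_units,size Override the scenario's default unit count and
#'   length/horizon.
#' @param q Mixing probability for `"hybrid"` (default 0.5).
#' @return List with elements `panel`, `params` (named list actually
#'   used), and `scenario`.
#' @export
generate_fixtures <- function(scenario, seed = 0, n_units = NULL,
                              size = NULL, q = 0.5) {
  rng <- as_twin_rng(seed)
  pick <- function(default) if (is.null(n_units)) default else n_units
  len <- function(default) if (is.null(size)) default else size
  qp <- q_params(0, 0.2, 1)
  sp <- q_params(0, 1, 1)
  cp <- contact_params(alpha = 1, pi0 = 0.25, scale = 0.25, rho = 0.5)
  switch(scenario,
    polya = list(
      panel = polya_simulate(len(20), pick(30), rng),
      params = list(n_black = 1, n_red = 1), scenario = scenario),
    mixture = list(
      panel = mixture_simulate(len(20), pick(30), rng),
      params = list(n_black = 1, n_red = 1), scenario = scenario),
    q_model = list(
      panel = q_simulate(qp, pick(30), len(10), rng),
      params = unclass(qp), scenario = scenario),
    q_twin = list(
      panel = q_twin_simulate(map_q_to_twin(qp), pick(30), len(10), rng),
      params = unclass(map_q_to_twin(qp)), scenario = scenario),
    sdm = list(
      panel = q_simulate(sp, pick(10), len(20), rng),
      params = unclass(sp), scenario = scenario),
    sdm_twin = list(
      panel = q_twin_simulate(map_q_to_twin(sp), pick(10), len(20), rng),
      params = unclass(map_q_to_twin(sp)), scenario = scenario),
    snm = list(
      panel = snm_simulate(cp, len(10), pick(30), rng),
      params = list(alpha = 1, pi0 = 0.25, scale = 0.25, rho = 0.5),
      scenario = scenario),
    snm_twin = list(
      panel = contact_twin_simulate(cp, len(10), pick(30), rng),
      params = list(alpha = 1, pi0 = 0.25, scale = 0.25, rho = 0.5),
      scenario = scenario),
    hybrid = list(
      panel = simulate_panel(
        mixture_model(q_model(qp), q_twin_model(map_q_to_twin(qp)), q),
        pick(30), len(10), rng),
      params = c(unclass(qp), list(q = q)), scenario = scenario),
    stop("unknown scenario '", scenario, "'", call. = FALSE))
}
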