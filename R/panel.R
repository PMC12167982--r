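#' Longitudinal panel of per-unit trajectories
#'
#' A `twin_panel` is a ragged collection of trajectories keyed by unit (and,
#' for multi-item data such as attitude surveys, an optional item).  All
#' trajectories in one panel are of the same kind:
#' \describe{
#'   \item{`"binary"`}{integer vectors of 0/1 outcomes, observation index
#'     `n = 1, 2, ...`}
#'   \item{`"real"`}{finite numeric vectors (e.g. log citation counts),
#'     observation index `n = 1, 2, ...`}
#'   \item{`"event"`}{strictly increasing event times in `(0, horizon]`,
#'     together with the per-unit observation horizon; time starts at 0.}
#' }
#' Trajectories store observed values only; model parameters live outside the
#' panel, so one panel can be scored under several models.
#'
#' @param records List of trajectories.  For `kind = "event"` each element is
#'   a list with components `times` and `horizon` (or is created via
#'   [event_trajectory()]).
#' @param kind One of `"binary"`, `"real"`, `"event"`.
#' @param unit_id Character vector of unit identifiers; defaults to
#'   `names(records)` or `"u1", "u2", ...`.
#' @param item_id Optional character vector of item identifiers (recycled
#'   `NA` when absent).  `(unit_id, item_id)` pairs must be unique.
#' @return An object of class `twin_panel`.
#' @seealso [read_panel()], [write_panel()], [simulate_panel()]
#' @export
panel <- function(records, kind = c("real", "binary", "event"),
                  unit_id = NULL, item_id = NULL) {
  kind <- match.arg(kind)
  if (!is.list(records)) stop("'records' must be a list", call. = FALSE)
  n <- length(records)
  if (is.null(unit_id)) {
    unit_id <- if (!is.null(names(records)) && all(nzchar(names(records))))
      names(records) else paste0("u", seq_len(n))
  }
  unit_id <- as.character(unit_id)
  if (length(unit_id) != n) stop("'unit_id' length mismatch", call. = FALSE)
  if (is.null(item_id)) item_id <- rep(NA_character_, n)
  item_id <- as.character(item_id)
  if (length(item_id) != n) stop("'item_id' length mismatch", call. = FALSE)
  key <- paste(unit_id, item_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (unit_id, item_id) keys: ",
         paste(unique(unit_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  records <- lapply(records, validate_trajectory, kind = kind)
  names(records) <- NULL
  structure(list(records = records, kind = kind,
                 unit_id = unit_id, item_id = item_id),
            class = "twin_panel")
}

validate_trajectory <- function(x, kind) {
  switch(kind,
    binary = {
      x <- as.integer(x)
      if (anyNA(x) || !all(x %in% c(0L, 1L)))
        stop("binary trajectories must contain only 0/1", call. = FALSE)
      x
    },
    real = {
      x <- as.numeric(x)
      if (anyNA(x) || any(!is.finite(x)))
        stop("real trajectories must be finite", call. = FALSE)
      x
    },
    event = {
      if (is.numeric(x)) stop("event trajectories need a horizon; ",
                              "use event_trajectory(times, horizon)",
                              call. = FALSE)
      event_trajectory(x$times, x$horizon)
    })
}

#' Event trajectory: event times with an observation horizon
#'
#' @param times Strictly increasing event times in `(0, horizon]`.
#' @param horizon Positive observation end time; events are right-censored
#'   at the horizon.
#' @return A list with components `times` and `horizon`, class
#'   `event_trajectory`.
#' @export
event_trajectory <- function(times, horizon) {
  times <- as.numeric(times)
  horizon <- as.numeric(horizon)
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("'horizon' must be a single positive number", call. = FALSE)
  if (anyNA(times) || any(times <= 0) || any(times > horizon))
    stop("event times must lie in (0, horizon]", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("event times must be strictly increasing (ties not allowed)",
         call. = FALSE)
  structure(list(times = times, horizon = horizon),
            class = "event_trajectory")
}

#' @export
length.twin_panel <- function(x) length(x$records)

#' @export
print.twin_panel <- function(x, ...) {
  n <- length(x)
  lens <- panel_lengths(x)
  cat(sprintf("<twin_panel: %d %s trajectories, lengths %s>\n",
              n, x$kind,
              if (n == 0) "-" else paste0(min(lens), "-", max(lens))))
  invisible(x)
}

panel_lengths <- function(p) {
  if (p$kind == "event") vapply(p$records, function(r) length(r$times), 0L)
  else lengths(p$records)
}

#' Convert a panel to a long (tidy) data frame
#'
#' Indexed panels produce columns `unit_id`, `item_id`, `index`, `value`;
#' event panels produce `unit_id`, `item_id`, `event_time`, `horizon`.
#' Units with zero events still contribute their horizon through
#' [write_panel()]'s sidecar handling; see that function.
#'
#' @param x A `twin_panel`.
#' @param ... Unused.
#' @export
as.data.frame.twin_panel <- function(x, ...) {
  lens <- panel_lengths(x)
  if (x$kind == "event") {
    data.frame(
      unit_id = rep(x$unit_id, lens),
      item_id = rep(x$item_id, lens),
      event_time = unlist(lapply(x$records, `[[`, "times"), use.names = FALSE),
      horizon = rep(vapply(x$records, `[[`, 0, "horizon"), lens),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      unit_id = rep(x$unit_id, lens),
      item_id = rep(x$item_id, lens),
      index = unlist(lapply(lens, seq_len), use.names = FALSE),
      value = unlist(x$records, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
}

#' Compare two panels for equality up to numeric tolerance
#'
#' @param a,b Panels of the same kind.
#' @param tol Absolute numeric tolerance (default `1e-12`).
#' @return Logical.
#' @export
panel_equal <- function(a, b, tol = 1e-12) {
  stopifnot(inherits(a, "twin_panel"), inherits(b, "twin_panel"))
  if (a$kind != b$kind || length(a) != length(b)) return(FALSE)
  oa <- order(a$unit_id, a$item_id)
  ob <- order(b$unit_id, b$item_id)
  if (!identical(a$unit_id[oa], b$unit_id[ob]) ||
      !identical(a$item_id[oa], b$item_id[ob])) return(FALSE)
  for (i in seq_along(oa)) {
    ra <- a$records[[oa[i]]]; rb <- b$records[[ob[i]]]
    if (a$kind == "event") {
      if (length(ra$times) != length(rb$times)) return(FALSE)
      if (abs(ra$horizon - rb$horizon) > tol) return(FALSE)
      if (length(ra$times) && max(abs(ra$times - rb$times)) > tol) return(FALSE)
    } else {
      if (length(ra) != length(rb)) return(FALSE)
      if (length(ra) && max(abs(ra - rb)) > tol) return(FALSE)
    }
  }
  TRUE
}
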