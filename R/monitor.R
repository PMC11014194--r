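.level_labels <- c("very low", "low", "medium", "high", "very high")

#' Map a Load probability onto the 1-5 workload level scale
#'
#' Monotone step mapping: the level increments each time `p_load` strictly
#' exceeds a cut point (defaults 0.2/0.4/0.6/0.8), so `p = 0` is level 1,
#' `p = 0.5` level 3 ("medium"), `p = 1` level 5.
#'
#' @param p_load probability of Load, in `[0, 1]` (vectorized).
#' @param cuts strictly increasing cut points inside (0, 1).
#' @return integer level(s) in 1..(length(cuts) + 1).
#' @export
cw_level <- function(p_load, cuts = c(0.2, 0.4, 0.6, 0.8)) {
  if (any(!is.finite(p_load)) || any(p_load < 0) || any(p_load > 1)) {
    stop("p_load must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(diff(cuts) > 0), all(cuts > 0 & cuts < 1))
  vapply(p_load, function(p) 1L + sum(p > cuts), integer(1))
}

#' Workload monitor state (perception-action loop)
#'
#' Holds the streaming history of fused Load probabilities, the derived 1-5
#' level, and the reporting interval. [update()] is pure: it returns a new
#' state, so replaying the same probability sequence reproduces the same
#' final state exactly.
#'
#' @param interval reporting interval in seconds (default 300 s = 5 min).
#' @param cuts level cut points, see [cw_level()].
#' @return An empty `cw_monitor` state.
#' @examples
#' m <- cw_monitor()
#' m <- update(m, 0.5)
#' m <- update(m, 0.6)
#' render_report(m)
#' @export
cw_monitor <- function(interval = 300, cuts = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(interval > 0)
  structure(list(interval = interval, cuts = cuts,
                 history = data.frame(index = integer(0), p_load = numeric(0),
                                      level = integer(0))),
            class = "cw_monitor")
}

#' @export
update.cw_monitor <- function(object, p_load, ...) {
  if (length(p_load) != 1 || !is.finite(p_load) || p_load < 0 || p_load > 1) {
    stop("p_load must be a single probability in [0, 1]", call. = FALSE)
  }
  h <- object$history
  object$history <- rbind(h, data.frame(index = nrow(h) + 1L,
                                        p_load = p_load,
                                        level = cw_level(p_load, object$cuts)))
  object
}

#' @export
print.cw_monitor <- function(x, ...) {
  cat(sprintf("cw_monitor: %d interval(s) of %s\n",
              nrow(x$history), format_interval(x$interval)))
  if (nrow(x$history)) cat(render_report(x), "\n")
  invisible(x)
}

format_interval <- function(seconds) {
  if (seconds %% 60 == 0) paste0(seconds / 60, " min") else paste0(seconds, " s")
}

format_pct <- function(x) {
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 2))
}

#' Render the operator report for the latest interval
#'
#' Stable template (tested verbatim): after at least two intervals,
#' `"The CW <increased by P%|decreased by P%|is unchanged> and
#' <reached|remains at> level L (<label> on the scale of 1-5) in the past
#' time interval (<interval>)."` Relative change is computed on `P(Load)`
#' against the previous interval. The first interval yields a baseline
#' message.
#'
#' @param state a [cw_monitor()] with at least one interval.
#' @return a single character message.
#' @export
render_report <- function(state) {
  stopifnot(inherits(state, "cw_monitor"))
  h <- state$history
  if (!nrow(h)) stop("no intervals recorded yet", call. = FALSE)
  k <- nrow(h)
  lvl <- h$level[k]
  lvl_txt <- sprintf("level %d (%s on the scale of 1-5)", lvl, .level_labels[lvl])
  iv <- format_interval(state$interval)
  if (k == 1) {
    return(sprintf("Baseline established: CW at %s; P(Load) = %s.",
                   lvl_txt, format_pct(100 * h$p_load[k])))
  }
  prev <- h$p_load[k - 1]; cur <- h$p_load[k]
  if (prev == cur) {
    return(sprintf(
      "The CW is unchanged and remains at %s in the past time interval (%s).",
      lvl_txt, iv))
  }
  if (prev == 0) {
    direction <- sprintf("increased to P(Load) = %s", format_pct(100 * cur))
  } else {
    pct <- 100 * (cur - prev) / prev
    direction <- sprintf("%s by %s%%",
                         if (pct > 0) "increased" else "decreased",
                         format_pct(abs(pct)))
  }
  sprintf("The CW %s and reached %s in the past time interval (%s).",
          direction, lvl_txt, iv)
}

#' Fold a probability stream through the monitor
#'
#' @param p_loads numeric vector of fused Load probabilities, one per
#'   interval.
#' @param state starting [cw_monitor()] state.
#' @return list with the final `state` and the per-interval `reports`.
#' @export
monitor_stream <- function(p_loads, state = cw_monitor()) {
  reports <- character(length(p_loads))
  for (i in seq_along(p_loads)) {
    state <- update(state, p_loads[i])
    reports[i] <- render_report(state)
  }
  list(state = state, reports = reports)
}

#' Write the monitor audit trail to JSON
#'
#' @param state a [cw_monitor()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_monitor_audit <- function(state, path) {
  stopifnot(inherits(state, "cw_monitor"))
  jsonlite::write_json(list(interval_s = state$interval, cuts = state$cuts,
                            history = state$history),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
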