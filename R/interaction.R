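#' The seven panel buttons
#'
#' Two position the sample along the vertical axis, two adjust the imaging
#' plane from dorsal to ventral, and one each records a stack, switches the
#' laser on manually, and shows the information screen.
#'
#' @export
BUTTONS <- c("sample_up", "sample_down", "plane_dorsal", "plane_ventral",
             "stack", "laser", "info")

#' Construct / read a button event train
#'
#' Event trains are replayable data frames with columns `t_ms` (numeric
#' milliseconds), `button` (one of [BUTTONS]) and `edge` (`"press"` or
#' `"release"`), sorted by `t_ms`. `read_events` accepts CSV (header
#' `t_ms,button,edge`) or JSONL (one object per line with those keys);
#' `write_events` writes CSV.
#'
#' @param t_ms,button,edge vectors of equal length.
#' @return a validated data frame of class `button_events`.
#' @export
button_events <- function(t_ms = numeric(0), button = character(0),
                          edge = character(0)) {
  ev <- data.frame(t_ms = as.numeric(t_ms), button = as.character(button),
                   edge = as.character(edge), stringsAsFactors = FALSE)
  bad <- setdiff(unique(ev$button), BUTTONS)
  if (length(bad)) stop_invalid("unknown buttons: %s", paste(bad, collapse = ", "))
  if (!all(ev$edge %in% c("press", "release")))
    stop_invalid("edge must be 'press' or 'release'")
  if (is.unsorted(ev$t_ms)) stop_invalid("event stream must be sorted by t_ms")
  class(ev) <- c("button_events", class(ev))
  ev
}

#' @param path CSV or JSONL file.
#' @rdname button_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_format("no such event file: %s", path)
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
    ev <- do.call(rbind, rows)
  } else {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("t_ms", "button", "edge") %in% names(ev)))
    stop_format("event file needs columns t_ms, button, edge")
  button_events(ev$t_ms, ev$button, ev$edge)
}

#' @param events a `button_events` data frame.
#' @rdname button_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("t_ms", "button", "edge")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Debounce a button event stream
#'
#' Mechanical switches bounce; spurious edges within a refractory period
#' after an accepted switch are discarded. The rule, applied per button
#' independently: a switch (press *or* release) at time `t` is accepted iff
#' no accepted switch on that button occurred in the open window
#' `(t - refractory_ms, t)`; accepted presses are emitted, accepted releases
#' only update the refractory window. The first press on a quiescent button
#' is always accepted.
#'
#' @param events a [button_events] data frame (must be sorted).
#' @param refractory_ms refractory period in ms (> 0); 50 ms by default.
#' @return the accepted press events (same columns, `edge == "press"`).
#' @export
debounce <- function(events, refractory_ms = 50) {
  if (refractory_ms <= 0) stop_invalid("refractory_ms must be > 0")
  if (is.unsorted(events$t_ms)) stop_invalid("event stream must be sorted")
  keep <- logical(nrow(events))
  for (b in unique(events$button)) {
    idx <- which(events$button == b)
    last <- -Inf
    for (i in idx) {
      t <- events$t_ms[i]
      if (t - last >= refractory_ms) {
        last <- t
        keep[i] <- events$edge[i] == "press"
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LED auto-off policy
#'
#' The transmission LED is switched off when no button has been pressed for
#' the timeout (5 minutes by default); session start counts as activity. The
#' state is a pure function of the accepted presses, `now` and the timeout.
#'
#' @param state list with `on` and `last_activity_ms` (as returned by a
#'   previous call), or `NULL` for session start at time 0.
#' @param events accepted press events (from [debounce()]) up to `now_ms`.
#' @param now_ms current session time in ms.
#' @param timeout_ms auto-off timeout in ms (> 0).
#' @return list with `on` and `last_activity_ms`.
#' @export
led_update <- function(state, events, now_ms, timeout_ms = 300000) {
  if (timeout_ms <= 0) stop_invalid("timeout_ms must be > 0")
  last <- if (is.null(state)) 0 else state$last_activity_ms
  if (!is.null(events) && nrow(events)) {
    t <- events$t_ms[events$t_ms <= now_ms]
    if (length(t)) last <- max(last, max(t))
  }
  list(on = (now_ms - last) < timeout_ms, last_activity_ms = last)
}

# current preview rendering at the session's stage position
session_preview <- function(session, t_ms = NA_real_) {
  devs <- session$devices
  cfg <- session$config
  pos <- devs$stage$position()
  trans <- devs$camera$snap("transmission", t_ms)
  fluo <- devs$camera$snap("fluorescence", t_ms)
  ind <- plane_indicator(pos$z_plane, c(cfg$z_min, cfg$z_max),
                         pos$vertical_pos, c(cfg$v_min, cfg$v_max))
  render_preview(trans, fluo, pos$z_plane, c(cfg$z_min, cfg$z_max),
                 canvas = cfg$canvas_px, s_front = cfg$s_front,
                 s_back = cfg$s_back, indicator = ind)
}

#' Dispatch one accepted button press
#'
#' The seven-button mapping: `sample_up`/`sample_down` move the sample
#' vertically by one step, `plane_dorsal`/`plane_ventral` move the imaging
#' plane axially (dorsal = towards plane 0), all four followed by a fresh
#' preview rendering; `stack` runs [acquire_stack()]; `laser` switches the
#' laser on for the configured dwell time; `info` returns the information
#' screen without touching any device. Every dispatch is logged. Stage moves
#' clamp at the bounding box, so holding a button at a limit is harmless.
#' Device errors are routed through [handle_runtime_error()]; in a `FATAL`
#' session every request returns the emergency screen.
#'
#' @param session a `spim_session`.
#' @param button one of [BUTTONS].
#' @param t_ms event time in session milliseconds.
#' @param on_plane optional stack-progress callback.
#' @return list with `view` (a [spim_view]), `outcome` (`"ok"`,
#'   `"recovered"` or `"exit"`), `exit_code` and for stacks `stack`.
#' @export
dispatch <- function(session, button, t_ms = NULL, on_plane = NULL) {
  if (!button %in% BUTTONS) stop_invalid("unknown button '%s'", button)
  if (is.null(t_ms)) t_ms <- session$clock_ms
  session$clock_ms <- t_ms
  if (session$state == "FATAL") {
    log_action(session$telemetry, paste0("button:", button),
               t = session_time(session))
    return(list(view = emergency_view(session$config$canvas_px),
                outcome = "ok", exit_code = NA_integer_))
  }
  # laser dwell expiry
  if (!is.null(session$laser_off_at) && t_ms >= session$laser_off_at) {
    session$devices$laser$off()
    session$laser_off_at <- NULL
  }
  session$last_activity_ms <- t_ms
  log_action(session$telemetry, paste0("button:", button),
             t = session_time(session))
  devs <- session$devices
  stack_out <- NULL
  action <- switch(
    button,
    sample_up = function() { devs$stage$move("vertical", 1L); session_preview(session, t_ms) },
    sample_down = function() { devs$stage$move("vertical", -1L); session_preview(session, t_ms) },
    plane_dorsal = function() { devs$stage$move("axial", -1L); session_preview(session, t_ms) },
    plane_ventral = function() { devs$stage$move("axial", 1L); session_preview(session, t_ms) },
    stack = function() {
      res <- acquire_stack(session, on_plane = on_plane, t_ms = t_ms)
      stack_out <<- res$stack
      log_action(session$telemetry, "stack_acquired",
                 detail = sprintf("planes=%d", length(res$stack$frames)),
                 t = session_time(session))
      res$view
    },
    laser = function() {
      devs$laser$on()
      session$laser_off_at <- t_ms + session$config$laser_dwell_s * 1000
      session_preview(session, t_ms)
    },
    info = function() info_view(session$config$canvas_px)
  )
  res <- tryCatch(
    list(view = action(), outcome = "ok", exit_code = NA_integer_),
    hardware_error = function(e) {
      h <- handle_runtime_error(session, e)
      if (h$outcome == "recovered")
        list(view = tryCatch(session_preview(session, t_ms),
                             error = function(e2) info_view(session$config$canvas_px)),
             outcome = "recovered", exit_code = NA_integer_)
      else list(view = NULL, outcome = "exit", exit_code = h$exit_code)
    })
  res$stack <- stack_out
  res
}
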