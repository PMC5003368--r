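#' Supervisor exit codes
#'
#' `EXIT_OK` (0): clean scheduled shutdown, the watchdog does not restart.
#' `EXIT_RESTART` (1): a hardware error persisted after re-initialisation;
#' the watchdog restarts the session. `EXIT_FATAL` (2): even the simulating
#' tier failed; no restart, the emergency screen persists.
#'
#' @name exit_codes
#' @export
EXIT_OK <- 0L
#' @rdname exit_codes
#' @export
EXIT_RESTART <- 1L
#' @rdname exit_codes
#' @export
EXIT_FATAL <- 2L

default_registry <- function(cfg, volumes) {
  bbox <- config_bbox(cfg)
  make_tier <- function(primary) {
    stage <- sim_stage(bbox)
    laser <- sim_laser()
    camera <- if (primary)
      sim_camera(volumes, stage, laser, exposure_ref = cfg$exposure_ref,
                 noise_sd = cfg$noise_sd, seed = cfg$seed + 1L)
    else playback_camera(volumes, stage)
    buttons <- sim_buttons()
    list(camera = camera, stage = stage, laser = laser, buttons = buttons)
  }
  # each tier is built lazily and at most once per detection pass
  tiers <- new.env(parent = emptyenv())
  tier_dev <- function(tier, name) {
    force(tier); force(name)
    function() {
      if (is.null(tiers[[tier]])) tiers[[tier]] <- make_tier(tier == "primary")
      tiers[[tier]][[name]]
    }
  }
  registry <- list()
  for (nm in c("camera", "stage", "laser", "buttons"))
    registry[[nm]] <- list(primary = tier_dev("primary", nm),
                           fallback = tier_dev("fallback", nm))
  registry
}

#' Start an instrument session
#'
#' Builds the telemetry log, ensures the phantom dataset, then performs
#' autonomous hardware detection ([detect_hardware()]): all primary devices
#' initialise cleanly -> `NORMAL`; any initialisation failure -> `FALLBACK`
#' on the simulating tier (which serves the cached phantom, so the
#' instrument appears functional); failure of the simulating tier too ->
#' `FATAL`, in which every request is answered with the emergency screen.
#' No initialisation error ever escapes: failures become mode decisions and
#' are logged and notified.
#'
#' @param config a [spim_config()].
#' @param registry optional device registry (see [detect_hardware()]);
#'   defaults to the fully simulated instrument.
#' @param telemetry optional [telemetry_log()] to reuse across restarts.
#' @param t0_ms initial session clock in ms (used by the watchdog so a
#'   restarted session resumes at the failure time, keeping log timestamps
#'   non-decreasing).
#' @return a session environment of class `spim_session` with fields
#'   `state` (`"NORMAL"`, `"FALLBACK"` or `"FATAL"`), `config`, `devices`,
#'   `telemetry`, `lut`, `clock_ms`.
#' @export
start_session <- function(config, registry = NULL, telemetry = NULL,
                          t0_ms = 0) {
  validate_config(config)
  s <- new.env(parent = emptyenv())
  class(s) <- "spim_session"
  s$config <- config
  s$clock_ms <- t0_ms
  s$laser_off_at <- NULL
  s$last_activity_ms <- 0
  s$led_on <- TRUE
  s$telemetry <- if (is.null(telemetry))
    telemetry_log(config$sync_dir) else telemetry
  s$lut <- depth_luts(config$phantom_dims[3L], config$colormap)
  volumes <- ensure_dataset(config$data_dir, config$phantom_dims,
                            config$n_vessels, config$seed)
  s$volumes <- volumes
  if (is.null(registry)) registry <- default_registry(config, volumes)
  s$registry <- registry
  det <- detect_hardware(registry, config$faults)
  s$devices <- det$devices
  s$state <- switch(det$mode, normal = "NORMAL", fallback = "FALLBACK",
                    fatal = "FATAL")
  for (e in det$errors)
    log_exception(s$telemetry, e, t = session_time(s))
  log_action(s$telemetry, "session_start", detail = s$state,
             t = session_time(s), notify = TRUE)
  if (det$mode != "normal")
    log_action(s$telemetry, "mode_change", detail = s$state,
               t = session_time(s))
  if (s$state != "FATAL") {
    dv <- s$devices
    tryCatch({
      dv$camera$set_exposure(config$exposure_ms)
      dv$laser$set_power(config$laser_power)
      dv$camera$start_acquisition()
    }, error = function(e) {
      # device misbehaving right after init: treat as runtime error
      log_exception(s$telemetry, e, t = session_time(s))
    })
  }
  s
}

#' @export
print.spim_session <- function(x, ...) {
  cat(sprintf("<spim_session %s, t = %.0f ms>\n", x$state, x$clock_ms))
  invisible(x)
}

session_time <- function(session, t_ms = NULL) {
  if (is.null(t_ms)) t_ms <- session$clock_ms
  session$config$session_start + t_ms / 1000
}

#' Handle a runtime hardware error
#'
#' In `NORMAL` state: the error is logged and notified, every device is
#' closed (best-effort; errors during close are swallowed and logged) and
#' re-initialised, and the failed operation is retried once. If the retry
#' succeeds the session stays `NORMAL` (`outcome = "recovered"`); if the
#' error recurs the session must exit with `EXIT_RESTART`
#' (`outcome = "exit"`). In `FALLBACK` state there is no hardware to
#' re-initialise: the error is logged and the session keeps serving the
#' phantom.
#'
#' @param session a `spim_session`.
#' @param error the [hardware_error] condition.
#' @param retry zero-argument function re-attempting the failed operation;
#'   `NULL` uses a side-effect-free probe of the failing device (a snap,
#'   a position read, a state read), so that a recovered session is in the
#'   same device state as one that never faulted. The failed user action
#'   itself is discarded; the visitor simply presses again.
#' @return `list(outcome, exit_code)` with outcome `"recovered"` or
#'   `"exit"`; `exit_code` is `EXIT_RESTART` when `outcome == "exit"`.
#' @export
handle_runtime_error <- function(session, error, retry = NULL) {
  log_exception(session$telemetry, error, t = session_time(session))
  if (session$state == "FALLBACK")
    return(list(outcome = "recovered", exit_code = NA_integer_))
  close_all(session$devices, on_error = function(d, e)
    log_exception(session$telemetry, e, t = session_time(session)))
  reinit_ok <- tryCatch({ init_all(session$devices); TRUE },
                        error = function(e) {
                          log_exception(session$telemetry, e,
                                        t = session_time(session))
                          FALSE
                        })
  if (reinit_ok && session$state == "NORMAL") {
    tryCatch({
      session$devices$camera$set_exposure(session$config$exposure_ms)
      session$devices$laser$set_power(session$config$laser_power)
      session$devices$camera$start_acquisition()
    }, error = function(e) reinit_ok <<- FALSE)
  }
  if (!reinit_ok)
    return(list(outcome = "exit", exit_code = EXIT_RESTART))
  if (is.null(retry)) retry <- device_probe(session, error)
  retried <- tryCatch({ if (!is.null(retry)) retry(); TRUE },
                      error = function(e) {
                        log_exception(session$telemetry, e,
                                      t = session_time(session))
                        FALSE
                      })
  if (retried) list(outcome = "recovered", exit_code = NA_integer_)
  else list(outcome = "exit", exit_code = EXIT_RESTART)
}

# Side-effect-free retry of the device named in a hardware error.
device_probe <- function(session, error) {
  dev_name <- if (!is.null(error$device)) error$device else "camera"
  d <- session$devices[[dev_name]]
  if (is.null(d)) return(NULL)
  switch(dev_name,
         camera = function() d$snap("transmission"),
         stage = function() d$position(),
         laser = function() d$is_on(),
         buttons = function() d$poll())
}

#' Close a session's devices and log the shutdown
#'
#' @param session a `spim_session`.
#' @param t_ms shutdown timestamp (session milliseconds).
#' @export
shutdown_session <- function(session, t_ms = NULL) {
  if (!is.null(t_ms)) session$clock_ms <- t_ms
  close_all(session$devices, on_error = function(d, e)
    log_exception(session$telemetry, e, t = session_time(session)))
  log_action(session$telemetry, "session_shutdown", detail = session$state,
             t = session_time(session), notify = TRUE)
  session$state <- "SHUTDOWN"
  invisible(session)
}

#' Watchdog restart loop
#'
#' The host-side stand-in for the batch-script loop that keeps the
#' instrument alive: `run_once` is invoked repeatedly as long as it returns
#' `EXIT_RESTART` and fewer than `max_restarts` restarts have been used;
#' `EXIT_OK` (scheduled shutdown) and `EXIT_FATAL` stop the loop
#' immediately.
#'
#' @param run_once zero-argument function returning an exit code.
#' @param max_restarts restart cap (>= 0); `Inf` reproduces an unbounded
#'   production loop.
#' @return `list(exit_code, runs)`.
#' @export
watchdog <- function(run_once, max_restarts = Inf) {
  stopifnot(max_restarts >= 0)
  runs <- 0L
  repeat {
    code <- run_once()
    runs <- runs + 1L
    if (!identical(as.integer(code), EXIT_RESTART)) break
    if (runs - 1L >= max_restarts) break
  }
  list(exit_code = as.integer(code), runs = runs)
}

#' Apply a maintainer settings delta
#'
#' The maintenance surface: bounding box, exposure time and laser power (and
#' any other configuration field) can be adjusted at run time. The delta is
#' validated atomically — either every field is applied (with exposure and
#' power pushed to the devices and the stage re-clamped into a narrowed
#' bounding box) or none is and the whole delta is rejected with a
#' diagnostic.
#'
#' @param session a `spim_session`.
#' @param delta named list of [spim_config()] fields.
#' @return the updated `spim_config`, invisibly.
#' @export
apply_settings <- function(session, delta) {
  known <- names(formals(spim_config))
  unknown <- setdiff(names(delta), known)
  if (length(unknown))
    stop_invalid("unknown settings: %s", paste(unknown, collapse = ", "))
  new_cfg <- session$config
  for (nm in names(delta)) new_cfg[[nm]] <- delta[[nm]]
  validate_config(new_cfg)
  session$config <- new_cfg
  if (session$state %in% c("NORMAL", "FALLBACK")) {
    session$devices$camera$set_exposure(new_cfg$exposure_ms)
    session$devices$laser$set_power(new_cfg$laser_power)
    session$devices$stage$clamp_to(config_bbox(new_cfg))
  }
  invisible(new_cfg)
}

#' Daily start/stop schedule against an injectable clock
#'
#' The exhibit computer boots at a fixed time every morning and shuts down
#' at night. Given a sorted vector of simulated clock ticks, returns the
#' `start` and `shutdown` actions whose scheduled occurrence falls inside a
#' tick interval `(previous tick, tick]`. Ticks never reaching a scheduled
#' time produce no actions. The corresponding OS power actions are behind
#' the `platform_hooks`, no-ops by default.
#'
#' @param config a [spim_config()] (uses `boot_time` and `shutdown_time`).
#' @param ticks sorted POSIXct clock ticks.
#' @param run_hooks whether to invoke `platform_hooks$power_on` /
#'   `power_off` for each action.
#' @return data frame with columns `time` (POSIXct occurrence) and `action`
#'   (`"start"` or `"shutdown"`), time-ordered.
#' @export
schedule_daily <- function(config, ticks, run_hooks = FALSE) {
  if (length(ticks) < 2L)
    return(data.frame(time = as.POSIXct(character(0), tz = "UTC"),
                      action = character(0)))
  ticks <- sort(ticks)
  lo <- ticks[1L]; hi <- ticks[length(ticks)]
  occurrences <- function(clock_time, label) {
    secs <- parse_clock_time(clock_time)
    d0 <- as.POSIXct(trunc(lo, "days"), tz = "UTC")
    cand <- seq(d0, by = "1 day",
                length.out = as.numeric(difftime(hi, d0, units = "days")) + 2L)
    cand <- cand + secs
    cand <- cand[cand > lo & cand <= hi]
    if (!length(cand)) return(NULL)
    data.frame(time = cand, action = label)
  }
  out <- rbind(occurrences(config$boot_time, "start"),
               occurrences(config$shutdown_time, "shutdown"))
  if (is.null(out) || !nrow(out))
    return(data.frame(time = as.POSIXct(character(0), tz = "UTC"),
                      action = character(0)))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  if (run_hooks) {
    for (a in out$action) {
      if (a == "start") config$platform_hooks$power_on()
      else config$platform_hooks$power_off()
    }
  }
  out
}
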