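#' Describe an injectable fault
#'
#' A fault schedule makes a simulated device misbehave on cue so every
#' error-handling path of the supervisor can be exercised deterministically.
#'
#' @param fail_on_init if `TRUE`, the first `init()` raises a
#'   [hardware_error] (every `init()` if `persistent`).
#' @param fail_after if set (>= 1), operational calls 1..`fail_after` succeed
#'   and every later call raises, until re-initialisation clears the fault
#'   (only when not `persistent`).
#' @param persistent if `TRUE`, re-initialisation does not clear the fault;
#'   if `FALSE` a single close/re-init cycle restores normal operation.
#' @param fallback_fail_on_init if `TRUE`, the fall-back tier's device for
#'   this peripheral also fails to initialise (drives the instrument fatal).
#' @return a list of class `fault_schedule`.
#' @export
fault_schedule <- function(fail_on_init = FALSE, fail_after = NULL,
                           persistent = FALSE, fallback_fail_on_init = FALSE) {
  if (!is.null(fail_after) && (!is.numeric(fail_after) || fail_after < 1))
    stop_invalid("fail_after must be >= 1 when present")
  structure(list(fail_on_init = isTRUE(fail_on_init),
                 fail_after = fail_after,
                 persistent = isTRUE(persistent),
                 fallback_fail_on_init = isTRUE(fallback_fail_on_init)),
            class = "fault_schedule")
}

empty_schedule <- function(s) {
  is.null(s) || (!s$fail_on_init && is.null(s$fail_after) &&
                   !s$fallback_fail_on_init)
}

#' Wrap a device with a fault-injection layer
#'
#' Returns a device satisfying the same interface contract whose calls raise
#' [hardware_error]s exactly as the schedule dictates; with an empty schedule
#' the wrapper is a bit-identical passthrough. Faults are raised *before* the
#' inner call runs, so the inner device's state (including its private noise
#' stream) is untouched by a failed call.
#'
#' @param device a `spim_device`.
#' @param schedule a [fault_schedule()] (or `NULL` for passthrough).
#' @return a wrapped `spim_device`.
#' @export
inject_faults <- function(device, schedule = NULL) {
  if (is.null(schedule)) schedule <- fault_schedule()
  stopifnot(inherits(schedule, "fault_schedule"))
  w <- new.env(parent = emptyenv())
  w$name <- device$name
  w$inner <- device
  w$schedule <- schedule
  w$op_count <- 0L
  w$init_attempts <- 0L
  w$active <- TRUE
  w$tripped <- FALSE
  class(w) <- c("fault_device", class(device))

  check_op <- function() {
    if (!w$active) return(invisible(NULL))
    if (w$tripped) hardware_error(w$name, "operate", "injected persistent fault")
    w$op_count <- w$op_count + 1L
    if (!is.null(w$schedule$fail_after) && w$op_count > w$schedule$fail_after) {
      w$tripped <- TRUE
      hardware_error(w$name, "operate",
                     sprintf("injected fault after %d calls", w$schedule$fail_after))
    }
    invisible(NULL)
  }

  w$init <- function() {
    w$init_attempts <- w$init_attempts + 1L
    if (w$active && w$schedule$fail_on_init &&
        (w$schedule$persistent || w$init_attempts == 1L))
      hardware_error(w$name, "init", "injected init failure")
    if (w$init_attempts > 1L && !w$schedule$persistent) {
      # transient fault: a close/re-init cycle repairs the peripheral
      w$active <- FALSE
      w$tripped <- FALSE
    }
    val <- device$init()
    w$initialized <- device$initialized
    val
  }
  w$close <- function() {
    val <- device$close()
    w$initialized <- device$initialized
    val
  }
  # forward every other function member through the operational fault check,
  # and mirror data members on read via get_member below
  for (nm in setdiff(ls(device), c("name", "init", "close"))) {
    member <- get(nm, envir = device)
    if (is.function(member)) {
      w[[nm]] <- local({
        fn <- member
        function(...) { check_op(); fn(...) }
      })
    }
  }
  w
}

#' Autonomous hardware detection
#'
#' Tries to initialise the primary implementation of every peripheral. If all
#' succeed, the instrument runs on its primary tier. If any initialisation
#' fails, every initialised primary is closed again and the fall-back
#' (simulating) tier is constructed for *all* devices — a single fall-back
#' mode, not per-device degradation. If a fall-back device also fails to
#' initialise, detection reports `"fatal"`. Detection never raises: a failure
#' is a mode decision, not an error.
#'
#' @param registry named list (per device) of
#'   `list(primary = factory, fallback = factory)`; each factory is a
#'   zero-argument function returning an uninitialised device.
#' @param faults optional named list (per device) of [fault_schedule()]s
#'   applied to the factories' products.
#' @return `list(mode, devices, errors)` with mode `"normal"`, `"fallback"`
#'   or `"fatal"`; `devices` is the named list of initialised devices (empty
#'   for fatal); `errors` the conditions encountered.
#' @export
detect_hardware <- function(registry, faults = NULL) {
  errors <- list()
  build_tier <- function(tier) {
    devs <- list()
    for (nm in names(registry)) {
      dev <- registry[[nm]][[tier]]()
      sched <- faults[[nm]]
      if (!is.null(sched)) {
        if (tier == "fallback") {
          sched <- fault_schedule(fail_on_init = sched$fallback_fail_on_init)
        }
        dev <- inject_faults(dev, sched)
      }
      devs[[nm]] <- dev
    }
    devs
  }
  primary <- build_tier("primary")
  ok <- TRUE
  inited <- list()
  for (nm in names(primary)) {
    res <- tryCatch({ primary[[nm]]$init(); TRUE },
                    error = function(e) { errors[[length(errors) + 1L]] <<- e; FALSE })
    if (!res) { ok <- FALSE; break }
    inited[[nm]] <- primary[[nm]]
  }
  if (ok) return(list(mode = "normal", devices = primary, errors = errors))
  close_all(inited)
  fallback <- tryCatch(build_tier("fallback"), error = function(e) {
    errors[[length(errors) + 1L]] <<- e
    NULL
  })
  if (!is.null(fallback)) {
    fb_ok <- TRUE
    fb_inited <- list()
    for (nm in names(fallback)) {
      res <- tryCatch({ fallback[[nm]]$init(); TRUE },
                      error = function(e) { errors[[length(errors) + 1L]] <<- e; FALSE })
      if (!res) { fb_ok <- FALSE; break }
      fb_inited[[nm]] <- fallback[[nm]]
    }
    if (fb_ok) return(list(mode = "fallback", devices = fallback, errors = errors))
    close_all(fb_inited)
  }
  list(mode = "fatal", devices = list(), errors = errors)
}
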