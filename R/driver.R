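#' Run one session over a scripted event train
#'
#' The headless session loop: start the session, debounce the raw event
#' train, dispatch every accepted press in order (enforcing the LED
#' auto-off, laser dwell and foreground-heartbeat policies along the way),
#' archive each stack rendering, and shut down cleanly when the simulated
#' clock passes the configured shutdown time or the script is exhausted.
#' Returns `EXIT_OK` for a clean shutdown, `EXIT_RESTART` when a hardware
#' error persisted through re-initialisation, `EXIT_FATAL` when even the
#' simulating tier failed (the script is still replayed: every request is
#' answered with the emergency screen).
#'
#' @param config a [spim_config()].
#' @param events a [button_events] data frame (raw, pre-debounce).
#' @param telemetry optional [telemetry_log()] reused across watchdog
#'   restarts.
#' @param registry optional device registry override.
#' @return list with `exit_code`, `session`, `accepted` (dispatched press
#'   count), `stacks` (acquired stack count), `led` (final LED state).
#' @export
run_session <- function(config, events = button_events(), telemetry = NULL,
                        registry = NULL, t0_ms = 0) {
  session <- start_session(config, registry = registry, telemetry = telemetry,
                           t0_ms = t0_ms)
  accepted <- debounce(events, config$debounce_ms)
  led <- led_update(NULL, NULL, 0, config$led_timeout_s * 1000)
  shutdown_ms <- {
    start_secs <- as.numeric(difftime(
      config$session_start, trunc(config$session_start, "days"), units = "secs"))
    delta <- parse_clock_time(config$shutdown_time) - start_secs
    if (delta <= 0) Inf else delta * 1000
  }
  exit_code <- EXIT_OK
  stacks <- 0L
  dispatched <- 0L
  last_heartbeat <- t0_ms
  hit_shutdown <- FALSE
  for (i in seq_len(nrow(accepted))) {
    t <- accepted$t_ms[i]
    if (t < t0_ms) next
    if (t >= shutdown_ms) { hit_shutdown <- TRUE; break }
    # foreground heartbeat: every foreground_interval_s of simulated time
    while (t - last_heartbeat >= config$foreground_interval_s * 1000) {
      last_heartbeat <- last_heartbeat + config$foreground_interval_s * 1000
      config$platform_hooks$foreground()
    }
    res <- dispatch(session, accepted$button[i], t_ms = t)
    dispatched <- dispatched + 1L
    led <- led_update(led, accepted[i, , drop = FALSE], t,
                      config$led_timeout_s * 1000)
    if (!is.null(res$stack)) {
      stacks <- stacks + 1L
      archive_rendering(config$sync_dir, res$view, session_time(session, t),
                        retention = config$retention)
    }
    if (res$outcome == "exit") {
      exit_code <- res$exit_code
      break
    }
  }
  if (session$state == "FATAL" && exit_code == EXIT_OK)
    exit_code <- EXIT_FATAL
  if (exit_code != EXIT_RESTART) {
    stats <- aggregate_daily(session$telemetry)
    tryCatch(export_stats_table(stats,
                                file.path(config$sync_dir, "stats.csv")),
             error = function(e) log_exception(session$telemetry, e,
                                               t = session_time(session)))
  }
  shutdown_session(session,
                   t_ms = if (hit_shutdown && is.finite(shutdown_ms))
                     shutdown_ms else NULL)
  list(exit_code = as.integer(exit_code), session = session,
       accepted = dispatched, stacks = stacks, led = led)
}

#' Replay a scripted session under the watchdog
#'
#' The deterministic end-to-end driver: a scripted event train, a fault
#' profile inside `config`, and a fixed seed reproduce a full museum day
#' byte-for-byte, including all telemetry files and renderings under
#' `config$sync_dir`. Restarted runs (after `EXIT_RESTART`) resume with the
#' remaining events, sharing one telemetry log.
#'
#' @param config a [spim_config()].
#' @param events a [button_events] data frame or event file path.
#' @param max_restarts watchdog restart cap.
#' @return list with `exit_code`, `runs`, `stacks`, `accepted`.
#' @export
simulate_session <- function(config, events = button_events(),
                             max_restarts = 3L) {
  if (is.character(events)) events <- read_events(events)
  telemetry <- telemetry_log(config$sync_dir)
  stacks <- 0L
  accepted <- 0L
  last <- NULL
  t0 <- 0
  wd <- watchdog(function() {
    res <- run_session(config, events, telemetry = telemetry, t0_ms = t0)
    stacks <<- stacks + res$stacks
    accepted <<- accepted + res$accepted
    last <<- res
    # a restarted session resumes just after the event that took it down
    t0 <<- res$session$clock_ms + 1
    res$exit_code
  }, max_restarts = max_restarts)
  list(exit_code = wd$exit_code, runs = wd$runs, stacks = stacks,
       accepted = accepted, last = last)
}

usage_text <- function() {
  paste(
    "usage: spimsim <command> [options]",
    "",
    "commands:",
    "  run               run the instrument under the watchdog",
    "                    [--config PATH] [--mode auto|fallback]",
    "                    [--fault-profile PATH] [--max-restarts N]",
    "                    [--events PATH] [--seed N] [--out DIR]",
    "  simulate-session  replay a scripted event train deterministically",
    "                    --events PATH [--config PATH] [--seed N] [--out DIR]",
    "  render-stack      composite a saved stack TIFF into a PNG",
    "                    --in PATH [--colormap NAME] --out PATH",
    "  stats             aggregate an action log into the website table",
    "                    --log DIR --out PATH",
    "  make-phantom      generate and cache the phantom dataset",
    "                    --out DIR [--seed N]",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3L)
    if (i + 1L > length(argv)) return(NULL)
    flags[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_config <- function(flags) {
  cfg_args <- list()
  cfg <- if (!is.null(flags$config)) load_config(flags$config)
  else spim_config()
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  if (!is.null(flags$out)) {
    cfg$sync_dir <- flags$out
    cfg$data_dir <- file.path(flags$out, "data")
  }
  if (!is.null(flags$`fault-profile`)) {
    raw <- yaml::read_yaml(flags$`fault-profile`)
    cfg$faults <- lapply(raw, function(s) do.call(fault_schedule, s))
  }
  if (identical(flags$mode, "fallback")) {
    # force the simulating tier by failing every primary init
    fs <- fault_schedule(fail_on_init = TRUE, persistent = TRUE)
    cfg$faults <- modifyList(list(camera = fs),
                             if (is.null(cfg$faults)) list() else cfg$faults)
  }
  validate_config(cfg)
  cfg
}

#' Command-line entry point
#'
#' Subcommands `run`, `simulate-session`, `render-stack`, `stats` and
#' `make-phantom`; see `inst/cli/spimsim.R` for the installed launcher. The
#' process exit status equals the session's final exit code; bad flags give
#' status 64.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit status, invisibly.
#' @export
spim_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) { message(usage_text()); return(invisible(64L)) }
  cmd <- argv[1L]
  flags <- parse_flags(argv[-1L])
  if (is.null(flags) ||
      !cmd %in% c("run", "simulate-session", "render-stack", "stats",
                  "make-phantom")) {
    message(usage_text())
    return(invisible(64L))
  }
  status <- switch(
    cmd,
    "run" = ,
    "simulate-session" = {
      if (cmd == "simulate-session" && is.null(flags$events)) {
        message(usage_text()); return(invisible(64L))
      }
      cfg <- cli_config(flags)
      events <- if (!is.null(flags$events)) read_events(flags$events)
      else button_events()
      max_restarts <- if (!is.null(flags$`max-restarts`))
        as.integer(flags$`max-restarts`) else 3L
      res <- simulate_session(cfg, events, max_restarts = max_restarts)
      res$exit_code
    },
    "render-stack" = {
      if (is.null(flags$`in`) || is.null(flags$out)) {
        message(usage_text()); return(invisible(64L))
      }
      stack <- load_stack(flags$`in`)
      lut <- depth_luts(stack$z_max + 1L,
                        if (is.null(flags$colormap)) "bluered" else flags$colormap)
      write_view_png(composite_stack(stack, lut), flags$out)
      0L
    },
    "stats" = {
      if (is.null(flags$log) || is.null(flags$out)) {
        message(usage_text()); return(invisible(64L))
      }
      export_stats_table(aggregate_daily(flags$log), flags$out)
      0L
    },
    "make-phantom" = {
      if (is.null(flags$out)) { message(usage_text()); return(invisible(64L)) }
      seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
      ensure_dataset(flags$out, seed = seed)
      0L
    })
  invisible(as.integer(status))
}
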