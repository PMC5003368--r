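#' Session configuration
#'
#' All operating constants of the virtual instrument in one validated list.
#' Defaults encode the intended unsupervised-exhibit operation: a 50 ms
#' button debounce refractory, a 5 minute LED auto-off, a 5 s
#' foreground-enforcement heartbeat, fixed daily boot and shutdown times and
#' a one-rendering-per-day archive.
#'
#' @param exposure_ms camera exposure time in ms (> 0).
#' @param exposure_ref reference exposure at which the phantom is reproduced
#'   unscaled.
#' @param laser_power laser power fraction in `[0, 1]`.
#' @param z_min,z_max axial bounding box (plane indices, 0-based, within the
#'   phantom).
#' @param v_min,v_max vertical bounding box (stage steps).
#' @param debounce_ms button refractory period in ms.
#' @param led_timeout_s LED auto-off timeout in seconds.
#' @param foreground_interval_s heartbeat interval for the
#'   keep-window-in-foreground platform hook, in seconds.
#' @param laser_dwell_s how long the laser button keeps the laser on, in
#'   seconds (unattended safety: never indefinitely).
#' @param boot_time,shutdown_time daily start/stop clock times, `"HH:MM"`.
#' @param data_dir phantom cache directory.
#' @param sync_dir directory whose contents an external synchroniser mirrors
#'   (logs, archive, stats table, notifications).
#' @param seed master seed for phantom generation and camera noise.
#' @param faults optional named list (per device) of [fault_schedule()]s.
#' @param retention archived renderings kept per calendar day.
#' @param phantom_dims `c(nx, ny, nz)` of the generated specimen.
#' @param n_vessels vessels in the phantom.
#' @param noise_sd camera read-noise sd (intensity units).
#' @param canvas_px `c(H, W)` rendering canvas.
#' @param colormap depth LUT palette (see [depth_luts()]).
#' @param s_front,s_back axial scale at the front/back plane.
#' @param session_start POSIXct wall-clock origin of session time; fixed so
#'   replayed sessions are byte-identical.
#' @param platform_hooks list of no-op OS hooks (`foreground()`,
#'   `power_on()`, `power_off()`), replaceable on real deployments.
#' @return validated list of class `spim_config`.
#' @export
spim_config <- function(exposure_ms = 10,
                        exposure_ref = 10,
                        laser_power = 1,
                        z_min = 0L, z_max = NULL,
                        v_min = 0L, v_max = 20L,
                        debounce_ms = 50,
                        led_timeout_s = 300,
                        foreground_interval_s = 5,
                        laser_dwell_s = 10,
                        boot_time = "08:00",
                        shutdown_time = "18:00",
                        data_dir = file.path(tempdir(), "spimsim-data"),
                        sync_dir = file.path(tempdir(), "spimsim-sync"),
                        seed = 1L,
                        faults = NULL,
                        retention = 1L,
                        phantom_dims = c(64L, 64L, 32L),
                        n_vessels = 5L,
                        noise_sd = 0,
                        canvas_px = c(96L, 96L),
                        colormap = "bluered",
                        s_front = 1, s_back = 0.85,
                        session_start = as.POSIXct("2016-01-15 08:00:00",
                                                   tz = "UTC"),
                        platform_hooks = NULL) {
  if (is.null(z_max)) z_max <- phantom_dims[3L] - 1L
  if (is.null(platform_hooks))
    platform_hooks <- list(foreground = function() invisible(NULL),
                           power_on = function() invisible(NULL),
                           power_off = function() invisible(NULL))
  cfg <- structure(list(
    exposure_ms = exposure_ms, exposure_ref = exposure_ref,
    laser_power = laser_power,
    z_min = as.integer(z_min), z_max = as.integer(z_max),
    v_min = as.integer(v_min), v_max = as.integer(v_max),
    debounce_ms = debounce_ms, led_timeout_s = led_timeout_s,
    foreground_interval_s = foreground_interval_s,
    laser_dwell_s = laser_dwell_s,
    boot_time = boot_time, shutdown_time = shutdown_time,
    data_dir = data_dir, sync_dir = sync_dir,
    seed = as.integer(seed), faults = faults, retention = as.integer(retention),
    phantom_dims = as.integer(phantom_dims), n_vessels = as.integer(n_vessels),
    noise_sd = noise_sd, canvas_px = as.integer(canvas_px),
    colormap = colormap, s_front = s_front, s_back = s_back,
    session_start = session_start, platform_hooks = platform_hooks),
    class = "spim_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$exposure_ms > 0, "exposure_ms must be > 0")
  chk(cfg$exposure_ref > 0, "exposure_ref must be > 0")
  chk(cfg$laser_power >= 0 && cfg$laser_power <= 1,
      "laser_power must lie in [0, 1]")
  chk(cfg$z_min <= cfg$z_max, "z_min must be <= z_max")
  chk(cfg$v_min <= cfg$v_max, "v_min must be <= v_max")
  chk(cfg$z_min >= 0 && cfg$z_max <= cfg$phantom_dims[3L] - 1L,
      "axial bounding box must lie within the phantom")
  for (f in c("debounce_ms", "led_timeout_s", "foreground_interval_s",
              "laser_dwell_s"))
    chk(cfg[[f]] > 0, sprintf("%s must be > 0", f))
  chk(cfg$retention >= 1, "retention must be >= 1")
  chk(all(cfg$phantom_dims >= 1), "phantom dimensions must be >= 1")
  chk(cfg$boot_time != cfg$shutdown_time,
      "boot_time and shutdown_time must differ")
  if (length(problems))
    stop_invalid("invalid configuration: %s", paste(problems, collapse = "; "))
  invisible(cfg)
}

config_bbox <- function(cfg) list(z_min = cfg$z_min, z_max = cfg$z_max,
                                  v_min = cfg$v_min, v_max = cfg$v_max)

#' Load a configuration file
#'
#' Flat key-value YAML; keys are [spim_config()] arguments, with fault
#' schedules under a `faults:` mapping of per-device keys (`fail_on_init`,
#' `fail_after`, `persistent`, `fallback_fail_on_init`).
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return a `spim_config`.
#' @export
load_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$faults))
    raw$faults <- lapply(raw$faults, function(s) do.call(fault_schedule, s))
  if (!is.null(raw$session_start))
    raw$session_start <- as.POSIXct(raw$session_start, tz = "UTC")
  raw <- modifyList(raw, list(...))
  known <- names(formals(spim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  do.call(spim_config, raw)
}

# "HH:MM" -> seconds since midnight
parse_clock_time <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1L]])
  parts[1L] * 3600 + parts[2L] * 60
}
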