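#' Simulated peripheral devices
#'
#' Each peripheral of the instrument sits behind a small interface contract:
#' a device is an environment of class `spim_device` whose function members
#' implement the contract, so a high-fidelity simulation, the fall-back
#' playback tier and a fault-injection wrapper are freely interchangeable.
#' Common members: `name`, `init()`, `close()`; see the individual
#' constructors for the device-specific members.
#'
#' @name devices
NULL

new_device <- function(name, class) {
  dev <- new.env(parent = emptyenv())
  dev$name <- name
  dev$initialized <- FALSE
  class(dev) <- c(class, "spim_device")
  dev
}

#' @export
print.spim_device <- function(x, ...) {
  cat(sprintf("<spim device '%s' (%s)%s>\n", x$name, class(x)[1L],
              if (isTRUE(x$initialized)) ", initialized" else ""))
  invisible(x)
}

#' Simulated sample stage
#'
#' Tracks the vertical sample position and the axial imaging-plane index.
#' Moves clamp silently at the configured bounding box: an unsupervised user
#' holding a button at a limit must never trigger an error path.
#'
#' Members: `move(axis, delta)` with axis `"vertical"` or `"axial"`;
#' `position()` returning `list(vertical_pos, z_plane)`; `clamp_to(bbox)`
#' re-clamping the current position into a new bounding box.
#'
#' @param bbox list with `z_min`, `z_max`, `v_min`, `v_max` (integers).
#' @param z_start,v_start initial position; defaults to the box centre.
#' @return a `spim_device` environment.
#' @export
sim_stage <- function(bbox, z_start = NULL, v_start = NULL) {
  stopifnot(bbox$z_min <= bbox$z_max, bbox$v_min <= bbox$v_max)
  dev <- new_device("stage", "sim_stage")
  dev$bbox <- bbox
  dev$z_plane <- as.integer(if (is.null(z_start))
    floor((bbox$z_min + bbox$z_max) / 2) else clamp(z_start, bbox$z_min, bbox$z_max))
  dev$vertical_pos <- as.integer(if (is.null(v_start))
    floor((bbox$v_min + bbox$v_max) / 2) else clamp(v_start, bbox$v_min, bbox$v_max))
  dev$init <- function() { dev$initialized <- TRUE; invisible(dev) }
  dev$close <- function() { dev$initialized <- FALSE; invisible(dev) }
  dev$move <- function(axis, delta) {
    if (!axis %in% c("vertical", "axial"))
      stop_invalid("unknown stage axis '%s'", axis)
    if (axis == "axial")
      dev$z_plane <- as.integer(clamp(dev$z_plane + delta,
                                      dev$bbox$z_min, dev$bbox$z_max))
    else
      dev$vertical_pos <- as.integer(clamp(dev$vertical_pos + delta,
                                           dev$bbox$v_min, dev$bbox$v_max))
    invisible(dev$position())
  }
  dev$position <- function() list(vertical_pos = dev$vertical_pos,
                                  z_plane = dev$z_plane)
  dev$clamp_to <- function(bbox) {
    stopifnot(bbox$z_min <= bbox$z_max, bbox$v_min <= bbox$v_max)
    dev$bbox <- bbox
    dev$z_plane <- as.integer(clamp(dev$z_plane, bbox$z_min, bbox$z_max))
    dev$vertical_pos <- as.integer(clamp(dev$vertical_pos, bbox$v_min, bbox$v_max))
    invisible(dev$position())
  }
  dev
}

#' Simulated excitation laser
#'
#' Members: `on()`, `off()`, `set_power(fraction)` with fraction in `[0, 1]`
#' (persists across on/off), `is_on()`, `power()`.
#'
#' @return a `spim_device` environment.
#' @export
sim_laser <- function() {
  dev <- new_device("laser", "sim_laser")
  dev$state_on <- FALSE
  dev$power_frac <- 1
  dev$init <- function() { dev$initialized <- TRUE; dev$state_on <- FALSE; invisible(dev) }
  dev$close <- function() { dev$state_on <- FALSE; dev$initialized <- FALSE; invisible(dev) }
  dev$on <- function() { dev$state_on <- TRUE; invisible(dev) }
  dev$off <- function() { dev$state_on <- FALSE; invisible(dev) }
  dev$set_power <- function(fraction) {
    if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
      stop_invalid("laser power must be a fraction in [0, 1]")
    dev$power_frac <- fraction
    invisible(dev)
  }
  dev$is_on <- function() dev$state_on
  dev$power <- function() dev$power_frac
  dev
}

#' Simulated camera
#'
#' Serves planes of the phantom volumes at the stage's current axial plane.
#' The fluorescence channel depends on the laser: with the laser off only a
#' noisy background plane is returned (no excitation, no signal). Intensities
#' are scaled by `min(1, exposure / exposure_ref)`, perturbed by seeded
#' Gaussian read noise of standard deviation `noise_sd`, and clipped to
#' `[0, IMAX]`. With `noise_sd = 0` and `exposure == exposure_ref` a snap is
#' the phantom plane exactly.
#'
#' Members: `set_exposure(ms)` (must be > 0), `start_acquisition()`,
#' `snap(channel)` (only between start and stop; returns a [spim_frame]),
#' `stop()`, `close()`.
#'
#' @param volumes list with `fluorescence` and `transmission` [spim_volume]s.
#' @param stage,laser sibling devices consulted at snap time.
#' @param exposure_ref reference exposure (ms) at which the phantom was
#'   "recorded"; snaps at this exposure reproduce it unscaled.
#' @param noise_sd read-noise standard deviation (intensity units).
#' @param seed seed of the camera's private noise stream.
#' @param background fluorescence background level used when the laser is off.
#' @return a `spim_device` environment.
#' @export
sim_camera <- function(volumes, stage, laser, exposure_ref = 10,
                       noise_sd = 0, seed = 1, background = 5) {
  dev <- new_device("camera", "sim_camera")
  dev$volumes <- volumes
  dev$stage <- stage
  dev$laser <- laser
  dev$exposure_ref <- exposure_ref
  dev$exposure <- exposure_ref
  dev$noise_sd <- noise_sd
  dev$rng_seed <- seed
  dev$rng_state <- NULL
  dev$background <- background
  dev$acquiring <- FALSE
  dev$init <- function() { dev$initialized <- TRUE; invisible(dev) }
  dev$close <- function() { dev$acquiring <- FALSE; dev$initialized <- FALSE; invisible(dev) }
  dev$set_exposure <- function(ms) {
    if (!is.numeric(ms) || ms <= 0) stop_invalid("exposure must be > 0 ms")
    dev$exposure <- ms
    invisible(dev)
  }
  dev$start_acquisition <- function() { dev$acquiring <- TRUE; invisible(dev) }
  dev$stop <- function() { dev$acquiring <- FALSE; invisible(dev) }
  dev$snap <- function(channel, t_ms = NA_real_) {
    if (!dev$acquiring)
      stop_invalid("snap() before start_acquisition()")
    vol <- dev$volumes[[channel]]
    if (is.null(vol)) stop_invalid("unknown channel '%s'", channel)
    z <- dev$stage$position()$z_plane
    zi <- clamp(z, 0L, vol$nz - 1L)
    if (channel == "fluorescence" && !dev$laser$is_on()) {
      base <- matrix(dev$background, vol$ny, vol$nx)
    } else {
      base <- matrix(vol$data[zi + 1L, , ], vol$ny, vol$nx)
      base <- base * min(1, dev$exposure / dev$exposure_ref)
      if (channel == "fluorescence") base <- base * dev$laser$power()
    }
    if (dev$noise_sd > 0) {
      noise <- rng_do(dev, rnorm(length(base), 0, dev$noise_sd))
      base <- base + noise
    }
    pixels <- clamp(round(base), 0, IMAX)
    spim_frame(matrix(as.integer(pixels), vol$ny, vol$nx), channel, z, t_ms)
  }
  dev
}

#' Fall-back playback camera
#'
#' The simulating tier's camera: serves the cached phantom planes verbatim,
#' ignoring exposure, laser power and noise settings, so a failed instrument
#' still appears functional. Same interface as [sim_camera()].
#'
#' @inheritParams sim_camera
#' @return a `spim_device` environment.
#' @export
playback_camera <- function(volumes, stage) {
  dev <- new_device("camera", "playback_camera")
  dev$volumes <- volumes
  dev$stage <- stage
  dev$acquiring <- FALSE
  dev$init <- function() { dev$initialized <- TRUE; invisible(dev) }
  dev$close <- function() { dev$acquiring <- FALSE; dev$initialized <- FALSE; invisible(dev) }
  dev$set_exposure <- function(ms) invisible(dev)
  dev$start_acquisition <- function() { dev$acquiring <- TRUE; invisible(dev) }
  dev$stop <- function() { dev$acquiring <- FALSE; invisible(dev) }
  dev$snap <- function(channel, t_ms = NA_real_) {
    if (!dev$acquiring) stop_invalid("snap() before start_acquisition()")
    vol <- dev$volumes[[channel]]
    if (is.null(vol)) stop_invalid("unknown channel '%s'", channel)
    z <- dev$stage$position()$z_plane
    zi <- clamp(z, 0L, vol$nz - 1L)
    spim_frame(matrix(vol$data[zi + 1L, , ], vol$ny, vol$nx), channel, z, t_ms)
  }
  dev
}

#' Simulated button panel device
#'
#' Holds a scripted train of button events and hands them out in order; the
#' virtual stand-in for the microcontroller-connected seven-button panel.
#' Members: `poll()` returning the next event row or `NULL`, `push(events)`
#' appending rows.
#'
#' @param events optional data frame of events (see [read_events()]).
#' @return a `spim_device` environment.
#' @export
sim_buttons <- function(events = NULL) {
  dev <- new_device("buttons", "sim_buttons")
  dev$queue <- events
  dev$cursor <- 0L
  dev$init <- function() { dev$initialized <- TRUE; invisible(dev) }
  dev$close <- function() { dev$initialized <- FALSE; invisible(dev) }
  dev$push <- function(events) {
    dev$queue <- if (is.null(dev$queue)) events else rbind(dev$queue, events)
    invisible(dev)
  }
  dev$poll <- function() {
    if (is.null(dev$queue) || dev$cursor >= nrow(dev$queue)) return(NULL)
    dev$cursor <- dev$cursor + 1L
    dev$queue[dev$cursor, , drop = FALSE]
  }
  dev
}

init_all <- function(devices) {
  for (d in devices) d$init()
  invisible(devices)
}

# best-effort close: a device failing to close must not prevent the others
# from closing
close_all <- function(devices, on_error = NULL) {
  for (d in devices) {
    tryCatch(d$close(), error = function(e) {
      if (!is.null(on_error)) on_error(d, e)
    })
  }
  invisible(devices)
}
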