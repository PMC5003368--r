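#' @importFrom stats rnorm runif
#' @importFrom utils modifyList head tail
NULL

#' Maximum pixel intensity of the virtual instrument (8-bit)
#' @export
IMAX <- 255L

# first argument first, so dim attributes survive pmin/pmax
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `expr`, and
#' restores the previous state, so seeded components never perturb a user's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Run expr under a device's private RNG stream (stored in the device env),
# leaving the global stream untouched afterwards.
rng_do <- function(dev, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(dev$rng_state)) set.seed(dev$rng_seed)
  else assign(".Random.seed", dev$rng_state, envir = globalenv())
  val <- expr
  dev$rng_state <- get(".Random.seed", envir = globalenv())
  val
}

#' Signal a hardware error
#'
#' Hardware errors are classed conditions (`hardware_error`) carrying the
#' device name and the phase (`init`, `operate`, `close`) in which the failure
#' occurred; the supervisor catches them and converts them into mode decisions
#' or exit codes.
#'
#' @param device device name, one of `"camera"`, `"stage"`, `"laser"`,
#'   `"buttons"`.
#' @param phase one of `"init"`, `"operate"`, `"close"`.
#' @param message human-readable description.
#' @export
hardware_error <- function(device, phase, message = "injected fault") {
  stopifnot(device %in% c("camera", "stage", "laser", "buttons"),
            phase %in% c("init", "operate", "close"))
  stop(structure(
    class = c("hardware_error", "error", "condition"),
    list(message = sprintf("[%s/%s] %s", device, phase, message),
         call = sys.call(-1), device = device, phase = phase)))
}

is_hardware_error <- function(x) inherits(x, "hardware_error")

stop_invalid <- function(fmt, ...) {
  stop(structure(
    class = c("invalid_argument", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stop_format <- function(fmt, ...) {
  stop(structure(
    class = c("format_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
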