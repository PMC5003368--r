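#' Construct an image volume
#'
#' A volume is the virtual specimen served by the simulated camera: a 3D
#' 8-bit intensity grid indexed `(z, y, x)` with z plane 0 the most dorsal
#' plane, plus a channel tag and an axial plane spacing in arbitrary units.
#'
#' @param data integer-valued 3D array with `dim = c(nz, ny, nx)`, values in
#'   `[0, IMAX]`.
#' @param channel `"fluorescence"` or `"transmission"`.
#' @param z_spacing axial units per plane (any positive number).
#' @param meta optional list of generator metadata (vessel centrelines etc.).
#' @return an object of class `spim_volume` with fields `data`, `channel`,
#'   `nz`, `ny`, `nx`, `z_spacing`, `meta`.
#' @export
spim_volume <- function(data, channel = c("fluorescence", "transmission"),
                        z_spacing = 1, meta = list()) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3L) stop_invalid("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop_invalid("all volume dimensions must be >= 1")
  if (min(data) < 0 || max(data) > IMAX)
    stop_invalid("intensities must lie in [0, %d]", IMAX)
  storage.mode(data) <- "integer"
  structure(list(data = data, channel = channel,
                 nz = dim(data)[1L], ny = dim(data)[2L], nx = dim(data)[3L],
                 z_spacing = z_spacing, meta = meta),
            class = "spim_volume")
}

#' @export
print.spim_volume <- function(x, ...) {
  cat(sprintf("<spim_volume %s: %d x %d x %d (z,y,x), range [%d, %d]>\n",
              x$channel, x$nz, x$ny, x$nx, min(x$data), max(x$data)))
  invisible(x)
}

# One correlated 3D random walk confined to the interior of the body
# ellipsoid. Points are continuous (x, y, z) voxel coordinates, 0-based.
vessel_path <- function(nx, ny, nz, step = 0.5, kappa = 0.25) {
  centre <- (c(nx, ny, nz) - 1) / 2
  semi <- 0.46 * c(nx, ny, nz)
  # keep the centreline far enough inside the silhouette that the whole
  # rendered tube (core + Gaussian skirt) stays within it
  rho_max <- max(0.3, 1 - 6 / min(semi))
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  p <- centre + semi * (0.8 * rho_max) * u * runif(1)^(1 / 3)
  d <- rnorm(3); d <- d / sqrt(sum(d^2))
  n_steps <- 4L * max(nx, ny, nz)
  pts <- matrix(0, n_steps + 1L, 3L)
  pts[1L, ] <- p
  for (i in seq_len(n_steps)) {
    d <- d + kappa * rnorm(3)
    d <- d / sqrt(sum(d^2))
    q <- p + step * d
    if (sqrt(sum(((q - centre) / semi)^2)) > rho_max) {
      d <- (centre - p) + 0.2 * rnorm(3)
      d <- d / sqrt(sum(d^2))
      q <- p + step * d
    }
    p <- q
    pts[i + 1L, ] <- p
  }
  pts
}

# Tube intensity profile: saturated core of radius `core`, Gaussian skirt of
# width sigma, cut off at core + 3*sigma. d may be a vector.
tube_profile <- function(d, sigma, core = 0.9) {
  out <- ifelse(d <= core, as.numeric(IMAX),
                IMAX * exp(-(d - core)^2 / (2 * sigma^2)))
  out[d > core + 3 * sigma] <- 0
  out
}

# Rasterise one centreline into a full-volume intensity field: minimum
# distance from each voxel centre to the sampled centreline, then the tube
# profile of that distance. Only voxels within the profile's support are
# touched.
rasterize_vessel <- function(dims, pts, radius, core = 0.9) {
  nz <- dims[1L]; ny <- dims[2L]; nx <- dims[3L]
  sigma <- radius / 2
  reach <- core + 3 * sigma
  d2 <- array(Inf, c(nz, ny, nx))
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1L]; py <- pts[i, 2L]; pz <- pts[i, 3L]
    xs <- max(0L, floor(px - reach)):min(nx - 1L, ceiling(px + reach))
    ys <- max(0L, floor(py - reach)):min(ny - 1L, ceiling(py + reach))
    zs <- max(0L, floor(pz - reach)):min(nz - 1L, ceiling(pz + reach))
    if (xs[1L] > xs[length(xs)] || ys[1L] > ys[length(ys)] ||
        zs[1L] > zs[length(zs)]) next
    cube <- outer(outer((zs - pz)^2, (ys - py)^2, "+"), (xs - px)^2, "+")
    d2[zs + 1L, ys + 1L, xs + 1L] <-
      pmin(d2[zs + 1L, ys + 1L, xs + 1L], cube)
  }
  field <- array(0, c(nz, ny, nx))
  fin <- is.finite(d2)
  field[fin] <- tube_profile(sqrt(d2[fin]), sigma, core)
  field
}

# Normalised ellipsoid radius of every voxel centre; <= 1 inside the body.
body_rho <- function(nz, ny, nx) {
  centre <- (c(nx, ny, nz) - 1) / 2
  semi <- 0.46 * c(nx, ny, nz)
  zr <- ((seq_len(nz) - 1 - centre[3L]) / semi[3L])^2
  yr <- ((seq_len(ny) - 1 - centre[2L]) / semi[2L])^2
  xr <- ((seq_len(nx) - 1 - centre[1L]) / semi[1L])^2
  sqrt(outer(outer(zr, yr, "+"), xr, "+"))
}

#' Generate the synthetic two-channel specimen
#'
#' Builds a phantom emulating a fluorescently labelled zebrafish: the
#' fluorescence channel holds bright vessel-like tubes (correlated 3D random
#' walks with a saturated-core/Gaussian-skirt cross-section, tube radius
#' 1 to 3 voxels) on a dark noisy background; the transmission (bright-field)
#' channel holds a bright background with a darker ellipsoidal body
#' silhouette that encloses all vessels. Identical arguments give
#' bit-identical output.
#'
#' @param nx,ny,nz plane width, height and plane count (all >= 1).
#' @param n_vessels number of vessel centrelines (>= 0).
#' @param seed integer seed; the generator never disturbs the caller's RNG
#'   stream.
#' @param z_spacing axial units per plane.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param background fluorescence background level (intensity units).
#' @return a list with elements `fluorescence` and `transmission`, both
#'   [spim_volume] objects of identical dimensions. The fluorescence volume's
#'   `meta` field records the vessel centrelines (`paths`), `radii` and the
#'   core radius used, so independent rasterisation oracles can replay them.
#' @examples
#' ph <- generate_phantom(32, 32, 16, n_vessels = 2, seed = 1)
#' ph$fluorescence
#' @export
generate_phantom <- function(nx, ny, nz, n_vessels = 5, seed = 1,
                             z_spacing = 1, noise_sd = 2, background = 5) {
  for (d in c(nx, ny, nz))
    if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d))
      stop_invalid("dimensions must be positive integers")
  if (n_vessels < 0) stop_invalid("n_vessels must be >= 0")
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  dims <- c(nz, ny, nx)
  n_vox <- prod(dims)
  core <- 0.9
  with_seed(seed, {
    paths <- lapply(seq_len(n_vessels), function(i) vessel_path(nx, ny, nz))
    radii <- if (n_vessels > 0) runif(n_vessels, 1, 3) else numeric(0)
    vessels <- array(0, dims)
    for (k in seq_len(n_vessels))
      vessels <- pmax(vessels, rasterize_vessel(dims, paths[[k]], radii[k], core))
    fluo_noise <- rnorm(n_vox, 0, noise_sd)
    trans_noise <- rnorm(n_vox, 0, noise_sd)
  })
  fluo <- clamp(round(pmax(vessels, background + fluo_noise)), 0, IMAX)
  rho <- body_rho(nz, ny, nx)
  trans_base <- ifelse(rho <= 1, 0.35 * IMAX, 0.9 * IMAX)
  trans <- clamp(round(trans_base + trans_noise), 0, IMAX)
  list(
    fluorescence = spim_volume(fluo, "fluorescence", z_spacing,
                               meta = list(paths = paths, radii = radii,
                                           core = core, seed = seed)),
    transmission = spim_volume(trans, "transmission", z_spacing)
  )
}

#' Save / load a volume as a multi-page TIFF
#'
#' One grayscale 8-bit page per z plane, in z-ascending order, the standard
#' exchange format for microscopy stacks. `load_volume(save_volume(v, p))`
#' reproduces `v`'s voxel data bit-exactly.
#'
#' @param volume a [spim_volume].
#' @param path file path (`.tif`).
#' @return `save_volume` returns `path` invisibly; `load_volume` returns a
#'   [spim_volume].
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "spim_volume"))
  pages <- lapply(seq_len(volume$nz),
                  function(z) volume$data[z, , , drop = TRUE] / IMAX)
  pages <- lapply(pages, function(p) matrix(p, volume$ny, volume$nx))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @param channel channel tag to attach to the loaded volume.
#' @param z_spacing axial spacing to attach.
#' @rdname save_volume
#' @export
load_volume <- function(path, channel = "fluorescence", z_spacing = 1) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_format("unreadable TIFF %s: %s",
                                                    path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_format("TIFF pages of differing shapes in %s", path)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L && dim(p)[3L] > 1L,
                 TRUE)))
    stop_format("expected grayscale pages in %s", path)
  nz <- length(pages); ny <- dim(pages[[1L]])[1L]; nx <- dim(pages[[1L]])[2L]
  data <- array(0L, c(nz, ny, nx))
  for (z in seq_len(nz)) data[z, , ] <- as.integer(round(pages[[z]] * IMAX))
  spim_volume(data, channel, z_spacing)
}

#' Generate-and-cache the pre-acquired example dataset
#'
#' The simulating (fall-back) tier of the instrument serves a pre-acquired
#' dataset. Here it is generated once and cached on disk as
#' `phantom_fluo.tif` / `phantom_trans.tif`; subsequent calls load the cache
#' unchanged. A corrupted or dimension-mismatched cache is regenerated and
#' overwritten. If the cache directory is unwritable, the freshly generated
#' pair is still returned (with a warning) so the session can proceed.
#'
#' @param dir cache directory.
#' @param dims `c(nx, ny, nz)` phantom dimensions.
#' @param n_vessels,seed passed to [generate_phantom()].
#' @return list with `fluorescence` and `transmission` volumes.
#' @export
ensure_dataset <- function(dir, dims = c(64L, 64L, 32L), n_vessels = 5,
                           seed = 1) {
  f_path <- file.path(dir, "phantom_fluo.tif")
  t_path <- file.path(dir, "phantom_trans.tif")
  cached <- tryCatch({
    fl <- load_volume(f_path, "fluorescence")
    tr <- load_volume(t_path, "transmission")
    ok <- identical(c(fl$nx, fl$ny, fl$nz), as.integer(dims)) &&
      identical(c(tr$nx, tr$ny, tr$nz), as.integer(dims))
    if (ok) list(fluorescence = fl, transmission = tr) else NULL
  }, error = function(e) NULL)
  if (!is.null(cached)) return(cached)
  pair <- generate_phantom(dims[1L], dims[2L], dims[3L],
                           n_vessels = n_vessels, seed = seed)
  tryCatch({
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    save_volume(pair$fluorescence, f_path)
    save_volume(pair$transmission, t_path)
  }, error = function(e)
    warning(sprintf("phantom cache not writable (%s); serving from memory",
                    conditionMessage(e)), call. = FALSE))
  pair
}
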