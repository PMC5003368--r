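#' Acquired 2D frame
#'
#' @param pixels ny x nx integer matrix in `[0, IMAX]`.
#' @param channel `"fluorescence"` or `"transmission"`.
#' @param z_index axial plane index (0-based).
#' @param t_ms acquisition timestamp in session milliseconds.
#' @return object of class `spim_frame`.
#' @export
spim_frame <- function(pixels, channel, z_index, t_ms = NA_real_) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, channel = channel,
                 z_index = as.integer(z_index), t_ms = t_ms),
            class = "spim_frame")
}

#' @export
print.spim_frame <- function(x, ...) {
  cat(sprintf("<spim_frame %s z=%d, %d x %d>\n", x$channel, x$z_index,
              nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Ordered z-series of fluorescence frames
#'
#' Frames must be z-ascending and contiguous, spanning exactly
#' `[z_min, z_max]` of the acquisition bounding box.
#'
#' @param frames list of [spim_frame]s, z-ascending.
#' @param z_min,z_max bounding box of the sweep.
#' @return object of class `spim_stack`.
#' @export
spim_stack <- function(frames, z_min, z_max) {
  z_min <- as.integer(z_min); z_max <- as.integer(z_max)
  if (length(frames) != z_max - z_min + 1L)
    stop_invalid("stack must hold z_max - z_min + 1 frames")
  zs <- vapply(frames, function(f) f$z_index, integer(1))
  if (!identical(zs, seq.int(z_min, z_max)))
    stop_invalid("stack frames must be contiguous and z-ascending")
  structure(list(frames = frames, z_min = z_min, z_max = z_max),
            class = "spim_stack")
}

#' @export
print.spim_stack <- function(x, ...) {
  cat(sprintf("<spim_stack %d planes, z in [%d, %d]>\n",
              length(x$frames), x$z_min, x$z_max))
  invisible(x)
}

#' Squared-intensity transparency law
#'
#' Each rendered pixel's opacity is proportional to the square of its
#' intensity, so dim haze is nearly transparent while bright vessels occlude
#' what lies behind them: `alpha = (I / IMAX)^2`.
#'
#' @param intensity intensities in `[0, IMAX]` (vectorised).
#' @return alpha values in `[0, 1]`.
#' @examples
#' alpha_of(c(0, IMAX / 2, IMAX))  # 0, 0.25, 1
#' @export
alpha_of <- function(intensity) {
  if (any(intensity < 0 | intensity > IMAX))
    stop_invalid("intensity outside [0, %d]", IMAX)
  (intensity / IMAX)^2
}

#' Pre-calculated per-plane depth colours
#'
#' One distinct colour per axial plane, so depth remains visible after the
#' stack is flattened into a single 2D rendering. The default map is a
#' blue-to-red hue ramp (dorsal blue, ventral red); any palette name accepted
#' by [grDevices::hcl.colors()] may be used instead.
#'
#' @param nz number of planes (>= 1).
#' @param colormap `"bluered"` or an `hcl.colors` palette name.
#' @return object of class `depth_lut`: an `nz` x 3 matrix of RGB rows in
#'   `[0, 1]`.
#' @export
depth_luts <- function(nz, colormap = "bluered") {
  if (nz < 1) stop_invalid("nz must be >= 1")
  f <- if (nz == 1L) 0 else (seq_len(nz) - 1) / (nz - 1)
  pals <- grDevices::hcl.pals()
  hit <- match(tolower(colormap), tolower(pals))
  if (identical(colormap, "bluered")) {
    cols <- grDevices::hsv(h = (2 / 3) * (1 - f), s = 1, v = 1)
  } else if (!is.na(hit)) {
    ramp <- grDevices::hcl.colors(max(nz, 2L), palette = pals[hit])
    cols <- ramp[round(f * (length(ramp) - 1)) + 1L]
  } else {
    stop_invalid("unknown colormap '%s'", colormap)
  }
  lut <- t(grDevices::col2rgb(cols)) / 255
  dimnames(lut) <- list(NULL, c("r", "g", "b"))
  class(lut) <- c("depth_lut", class(lut))
  lut
}

#' Rendered screen content
#'
#' @param rgb H x W x 3 array with components in `[0, 1]`.
#' @param mode `"preview"`, `"stack"`, `"info"` or `"emergency"`.
#' @param indicator optional [plane_indicator()] descriptor.
#' @return object of class `spim_view`.
#' @export
spim_view <- function(rgb, mode = c("preview", "stack", "info", "emergency"),
                      indicator = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  if (min(rgb) < 0 || max(rgb) > 1)
    stop_invalid("colour components must lie in [0, 1]")
  structure(list(rgb = rgb, mode = mode, indicator = indicator),
            class = "spim_view")
}

#' @export
print.spim_view <- function(x, ...) {
  cat(sprintf("<spim_view %s, %d x %d>\n", x$mode, dim(x$rgb)[1L], dim(x$rgb)[2L]))
  invisible(x)
}

# Bilinear resampling of a matrix by scale factor s about the canvas centre,
# onto an H x W canvas; source pixels outside the matrix contribute 0.
# With s = 1 and canvas == source dimensions this is the exact identity.
resample_plane <- function(mat, s, H, W) {
  h <- nrow(mat); w <- ncol(mat)
  yi <- (seq_len(H) - 1 - (H - 1) / 2) / s + (h - 1) / 2
  xi <- (seq_len(W) - 1 - (W - 1) / 2) / s + (w - 1) / 2
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  # gather with zero padding: index helper maps out-of-range to 0 value
  at <- function(r, c) {
    # r, c: integer matrices (0-based)
    ok <- r >= 0 & r < h & c >= 0 & c < w
    out <- matrix(0, nrow(r), ncol(r))
    out[ok] <- mat[cbind(r[ok] + 1L, c[ok] + 1L)]
    out
  }
  R0 <- matrix(y0, H, W); C0 <- matrix(x0, H, W, byrow = TRUE)
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  at(R0, C0) * (1 - FY) * (1 - FX) +
    at(R0 + 1L, C0) * FY * (1 - FX) +
    at(R0, C0 + 1L) * (1 - FY) * FX +
    at(R0 + 1L, C0 + 1L) * FY * FX
}

# Linear axial scale function: s_front at z_min (front), s_back at z_max.
axial_scale <- function(z_min, z_max, s_front = 1, s_back = 0.85) {
  force(z_min); force(z_max)
  function(z) {
    if (z_max == z_min) return(s_front)
    f <- (z - z_min) / (z_max - z_min)
    s_front + f * (s_back - s_front)
  }
}

#' Depth-coded alpha compositing of a stack
#'
#' The stack-mode rendering pipeline: planes are taken back to front (from
#' `z_max` down to `z_min`), each resampled by its axial scale factor about
#' the canvas centre, coloured with its depth LUT entry, and blended onto the
#' canvas with the over operator using the squared-intensity transparency
#' `alpha = (I/IMAX)^2`:
#' `out <- alpha * (c_z * I/IMAX) + (1 - alpha) * out` over a black
#' background. A progress callback sees the partial composite after each
#' plane, which is how the live display stays continuously updated during
#' acquisition.
#'
#' @param stack a [spim_stack].
#' @param lut a [depth_luts()] table with at least as many rows as the
#'   phantom has planes (indexed by absolute `z_index`).
#' @param scale per-plane scale: a function of z, or `NULL` for the default
#'   linear [axial_scale] over the stack's range.
#' @param canvas `c(H, W)` output size; defaults to the plane size.
#' @param on_plane optional callback `function(view, z)` fired after each
#'   plane is composited.
#' @return a [spim_view] with mode `"stack"`.
#' @export
composite_stack <- function(stack, lut, scale = NULL, canvas = NULL,
                            on_plane = NULL) {
  stopifnot(inherits(stack, "spim_stack"))
  if (nrow(lut) < stack$z_max + 1L)
    stop_invalid("depth LUT has %d entries but stack reaches plane %d",
                 nrow(lut), stack$z_max)
  f1 <- stack$frames[[1L]]
  if (is.null(canvas)) canvas <- dim(f1$pixels)
  H <- canvas[1L]; W <- canvas[2L]
  if (is.null(scale)) scale <- axial_scale(stack$z_min, stack$z_max)
  out <- array(0, c(H, W, 3L))
  for (z in seq.int(stack$z_max, stack$z_min)) {
    fr <- stack$frames[[z - stack$z_min + 1L]]
    I <- resample_plane(fr$pixels, scale(z), H, W)
    I <- clamp(I, 0, IMAX)
    a <- alpha_of(I)
    i_norm <- I / IMAX
    cz <- lut[z + 1L, ]
    for (ch in 1:3)
      out[, , ch] <- a * (cz[ch] * i_norm) + (1 - a) * out[, , ch]
    if (!is.null(on_plane))
      on_plane(spim_view(clamp(out, 0, 1), "stack"), z)
  }
  spim_view(clamp(out, 0, 1), "stack")
}

# Draw a straight line segment (grey level or rgb vector) into an rgb array.
draw_segment <- function(rgb, x0, y0, x1, y1, col) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  xs <- round(seq(x0, x1, length.out = n))
  ys <- round(seq(y0, y1, length.out = n))
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
  for (ch in 1:3) rgb[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  rgb
}

# Receding coordinate box: front rectangle at s_front, back rectangle at
# s_back, connected at the corners; drawn in grey so it never adds colour
# saturation to the preview.
draw_coordinate_box <- function(rgb, h, w, s_front, s_back, grey = 0.35) {
  H <- dim(rgb)[1L]; W <- dim(rgb)[2L]
  rect <- function(s) {
    hh <- s * h / 2; ww <- s * w / 2
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    list(x = c(cx - ww, cx + ww, cx + ww, cx - ww),
         y = c(cy - hh, cy - hh, cy + hh, cy + hh))
  }
  fr <- rect(s_front); bk <- rect(s_back)
  col <- rep(grey, 3)
  for (i in 1:4) {
    j <- if (i == 4L) 1L else i + 1L
    rgb <- draw_segment(rgb, bk$x[i], bk$y[i], bk$x[j], bk$y[j], col)
    rgb <- draw_segment(rgb, bk$x[i], bk$y[i], fr$x[i], fr$y[i], col)
    rgb <- draw_segment(rgb, fr$x[i], fr$y[i], fr$x[j], fr$y[j], col)
  }
  rgb
}

#' Preview-mode rendering
#'
#' The live single-plane display: the transmission image is rendered in
#' grey, the fluorescence signal is overlaid additively on the green channel
#' (clipped at 1), and the result is scaled linearly with the current axial
#' position (front plane largest) and centred on the canvas over a receding
#' grey coordinate box, which gives a 3D impression while the user moves the
#' imaging plane.
#'
#' @param transmission,fluorescence co-registered [spim_frame]s (same shape
#'   and z).
#' @param z current axial plane index.
#' @param z_range `c(z_min, z_max)`.
#' @param canvas `c(H, W)` output size; defaults to 1.3 x the plane size.
#' @param s_front,s_back scale at the front (`z_min`) and back (`z_max`)
#'   plane.
#' @param indicator optional [plane_indicator()] descriptor to attach.
#' @return a [spim_view] with mode `"preview"`.
#' @export
render_preview <- function(transmission, fluorescence, z, z_range,
                           canvas = NULL, s_front = 1, s_back = 0.85,
                           indicator = NULL) {
  if (!identical(dim(transmission$pixels), dim(fluorescence$pixels)))
    stop_invalid("transmission and fluorescence frames differ in shape")
  h <- nrow(transmission$pixels); w <- ncol(transmission$pixels)
  if (is.null(canvas)) canvas <- c(ceiling(1.3 * h), ceiling(1.3 * w))
  H <- canvas[1L]; W <- canvas[2L]
  s <- axial_scale(z_range[1L], z_range[2L], s_front, s_back)(z)
  grey <- resample_plane(transmission$pixels / IMAX, s, H, W)
  green <- resample_plane(fluorescence$pixels / IMAX, s, H, W)
  grey <- clamp(grey, 0, 1); green <- clamp(green, 0, 1)
  rgb <- array(0, c(H, W, 3L))
  rgb <- draw_coordinate_box(rgb, h, w, s_front, s_back)
  # paste the scaled plane opaquely over the box region it covers
  hh <- s * h / 2; ww <- s * w / 2
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rows <- which(seq_len(H) >= cy - hh & seq_len(H) <= cy + hh)
  cols <- which(seq_len(W) >= cx - ww & seq_len(W) <= cx + ww)
  for (ch in 1:3) rgb[rows, cols, ch] <- grey[rows, cols]
  rgb[rows, cols, 2L] <- clamp(grey[rows, cols] + green[rows, cols], 0, 1)
  spim_view(rgb, "preview", indicator = indicator)
}

#' Schematic position indicator
#'
#' Normalised coordinates of the current imaging plane and vertical sample
#' position inside the bounding box, plus a schematic wireframe of the
#' specimen, for the small 3D model drawn next to the rendering. Fraction 0
#' corresponds to the dorsal-most plane / lower vertical limit.
#'
#' @param z,z_range current plane and `c(z_min, z_max)`.
#' @param vertical,v_range current vertical position and `c(v_min, v_max)`.
#' @return a list with `z_fraction`, `v_fraction` and `wireframe` (a list of
#'   normalised segments sketching the body outline and the current plane).
#' @export
plane_indicator <- function(z, z_range, vertical, v_range) {
  zf <- if (z_range[2L] == z_range[1L]) 0
  else (z - z_range[1L]) / (z_range[2L] - z_range[1L])
  vf <- if (v_range[2L] == v_range[1L]) 0
  else (vertical - v_range[1L]) / (v_range[2L] - v_range[1L])
  theta <- seq(0, 2 * pi, length.out = 33L)
  body <- cbind(0.5 + 0.45 * cos(theta), 0.5 + 0.2 * sin(theta))
  plane_y <- 0.3 + 0.4 * zf
  list(z_fraction = zf, v_fraction = vf,
       wireframe = list(body_outline = body,
                        plane = rbind(c(0.05, plane_y), c(0.95, plane_y))))
}

#' Acquire a z-stack with live compositing
#'
#' Stack mode: the laser is switched on, the stage sweeps the axial bounding
#' box from back (`z_max`) to front (`z_min`), one fluorescence frame is
#' captured per plane, and the depth-coded composite grows plane by plane
#' (the callback sees each partial rendering). Afterwards the stage returns
#' to its pre-stack plane and the laser is restored to its previous state.
#' Device errors propagate to the caller; a partial stack is discarded.
#'
#' @param session a session from [start_session()].
#' @param on_plane optional progress callback `function(view, z)`.
#' @param t_ms acquisition timestamp (session milliseconds).
#' @return `list(stack = spim_stack, view = spim_view)`.
#' @export
acquire_stack <- function(session, on_plane = NULL, t_ms = NA_real_) {
  devs <- session$devices
  cfg <- session$config
  z0 <- devs$stage$position()$z_plane
  laser_was_on <- devs$laser$is_on()
  devs$laser$on()
  frames <- vector("list", cfg$z_max - cfg$z_min + 1L)
  restore <- function() {
    cur <- devs$stage$position()$z_plane
    if (cur != z0) devs$stage$move("axial", z0 - cur)
    if (!laser_was_on) devs$laser$off()
  }
  partial <- vector("list", length(frames))
  res <- tryCatch({
    for (z in seq.int(cfg$z_max, cfg$z_min)) {
      cur <- devs$stage$position()$z_plane
      if (cur != z) devs$stage$move("axial", z - cur)
      frames[[z - cfg$z_min + 1L]] <- devs$camera$snap("fluorescence", t_ms)
    }
    stack <- spim_stack(frames, cfg$z_min, cfg$z_max)
    view <- composite_stack(stack, session$lut,
                            canvas = cfg$canvas_px, on_plane = on_plane)
    list(stack = stack, view = view)
  }, error = function(e) { restore(); stop(e) })
  restore()
  res
}

#' Export a stack as a multi-page TIFF
#'
#' Raw fluorescence planes, z-ascending, 8-bit grayscale.
#'
#' @param stack a [spim_stack].
#' @param path output path.
#' @export
save_stack <- function(stack, path) {
  pages <- lapply(stack$frames, function(f) f$pixels / IMAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Load a stack exported by [save_stack()]
#'
#' @param path multi-page TIFF path.
#' @param z_min z index of the first page.
#' @return a [spim_stack].
#' @export
load_stack <- function(path, z_min = 0L) {
  vol <- load_volume(path, "fluorescence")
  frames <- lapply(seq_len(vol$nz), function(i)
    spim_frame(matrix(vol$data[i, , ], vol$ny, vol$nx), "fluorescence",
               z_min + i - 1L))
  spim_stack(frames, z_min, z_min + vol$nz - 1L)
}

#' Write a rendered view to PNG
#'
#' @param view a [spim_view].
#' @param path output path.
#' @export
write_view_png <- function(view, path) {
  png::writePNG(view$rgb, path)
  invisible(path)
}

# Static informational screen: dark blue background, light panel.
info_view <- function(canvas = c(192L, 192L)) {
  H <- canvas[1L]; W <- canvas[2L]
  rgb <- array(0, c(H, W, 3L))
  rgb[, , 3L] <- 0.25
  r <- round(H * 0.15):round(H * 0.85); c <- round(W * 0.1):round(W * 0.9)
  for (ch in 1:3) rgb[r, c, ch] <- 0.85
  rgb[round(H * 0.2):round(H * 0.3), c, 1L] <- 0.1
  rgb[round(H * 0.2):round(H * 0.3), c, 2L] <- 0.3
  rgb[round(H * 0.2):round(H * 0.3), c, 3L] <- 0.5
  spim_view(rgb, "info")
}

# Emergency screen shown in fatal mode: red field with a white cross, asking
# for the visitor's patience until the device is repaired.
emergency_view <- function(canvas = c(192L, 192L)) {
  H <- canvas[1L]; W <- canvas[2L]
  rgb <- array(0, c(H, W, 3L))
  rgb[, , 1L] <- 0.55
  band_r <- round(H * 0.45):round(H * 0.55)
  band_c <- round(W * 0.45):round(W * 0.55)
  for (ch in 1:3) {
    rgb[band_r, round(W * 0.2):round(W * 0.8), ch] <- 1
    rgb[round(H * 0.2):round(H * 0.8), band_c, ch] <- 1
  }
  spim_view(rgb, "emergency")
}
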