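# Independent oracles and fixture builders shared by the suite. Oracles are
# deliberately naive (quadratic scans, voxel-by-voxel loops) and share no
# code with the implementation paths they check.

# O(n^2)-style debounce oracle: for every event, scan all previously
# accepted switches on the same button.
debounce_oracle <- function(events, refractory_ms) {
  n <- nrow(events)
  acc_t <- numeric(n); acc_b <- character(n); k <- 0L
  out <- logical(n)
  for (i in seq_len(n)) {
    t <- events$t_ms[i]; b <- events$button[i]
    prev_t <- acc_t[seq_len(k)]; prev_b <- acc_b[seq_len(k)]
    # full scan over every previously accepted switch; an accepted switch at
    # exactly t - refractory_ms does not block (open window), one at t does
    blocked <- any(prev_b == b & prev_t > t - refractory_ms & prev_t <= t)
    if (!blocked) {
      k <- k + 1L
      acc_t[k] <- t; acc_b[k] <- b
      out[i] <- events$edge[i] == "press"
    }
  }
  res <- events[out, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-pixel over-operator oracle for back-to-front compositing (no
# resampling; canvas == plane size, scale = 1).
composite_oracle <- function(stack, lut) {
  h <- nrow(stack$frames[[1]]$pixels); w <- ncol(stack$frames[[1]]$pixels)
  out <- array(0, c(h, w, 3))
  for (y in seq_len(h)) for (x in seq_len(w)) {
    px <- c(0, 0, 0)
    for (z in seq.int(stack$z_max, stack$z_min)) {
      I <- stack$frames[[z - stack$z_min + 1]]$pixels[y, x]
      a <- (I / 255)^2
      cz <- lut[z + 1, ]
      px <- a * (cz * I / 255) + (1 - a) * px
    }
    out[y, x, ] <- px
  }
  out
}

# Voxel-by-voxel rasterisation of vessel centrelines, replaying the paths
# and radii recorded in a phantom's metadata: min distance to the sampled
# centreline per vessel, saturated-core/Gaussian-skirt profile, max over
# vessels.
rasterise_oracle <- function(meta, nz, ny, nx) {
  field <- array(0, c(nz, ny, nx))
  for (k in seq_along(meta$paths)) {
    pts <- meta$paths[[k]]
    sigma <- meta$radii[k] / 2
    core <- meta$core
    for (z in 0:(nz - 1)) for (y in 0:(ny - 1)) for (x in 0:(nx - 1)) {
      d2 <- min((pts[, 1] - x)^2 + (pts[, 2] - y)^2 + (pts[, 3] - z)^2)
      d <- sqrt(d2)
      I <- if (d > core + 3 * sigma) 0
      else if (d <= core) 255
      else 255 * exp(-(d - core)^2 / (2 * sigma^2))
      if (I > field[z + 1, y + 1, x + 1]) field[z + 1, y + 1, x + 1] <- I
    }
  }
  field
}

# Clamped random-walk replay for the stage.
clamped_walk_oracle <- function(start, deltas, lo, hi) {
  pos <- start
  for (d in deltas) pos <- min(hi, max(lo, pos + d))
  pos
}

# Random press/release event train over the seven buttons.
random_train <- function(n, t_max = 60000, buttons = BUTTONS) {
  t <- sort(sample(0:t_max, n, replace = TRUE))
  button_events(t, sample(buttons, n, replace = TRUE),
                sample(c("press", "release"), n, replace = TRUE,
                       prob = c(0.6, 0.4)))
}

# Small random stack over a shared LUT.
random_stack <- function(nz, ny, nx, z_min = 0) {
  frames <- lapply(seq_len(nz), function(i)
    spim_frame(matrix(sample(0:255, ny * nx, replace = TRUE), ny, nx),
               "fluorescence", z_min + i - 1))
  spim_stack(frames, z_min, z_min + nz - 1)
}

# Small session configuration sharing one phantom cache across tests so the
# dataset is generated once per suite run.
shared_cache <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "spimsim-test-cache")
      ensure_dataset(dir, c(24L, 24L, 8L), n_vessels = 3, seed = 11)
    }
    dir
  }
})

tiny_config <- function(sync_dir = tempfile("sync"), ...) {
  args <- utils::modifyList(
    list(phantom_dims = c(24L, 24L, 8L), z_max = 7L, n_vessels = 3L,
         seed = 11L, canvas_px = c(32L, 32L), v_max = 6L,
         data_dir = shared_cache(), sync_dir = sync_dir),
    list(...))
  do.call(spim_config, args)
}
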