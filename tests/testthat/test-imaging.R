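test_that("transparency follows the squared-intensity law", {
  expect_identical(alpha_of(0), 0)
  expect_identical(alpha_of(255), 1)
  expect_identical(alpha_of(255 / 2), 0.25)
  xs <- seq(0, 255, by = 5)
  expect_equal(alpha_of(xs), (xs / 255)^2)
  expect_error(alpha_of(-1), class = "invalid_argument")
  expect_error(alpha_of(256), class = "invalid_argument")
})

test_that("depth LUTs give one distinct colour per plane", {
  one <- depth_luts(1)
  expect_identical(dim(one), c(1L, 3L))
  two <- depth_luts(2)
  # endpoints are the colormap endpoints: blue and red for the default ramp
  expect_equal(two[1, ], c(r = 0, g = 0, b = 1))
  expect_equal(two[2, ], c(r = 1, g = 0, b = 0))
  expect_identical(depth_luts(64)[1, ], two[1, ])
  expect_identical(depth_luts(64)[64, ], two[2, ])

  for (nz in c(8, 64, 256)) {
    lut <- depth_luts(nz)
    expect_identical(nrow(unique(as.data.frame(unclass(lut)))), as.integer(nz))
  }
  lut2 <- depth_luts(16, "viridis")
  expect_identical(nrow(unique(as.data.frame(unclass(lut2)))), 16L)
  expect_error(depth_luts(8, "no-such-map"), class = "invalid_argument")
  expect_error(depth_luts(0), class = "invalid_argument")
})

test_that("degenerate composites: all-zero stack and single opaque pixel", {
  lut <- depth_luts(4)
  zero <- spim_stack(lapply(0:3, function(z)
    spim_frame(matrix(0L, 5, 5), "fluorescence", z)), 0, 3)
  v <- composite_stack(zero, lut)
  expect_true(all(v$rgb == 0))

  px <- matrix(0L, 5, 5); px[2, 3] <- 255L
  one <- spim_stack(list(spim_frame(px, "fluorescence", 2)), 2, 2)
  v2 <- composite_stack(one, lut, scale = function(z) 1)
  expect_equal(v2$rgb[2, 3, ], unname(lut[3, ]))  # alpha = 1: pure c_z
  expect_true(all(v2$rgb[-2, , ] == 0))
})

test_that("two-plane composite matches the closed-form over operator", {
  withr::with_seed(41, {
    lut <- depth_luts(2)
    for (rep in 1:20) {
      p1 <- matrix(sample(0:255, 16, TRUE), 4, 4)  # front, z = 0
      p2 <- matrix(sample(0:255, 16, TRUE), 4, 4)  # back,  z = 1
      st <- spim_stack(list(spim_frame(p1, "fluorescence", 0),
                            spim_frame(p2, "fluorescence", 1)), 0, 1)
      v <- composite_stack(st, lut, scale = function(z) 1)
      i1 <- p1 / 255; i2 <- p2 / 255
      a1 <- i1^2; a2 <- i2^2
      for (ch in 1:3) {
        closed <- a1 * lut[1, ch] * i1 + (1 - a1) * a2 * lut[2, ch] * i2
        expect_equal(v$rgb[, , ch], closed, tolerance = 1e-12)
      }
    }
  })
})

test_that("compositing equals the per-pixel oracle on random stacks", {
  withr::with_seed(43, {
    lut <- depth_luts(8)
    for (rep in 1:20) {
      st <- random_stack(8, 8, 8)
      v <- composite_stack(st, lut, scale = function(z) 1)
      expect_equal(v$rgb, composite_oracle(st, lut), tolerance = 1e-9)
    }
  })
})

test_that("opacity limits: full occlusion and the linear regime", {
  lut <- depth_luts(3)
  # all alpha = 1 (saturated planes): composite is the front plane's colour
  sat <- spim_stack(lapply(0:2, function(z)
    spim_frame(matrix(255L, 3, 3), "fluorescence", z)), 0, 2)
  v <- composite_stack(sat, lut, scale = function(z) 1)
  for (ch in 1:3) expect_equal(v$rgb[, , ch], matrix(lut[1, ch], 3, 3))

  # small alpha: composite approaches the alpha-weighted sum
  dim_planes <- spim_stack(lapply(0:2, function(z)
    spim_frame(matrix(10L, 3, 3), "fluorescence", z)), 0, 2)
  vd <- composite_stack(dim_planes, lut, scale = function(z) 1)
  a <- (10 / 255)^2; i <- 10 / 255
  for (ch in 1:3) {
    lin <- a * i * sum(lut[1:3, ch])
    expect_equal(vd$rgb[2, 2, ch], lin, tolerance = a * 2)
  }
})

test_that("front-plane brightening never lowers its composite contribution", {
  withr::with_seed(47, {
    lut <- depth_luts(4)
    st <- random_stack(4, 6, 6)
    base <- composite_stack(st, lut, scale = function(z) 1)$rgb
    for (I in c(40L, 120L, 200L, 255L)) {
      st2 <- st
      px <- st2$frames[[1]]$pixels
      prev <- px[3, 3]
      px[3, 3] <- max(prev, I)
      st2$frames[[1]]$pixels <- px
      v <- composite_stack(st2, lut, scale = function(z) 1)$rgb
      # the front plane's own colour share at that pixel is monotone in I
      a_old <- (prev / 255)^2; a_new <- (max(prev, I) / 255)^2
      contrib_old <- a_old * lut[1, ] * prev / 255
      contrib_new <- a_new * lut[1, ] * max(prev, I) / 255
      expect_true(all(contrib_new >= contrib_old - 1e-12))
      # and pixels elsewhere are untouched
      expect_equal(v[1, 1, ], base[1, 1, ])
    }
  })
})

test_that("progressive rendering ends bit-exactly at the returned composite", {
  withr::with_seed(53, {
    st <- random_stack(6, 8, 8)
    lut <- depth_luts(6)
    partials <- list()
    v <- composite_stack(st, lut, on_plane = function(view, z)
      partials[[length(partials) + 1]] <<- view)
    expect_length(partials, 6L)
    expect_identical(partials[[6]]$rgb, v$rgb)
  })
})

test_that("axial scaling in the preview is linear in z", {
  sc <- spimsim:::axial_scale(0, 10, s_front = 1, s_back = 0.85)
  expect_identical(sc(0), 1)
  expect_identical(sc(10), 0.85)
  expect_equal(sc(5), (1 + 0.85) / 2)
})

test_that("preview is grey without fluorescence, green where only signal", {
  trans <- spim_frame(matrix(180L, 10, 10), "transmission", 2)
  dark <- spim_frame(matrix(0L, 10, 10), "fluorescence", 2)
  v <- render_preview(trans, dark, 2, c(0, 7))
  # zero fluorescence: saturation 0 at every pixel (R = G = B)
  expect_equal(v$rgb[, , 1], v$rgb[, , 2])
  expect_equal(v$rgb[, , 2], v$rgb[, , 3])

  black <- spim_frame(matrix(0L, 10, 10), "transmission", 2)
  spot <- matrix(0L, 10, 10); spot[5, 5] <- 255L
  fl <- spim_frame(spot, "fluorescence", 2)
  v2 <- render_preview(black, fl, 2, c(0, 7), canvas = c(10, 10),
                       s_front = 1, s_back = 1)
  expect_equal(v2$rgb[5, 5, ], c(0, 1, 0))  # pure green

  expect_error(render_preview(trans,
                              spim_frame(matrix(0L, 4, 4), "fluorescence", 2),
                              2, c(0, 7)),
               class = "invalid_argument")
})

test_that("stack acquisition sweeps the box, reports progress, restores state", {
  cfg <- tiny_config(z_min = 3L, z_max = 7L)
  s <- start_session(cfg)
  z_before <- s$devices$stage$position()$z_plane
  calls <- 0L
  res <- acquire_stack(s, on_plane = function(view, z) calls <<- calls + 1L)
  expect_length(res$stack$frames, 5L)
  expect_identical(calls, 5L)
  zs <- vapply(res$stack$frames, function(f) f$z_index, integer(1))
  expect_identical(zs, 3:7)
  expect_identical(s$devices$stage$position()$z_plane, z_before)
  expect_false(s$devices$laser$is_on())

  # fallback sessions serve the static phantom: repeated stacks identical
  cfg2 <- tiny_config(z_min = 3L, z_max = 7L, faults = list(
    camera = fault_schedule(fail_on_init = TRUE, persistent = TRUE)))
  s2 <- start_session(cfg2)
  a <- acquire_stack(s2)
  b <- acquire_stack(s2)
  expect_identical(lapply(a$stack$frames, `[[`, "pixels"),
                   lapply(b$stack$frames, `[[`, "pixels"))
  expect_identical(a$view$rgb, b$view$rgb)
})

test_that("plane indicator reports normalised fractions", {
  expect_identical(plane_indicator(0, c(0, 10), 5, c(0, 10))$z_fraction, 0)
  expect_identical(plane_indicator(10, c(0, 10), 5, c(0, 10))$z_fraction, 1)
  expect_identical(plane_indicator(5, c(0, 10), 5, c(0, 10))$z_fraction, 0.5)
  ind <- plane_indicator(2, c(0, 4), 3, c(0, 6))
  expect_identical(ind$v_fraction, 0.5)
  expect_true(is.list(ind$wireframe))
  # degenerate single-plane range
  expect_identical(plane_indicator(0, c(0, 0), 0, c(0, 0))$z_fraction, 0)
})

test_that("stack TIFF export round-trips and renders via the CLI path", {
  cfg <- tiny_config()
  s <- start_session(cfg)
  res <- acquire_stack(s)
  p <- tempfile(fileext = ".tif")
  save_stack(res$stack, p)
  back <- load_stack(p, z_min = res$stack$z_min)
  expect_identical(lapply(back$frames, `[[`, "pixels"),
                   lapply(res$stack$frames, `[[`, "pixels"))
  out <- tempfile(fileext = ".png")
  code <- spim_main(c("render-stack", "--in", p, "--out", out))
  expect_identical(code, 0L)
  expect_true(file.exists(out))
})
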