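make_rig <- function(noise_sd = 0, exposure_ref = 10, seed = 1) {
  vols <- generate_phantom(12, 10, 6, n_vessels = 2, seed = 4)
  bbox <- list(z_min = 0L, z_max = 5L, v_min = 0L, v_max = 4L)
  stage <- sim_stage(bbox)
  laser <- sim_laser()
  cam <- sim_camera(vols, stage, laser, exposure_ref = exposure_ref,
                    noise_sd = noise_sd, seed = seed)
  init_all(list(stage, laser, cam))
  list(vols = vols, stage = stage, laser = laser, cam = cam, bbox = bbox)
}

test_that("noise-free snap at reference exposure is the phantom plane", {
  r <- make_rig()
  r$laser$on()
  r$cam$start_acquisition()
  z <- r$stage$position()$z_plane
  fr <- r$cam$snap("fluorescence")
  expect_identical(fr$pixels,
                   matrix(r$vols$fluorescence$data[z + 1, , ], 10, 12))
  expect_identical(fr$z_index, z)
  tr <- r$cam$snap("transmission")
  expect_identical(tr$pixels,
                   matrix(r$vols$transmission$data[z + 1, , ], 10, 12))
})

test_that("laser off yields only background in the fluorescence channel", {
  r <- make_rig()
  r$cam$start_acquisition()
  expect_false(r$laser$is_on())
  fr <- r$cam$snap("fluorescence")
  expect_true(all(fr$pixels < 0.8 * 255))
})

test_that("exposure scaling and snap-before-start contract hold", {
  r <- make_rig()
  r$laser$on()
  expect_error(r$cam$snap("fluorescence"), class = "invalid_argument")
  r$cam$start_acquisition()
  r$cam$set_exposure(5)  # half the reference -> half intensity
  z <- r$stage$position()$z_plane
  fr <- r$cam$snap("fluorescence")
  expect_identical(fr$pixels,
                   matrix(as.integer(round(
                     r$vols$fluorescence$data[z + 1, , ] * 0.5)), 10, 12))
  r$cam$set_exposure(40)  # above reference: clipped scaling at 1
  expect_identical(r$cam$snap("fluorescence")$pixels,
                   matrix(r$vols$fluorescence$data[z + 1, , ], 10, 12))
  expect_error(r$cam$set_exposure(0), class = "invalid_argument")
})

test_that("camera noise has the configured scale (noise-model check)", {
  r <- make_rig(noise_sd = 2, seed = 123)
  r$laser$on()
  r$cam$start_acquisition()
  z <- r$stage$position()$z_plane
  plane <- r$vols$transmission$data[z + 1, , ]
  n_snap <- 100
  means <- replicate(n_snap, mean(r$cam$snap("transmission")$pixels))
  # mean over pixels and snaps stays within 3 sigma / sqrt(n) of the truth
  # (rounding adds < 0.5/sqrt(n_pix) which is negligible at this scale)
  tol <- 3 * 2 / sqrt(n_snap) + 0.05
  expect_lt(abs(mean(means) - mean(plane)), tol)
})

test_that("stage clamps at the bounding box and moves invert", {
  r <- make_rig()
  st <- r$stage
  st$move("axial", 100)
  expect_identical(st$position()$z_plane, 5L)
  st$move("axial", 1)
  expect_identical(st$position()$z_plane, 5L)
  st$move("axial", -4)  # back to the interior, where moves invert exactly
  p0 <- st$position()
  st$move("axial", 3); st$move("axial", -3)
  expect_identical(st$position(), p0)
  expect_error(st$move("diagonal", 1), class = "invalid_argument")
})

test_that("a long clamped random walk matches the replay oracle", {
  withr::with_seed(99, {
    r <- make_rig()
    st <- r$stage
    deltas <- sample(c(-1L, 1L), 1000, replace = TRUE)
    start <- st$position()$z_plane
    for (d in deltas) st$move("axial", d)
    expect_identical(st$position()$z_plane,
                     clamped_walk_oracle(start, deltas, 0L, 5L))
    vdeltas <- sample(c(-1L, 1L), 1000, replace = TRUE)
    vstart <- st$position()$vertical_pos
    for (d in vdeltas) st$move("vertical", d)
    expect_identical(st$position()$vertical_pos,
                     clamped_walk_oracle(vstart, vdeltas, 0L, 4L))
  })
})

test_that("laser interface: state, power persistence, validation", {
  l <- sim_laser(); l$init()
  expect_false(l$is_on())
  l$set_power(0.4)
  l$on()
  expect_true(l$is_on())
  l$off(); l$on()
  expect_identical(l$power(), 0.4)  # power persists across on/off
  expect_error(l$set_power(1.5), class = "invalid_argument")
  expect_error(l$set_power(-0.1), class = "invalid_argument")
})

test_that("fault wrapper raises exactly per schedule", {
  r <- make_rig()
  w <- inject_faults(r$stage, fault_schedule(fail_after = 3))
  w$init()
  for (i in 1:3) expect_silent(w$move("axial", 0))
  expect_error(w$move("axial", 0), class = "hardware_error")
  # once tripped, every call raises until re-init clears it (transient)
  expect_error(w$position(), class = "hardware_error")
  w$close(); w$init()
  expect_silent(w$move("axial", 0))

  w2 <- inject_faults(sim_laser(), fault_schedule(fail_on_init = TRUE))
  err <- tryCatch(w2$init(), error = function(e) e)
  expect_s3_class(err, "hardware_error")
  expect_identical(err$phase, "init")
  w2$init()  # transient init fault: second attempt succeeds
  expect_true(w2$initialized)

  w3 <- inject_faults(sim_laser(),
                      fault_schedule(fail_on_init = TRUE, persistent = TRUE))
  expect_error(w3$init(), class = "hardware_error")
  expect_error(w3$init(), class = "hardware_error")
})

test_that("an empty schedule is a bit-identical passthrough", {
  withr::with_seed(7, {
    mk <- function(wrapped) {
      vols <- generate_phantom(8, 8, 4, n_vessels = 1, seed = 2)
      bbox <- list(z_min = 0L, z_max = 3L, v_min = 0L, v_max = 2L)
      stage <- sim_stage(bbox)
      laser <- sim_laser()
      cam <- sim_camera(vols, stage, laser, noise_sd = 1, seed = 5)
      if (wrapped) {
        stage <- inject_faults(stage, fault_schedule())
        cam <- inject_faults(cam, fault_schedule())
      }
      init_all(list(stage, laser, cam))
      laser$on(); cam$start_acquisition()
      list(stage = stage, cam = cam)
    }
    a <- mk(FALSE); b <- mk(TRUE)
    ops <- sample(c("move", "snap"), 100, replace = TRUE)
    deltas <- sample(-2:2, 100, replace = TRUE)
    for (i in seq_along(ops)) {
      if (ops[i] == "move") {
        expect_identical(a$stage$move("axial", deltas[i]),
                         b$stage$move("axial", deltas[i]))
      } else {
        expect_identical(a$cam$snap("fluorescence")$pixels,
                         b$cam$snap("fluorescence")$pixels)
      }
    }
  })
})

test_that("detection selects primary, all-or-nothing fallback, or fatal", {
  vols <- generate_phantom(8, 8, 4, n_vessels = 1, seed = 2)
  bbox <- list(z_min = 0L, z_max = 3L, v_min = 0L, v_max = 2L)
  registry <- local({
    mk <- function() {
      stage <- sim_stage(bbox); laser <- sim_laser()
      list(camera = sim_camera(vols, stage, laser), stage = stage,
           laser = laser, buttons = sim_buttons())
    }
    tiers <- list(primary = mk(), fallback = mk())
    out <- list()
    for (nm in names(tiers$primary)) {
      out[[nm]] <- local({
        n <- nm
        list(primary = function() tiers$primary[[n]],
             fallback = function() tiers$fallback[[n]])
      })
    }
    out
  })
  det <- detect_hardware(registry)
  expect_identical(det$mode, "normal")
  expect_named(det$devices, c("camera", "stage", "laser", "buttons"))

  det2 <- detect_hardware(registry, list(
    camera = fault_schedule(fail_on_init = TRUE, persistent = TRUE)))
  expect_identical(det2$mode, "fallback")
  # ALL devices switch to the fallback tier, not just the failed one
  expect_length(det2$devices, 4L)

  det3 <- detect_hardware(registry, list(
    camera = fault_schedule(fail_on_init = TRUE, persistent = TRUE,
                            fallback_fail_on_init = TRUE)))
  expect_identical(det3$mode, "fatal")
  expect_length(det3$devices, 0L)
})

test_that("fallback playback camera satisfies the camera contract", {
  vols <- generate_phantom(8, 8, 4, n_vessels = 1, seed = 2)
  stage <- sim_stage(list(z_min = 0L, z_max = 3L, v_min = 0L, v_max = 2L))
  cam <- playback_camera(vols, stage)
  cam$init()
  expect_error(cam$snap("fluorescence"), class = "invalid_argument")
  cam$start_acquisition()
  cam$set_exposure(3)  # ignored, still serves the cached planes verbatim
  z <- stage$position()$z_plane
  expect_identical(cam$snap("fluorescence")$pixels,
                   matrix(vols$fluorescence$data[z + 1, , ], 8, 8))
})
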