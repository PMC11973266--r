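small_render_config <- function(method = "canny", ...) {
  render_config(screen_size = c(200L, 320L), patch_size = 64L,
                aperture_radius = 32, method = method,
                sim_config = tiny_sim_config(), ...)
}

test_that("the Canny baseline maps flat patches to empty frames", {
  cfg <- small_render_config()
  flat <- array(0.5, c(64, 64, 3))
  fr <- canny_representation(flat, cfg)
  expect_true(all(fr == 0))
  expect_identical(dim(unclass(fr)), c(64L, 64L))
})

test_that("a vertical step edge yields a single vertical phosphene line", {
  cfg <- small_render_config()
  step <- array(0.1, c(64, 64, 3))
  step[, 33:64, ] <- 0.9
  fr <- canny_representation(step, cfg)
  map_active <- which(pointspv:::block_max_pool(
    pointspv:::cpp_canny(pointspv:::rgb_to_gray(step) * 255,
                         cfg$canny_low, cfg$canny_high, cfg$canny_sigma),
    8) > 0, arr.ind = TRUE)
  # all active grid cells lie in exactly one column
  expect_identical(length(unique(map_active[, 2])), 1L)
  expect_gt(nrow(map_active), 0)
  expect_gt(sum(fr), 0)
})

test_that("both representation methods produce frames of identical geometry", {
  cfg_c <- small_render_config("canny")
  enc <- init_encoder(tiny_encoder_config(), rng_seed = 1)
  patch <- random_patch(64, seed = 2)
  fr_c <- canny_representation(patch, cfg_c)
  fr_p <- simulate_phosphenes(encode(enc, patch), cfg_c$sim_config)
  expect_identical(dim(unclass(fr_c)), dim(unclass(fr_p)))

  raw <- render_config(screen_size = c(200L, 320L), patch_size = 64L,
                       method = "canny", canny_mode = "raw_edges",
                       sim_config = tiny_sim_config())
  expect_identical(dim(unclass(canny_representation(patch, raw))),
                   c(64L, 64L))
  expect_error(render_config(canny_low = 300, canny_high = 200), "canny_low")
})

screen_image <- function(H = 200, W = 320, seed = 3) {
  withr::with_seed(seed, array(runif(H * W * 3), c(H, W, 3)))
}

test_that("rendered frames honor the circular aperture", {
  cfg <- small_render_config()
  img <- screen_image()
  fr <- render_frame(img, c(100, 160), config = cfg)
  expect_identical(dim(fr$pixels), c(200L, 320L))
  nz <- which(fr$pixels > 0, arr.ind = TRUE)
  d2 <- (nz[, 1] - 1 - 100)^2 + (nz[, 2] - 1 - 160)^2
  expect_true(all(d2 <= cfg$aperture_radius^2))

  # allowed-region size matches the brute-force disk rasterization
  allowed <- sum(outer((0:199 - 100)^2, (0:319 - 160)^2, "+") <=
                   cfg$aperture_radius^2)
  expect_identical(allowed, brute_disk_count(100, 160, cfg$aperture_radius,
                                             200, 320))
  expect_lte(nrow(nz), allowed)
  expect_error(render_frame(img, c(500, 10), config = cfg), "off screen")
  expect_error(render_frame(img[1:50, , ], c(10, 10), config = cfg),
               "resolution")
})

test_that("different gaze points move the aperture, not the geometry", {
  cfg <- small_render_config()
  img <- screen_image()
  f1 <- render_frame(img, c(60, 80), config = cfg)
  f2 <- render_frame(img, c(140, 240), config = cfg)
  in_disk <- function(fr, gy, gx) {
    nz <- which(fr$pixels != 0, arr.ind = TRUE)
    all((nz[, 1] - 1 - gy)^2 + (nz[, 2] - 1 - gx)^2 <= cfg$aperture_radius^2)
  }
  expect_true(in_disk(f1, 60, 80))
  expect_true(in_disk(f2, 140, 240))
  expect_false(identical(f1$pixels, f2$pixels))
})

test_that("session replay renders one frame per sample, reproducibly", {
  sc <- generate_scene(0, c(200, 320), rng_seed = 12)
  lg <- generate_gaze_log(sc, 5, rng_seed = 2)
  cfg <- small_render_config()
  frames <- simulate_session(sc$image, lg, config = cfg)
  expect_length(frames, nrow(lg$samples))
  expect_identical(vapply(frames, `[[`, numeric(1), "t_ms"),
                   lg$samples$t_ms)
  frames2 <- simulate_session(sc$image, lg, config = cfg)
  expect_identical(lapply(frames, `[[`, "pixels"),
                   lapply(frames2, `[[`, "pixels"))
  # aperture invariant holds for every frame
  for (fr in frames) {
    nz <- which(fr$pixels > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      d2 <- (nz[, 1] - 1 - fr$gaze[["y"]])^2 + (nz[, 2] - 1 - fr$gaze[["x"]])^2
      expect_true(all(d2 <= cfg$aperture_radius^2 + 1e-9))
    }
  }
  expect_length(simulate_session(sc$image,
                                 generate_gaze_log(sc, 0, rng_seed = 1),
                                 config = cfg), 0)

  # blanking saccade frames keeps fixation frames intact
  cfgb <- small_render_config(blank_saccades = TRUE)
  fb <- simulate_session(sc$image, lg, config = cfgb)
  sac <- lg$samples$event == "saccade"
  expect_true(all(vapply(fb[sac], function(f) all(f$pixels == 0), logical(1))))
  expect_false(all(fb[[which(!sac)[1]]]$pixels == 0))
})
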