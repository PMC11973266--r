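make_scene <- function(mask, id = "s1", label = 0L) {
  H <- nrow(mask)
  W <- ncol(mask)
  img <- withr::with_seed(1, array(runif(H * W * 3), c(H, W, 3)))
  structure(list(image = img, mask = mask, label = label, scene_id = id),
            class = "spv_scene")
}

test_that("viewing points land on mask foreground, uniformly", {
  m <- matrix(0L, 16, 16)
  m[8, 4] <- 1L                        # 0-based (7, 3)
  sc <- make_scene(m)
  pt <- sample_viewing_point(sc, rng_seed = 1)
  expect_identical(pt, c(y = 7, x = 3) + 0.0)

  expect_error(sample_viewing_point(make_scene(matrix(0L, 8, 8))), "empty")

  # two-pixel mask: 10,000 draws, each frequency within [0.47, 0.53]
  m2 <- matrix(0L, 16, 16)
  m2[3, 5] <- 1L
  m2[10, 12] <- 1L
  sc2 <- make_scene(m2)
  pts <- withr::with_seed(99, replicate(10000, sample_viewing_point(sc2)[["y"]]))
  f <- mean(pts == 2)
  expect_gte(f, 0.47)
  expect_lte(f, 0.53)

  # 10-pixel mask: chi-square goodness of fit, p > 0.01
  m3 <- matrix(0L, 16, 16)
  m3[sample(256, 10)] <- 1L
  sc3 <- make_scene(m3)
  draws <- withr::with_seed(7, replicate(10000, {
    p <- sample_viewing_point(sc3)
    p[["y"]] * 16 + p[["x"]]
  }))
  obs <- table(factor(draws, levels = sort(unique(draws))))
  expect_length(obs, 10)
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})

test_that("patch extraction is centered, clamped at borders, and validated", {
  sc <- make_scene(matrix(1L, 200, 200))
  p <- extract_patch(sc, c(y = 100, x = 100), 100)
  expect_identical(p$window, c(top = 50L, left = 50L))
  expect_identical(dim(p$pixels), c(100L, 100L, 3L))
  expect_identical(p$pixels, sc$image[51:150, 51:150, , drop = FALSE])
  expect_false(p$background_removed)

  # corner point: window clamped to rows/cols 0..99
  p0 <- extract_patch(sc, c(y = 0, x = 0), 100)
  expect_identical(p0$window, brute_window(0, 0, 100, 200, 200))
  expect_identical(p0$pixels, sc$image[1:100, 1:100, , drop = FALSE])
  expect_identical(p0$center, c(y = 0, x = 0))   # center stays the sampled point

  # general border agreement with the brute-force window oracle
  for (pt in list(c(3, 180), c(199, 0), c(120, 50))) {
    pp <- extract_patch(sc, c(y = pt[1], x = pt[2]), 64)
    expect_identical(pp$window, brute_window(pt[1], pt[2], 64, 200, 200))
  }
  expect_error(extract_patch(sc, c(y = 10, x = 10), 300), "patch_size")
})

test_that("background masking zeroes exactly the off-mask pixels and is idempotent", {
  mask <- matrix(0L, 128, 128)
  mask[, 1:64] <- 1L                   # left half foreground
  sc <- make_scene(mask)
  p <- extract_patch(sc, c(y = 64, x = 64), 64)   # window cols 32..95
  pm <- mask_background(p, sc)
  expect_true(pm$background_removed)
  sub <- mask[33:96, 33:96]
  n_bg <- sum(sub == 0L)
  expect_identical(sum(pm$pixels[, , 1] == 0), n_bg)
  expect_identical(pm$pixels[, , 1] != 0, sub == 1L, ignore_attr = TRUE)
  # foreground pixels untouched
  expect_identical(pm$pixels[, 1:32, ], p$pixels[, 1:32, ])
  # idempotent
  expect_identical(mask_background(pm, sc)$pixels, pm$pixels)

  # fully inside mask: unchanged; fully outside: all zero
  pin <- mask_background(extract_patch(sc, c(y = 64, x = 16), 32), sc)
  expect_identical(pin$pixels, extract_patch(sc, c(y = 64, x = 16), 32)$pixels)
  pout <- mask_background(extract_patch(sc, c(y = 64, x = 110), 32), sc)
  expect_true(all(pout$pixels == 0))

  other <- make_scene(mask, id = "other")
  expect_error(mask_background(p, other), "source_id")
})

test_that("patch datasets split at image level without leakage", {
  scenes <- generate_dataset(10, n_classes = 2, size = c(128, 128), rng_seed = 5)
  d <- build_patch_dataset(scenes, points_per_object = 5, split_fraction = 0.8,
                           patch_size = 64, rng_seed = 1)
  expect_identical(nrow(d$train), 40L)
  expect_identical(nrow(d$val), 10L)
  expect_length(intersect(unique(d$train$source_id), unique(d$val$source_id)), 0)
  expect_true(all(vapply(d$train$patch_nobg, function(p)
    isTRUE(p$background_removed), logical(1))))

  d2 <- build_patch_dataset(scenes, points_per_object = 5, split_fraction = 0.8,
                            patch_size = 64, rng_seed = 1)
  expect_identical(d$train$patch_id, d2$train$patch_id)

  expect_error(build_patch_dataset(scenes[1], points_per_object = 1,
                                   split_fraction = 0.8, patch_size = 64),
               "split")
  expect_error(build_patch_dataset(scenes, split_fraction = 1.2), "split_fraction")
})

test_that("patch-level splitting mode allows patches of one scene in both splits", {
  scenes <- generate_dataset(4, n_classes = 2, size = c(128, 128), rng_seed = 6)
  d <- build_patch_dataset(scenes, points_per_object = 10, split_fraction = 0.5,
                           patch_size = 64, rng_seed = 2, level = "patch")
  expect_identical(nrow(d$train) + nrow(d$val), 40L)
  expect_gt(length(intersect(unique(d$train$source_id),
                             unique(d$val$source_id))), 0)
})
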