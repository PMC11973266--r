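test_that("the default encoder has the reference 13-group architecture", {
  enc <- init_encoder(encoder_config(), rng_seed = 1)
  expect_identical(n_layer_groups(enc), 13L)
  types <- vapply(enc$net, `[[`, character(1), "type")
  groups <- vapply(enc$net, `[[`, integer(1), "group")
  # four residual blocks, groups 5-8
  expect_identical(groups[types == "res"], 5:8)
  # three pooling stages: groups 3, 4 and the first decoder group (9)
  expect_identical(groups[types == "pool"], c(3L, 4L, 9L))
  # batch normalization in groups 1-11 only
  expect_identical(sort(unique(groups[types == "bn"])), c(1:4, 9:11))
  # sigmoid output, single channel
  expect_identical(types[length(types)], "sigmoid")
  convs <- enc$net[types == "conv"]
  expect_identical(convs[[length(convs)]]$cout, 1L)
  # channel progression 3-8-16-32-64 on the way in
  expect_identical(vapply(convs[1:4], `[[`, integer(1), "cout"),
                   c(8L, 16L, 32L, 64L))
})

test_that("encoder initialization is seed-reproducible and config-validated", {
  e1 <- init_encoder(encoder_config(grid_size = 8, width = 0.25), rng_seed = 5)
  e2 <- init_encoder(encoder_config(grid_size = 8, width = 0.25), rng_seed = 5)
  expect_identical(spv_params(e1), spv_params(e2))
  e3 <- init_encoder(encoder_config(grid_size = 8, width = 0.25), rng_seed = 6)
  expect_false(identical(spv_params(e1), spv_params(e3)))
  expect_error(encoder_config(grid_size = 32, internal_size = 100),
               "internal_size")
  expect_error(encoder_config(binarize_threshold = 1), "binarize_threshold")
})

test_that("parameter count is a pure function of the configuration", {
  enc <- init_encoder(encoder_config(), rng_seed = 2)
  # frozen regression constant for the default (Table-style) architecture
  expect_identical(length(spv_params(enc)), 345823L)
  enc_small <- init_encoder(tiny_encoder_config(), rng_seed = 2)
  expect_identical(length(spv_params(enc_small)),
                   length(spv_params(init_encoder(tiny_encoder_config(),
                                                  rng_seed = 9))))
})

test_that("encoding yields a binary grid of the configured size", {
  enc <- init_encoder(encoder_config(), rng_seed = 1)
  patch <- random_patch(100, seed = 3)
  map <- encode(enc, patch)
  expect_identical(dim(map$values), c(32L, 32L))
  expect_true(all(map$values %in% c(0L, 1L)))
  expect_true(all(map$soft_values > 0 & map$soft_values < 1))
  expect_identical(map$values,
                   matrix(as.integer(map$soft_values > 0.5), 32, 32))
  # deterministic in evaluation mode
  expect_identical(encode(enc, patch)$values, map$values)
  expect_error(encode(enc, random_patch(64)), "expects")

  enc16 <- init_encoder(encoder_config(grid_size = 16, width = 0.25),
                        rng_seed = 1)
  expect_identical(dim(encode(enc16, random_patch(100, 4))$values),
                   c(16L, 16L))
})

test_that("binarization uses a strict inequality at the threshold", {
  enc <- init_encoder(tiny_encoder_config(), rng_seed = 1)
  # zero the output convolution so the sigmoid is exactly 0.5 everywhere
  last <- length(enc$net) - 1L
  expect_identical(enc$net[[last]]$type, "conv")
  enc$net[[last]]$params$W[] <- 0
  enc$net[[last]]$params$b[] <- 0
  map <- encode(enc, random_patch(64, 8))
  expect_true(all(map$soft_values == 0.5))
  expect_true(all(map$values == 0L))
})

test_that("straight-through gradients flow and match the sigmoid path", {
  cfg <- tiny_encoder_config()
  enc <- init_encoder(cfg, rng_seed = 4)
  patch <- random_patch(64, seed = 5)
  encd <- encode_for_training(enc, patch)
  g <- cfg$grid_size
  # loss = sum of binary map values
  bk <- encoding_backward(encd, matrix(1, g, g))
  expect_gt(bk$first_layer_grad_norm, 0)
  expect_true(all(is.finite(unlist(bk$grads))))

  # straight-through backward equals the backward of the sigmoid-only
  # network for the same loss on soft values: finite differences on two
  # first-layer parameters of sum(soft)
  soft_sum <- function(e) {
    st <- pointspv:::encoder_input_state(e, list(patch))
    f <- pointspv:::net_forward(e$net, st, training = TRUE)
    sum(f$st$x[, 1])
  }
  eps <- 1e-5
  for (k in c(1L, 9L)) {
    ep <- enc
    ep$net[[1]]$params$W[k] <- ep$net[[1]]$params$W[k] + eps
    em <- enc
    em$net[[1]]$params$W[k] <- em$net[[1]]$params$W[k] - eps
    g_num <- (soft_sum(ep) - soft_sum(em)) / (2 * eps)
    expect_equal(bk$grads[[1]]$W[k], g_num, tolerance = 5e-3)
  }

  # evaluation-mode output shape/binarity unaffected by training machinery
  map_eval <- encode(enc, patch)
  expect_true(all(map_eval$values %in% c(0L, 1L)))
})
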