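test_that("perceptual loss implements the normalized squared L2 difference", {
  a <- array(0, c(2, 2, 1))
  expect_identical(perceptual_loss(a, a), 0)
  b <- a
  b[1, 1, 1] <- 2                       # single element differing by 2
  expect_identical(perceptual_loss(a, b), 1.0)   # 4 / (2*2*1)
  expect_error(perceptual_loss(a, array(0, c(2, 3, 1))), "shape")

  for (i in 1:100) {
    d <- withr::with_seed(i, sample(2:6, 3, replace = TRUE))
    x <- withr::with_seed(i + 200, array(rnorm(prod(d)), d))
    y <- withr::with_seed(i + 400, array(rnorm(prod(d)), d))
    expect_equal(perceptual_loss(x, y), brute_perceptual(x, y),
                 tolerance = 1e-6)
  }
})

test_that("the combined loss is the gamma-weighted convex combination", {
  expect_identical(combined_loss(1.0, 0.0), 0.75)
  expect_identical(combined_loss(0.0, 1.0), 0.25)
  for (g in c(0, 0.3, 1)) {
    expect_equal(combined_loss(0.7, 0.7, g), 0.7)
  }
  expect_error(combined_loss(1, 0, gamma = 1.2), "gamma")
  expect_error(combined_loss(Inf, 0), "finite")
})

make_training_bits <- function(seed = 1) {
  d <- tiny_patch_data()
  bb <- tiny_backbone(seed = seed)
  list(data = d, backbone = bb,
       encoder = init_encoder(tiny_encoder_config(), rng_seed = seed),
       sighted = sighted_unit(bb), blind = blind_unit(bb),
       sim = tiny_sim_config())
}

test_that("one training step routes gradients as specified", {
  bits <- make_training_bits(11)
  batch <- bits$data$train[1:4, ]
  sighted_before <- spv_params(bits$sighted)
  enc_before <- spv_params(bits$encoder)

  r <- train_step(bits$encoder, bits$blind, bits$sighted, batch,
                  sim_config = bits$sim, config = loss_config(rng_seed = 1))
  # sighted weights bit-identical after the step
  expect_identical(spv_params(bits$sighted), sighted_before)
  # encoder and blind unit updated
  expect_false(identical(spv_params(r$encoder), enc_before))
  # loss record satisfies the weighted-combination identity
  expect_equal(r$record$L, 0.75 * r$record$L_P + 0.25 * r$record$L_CE,
               tolerance = 1e-9)
  expect_error(train_step(bits$encoder, bits$blind, bits$sighted,
                          bits$data$train[0, ], bits$sim), "at least one")
})

test_that("classifier gradients come solely from the cross-entropy term", {
  bits <- make_training_bits(12)
  batch <- bits$data$train[1:4, ]
  # gamma = 1 removes the cross-entropy weight: classifier stages get
  # exactly zero gradient and their parameters must not move
  cls_stages <- bits$blind$backbone$stage > bits$blind$split_index
  cls_params_before <- pointspv:::net_param_vector(
    bits$blind$backbone$net[cls_stages])
  r <- train_step(bits$encoder, bits$blind, bits$sighted, batch,
                  sim_config = bits$sim,
                  config = loss_config(gamma = 1, rng_seed = 1))
  cls_params_after <- pointspv:::net_param_vector(
    r$blind$backbone$net[cls_stages])
  expect_identical(cls_params_before, cls_params_after)
  # while feature stages still move under the perceptual term
  expect_false(identical(
    pointspv:::net_param_vector(bits$blind$backbone$net[!cls_stages]),
    pointspv:::net_param_vector(r$blind$backbone$net[!cls_stages])))
})

test_that("with gamma = 0 the perceptual term is reported but inert", {
  bits <- make_training_bits(13)
  batch <- bits$data$train[1:4, ]
  est <- pointspv:::encoder_input_state(bits$encoder, batch$patch)
  sf <- pointspv:::precompute_sighted(bits$sighted, batch$patch_nobg)
  labels1 <- as.integer(batch$label) + 1L
  r1 <- pointspv:::pipeline_batch(bits$encoder, bits$blind, bits$sim,
                                  est, sf, labels1, gamma = 0)
  # perturb the sighted reference: L_P changes, gradients must not
  r2 <- pointspv:::pipeline_batch(bits$encoder, bits$blind, bits$sim,
                                  est, sf * 10, labels1, gamma = 0)
  expect_false(isTRUE(all.equal(r1$L_P, r2$L_P)))
  expect_equal(r1$enc_grads, r2$enc_grads, tolerance = 1e-12)
  expect_gt(r1$L_P, 0)
})

test_that("gradients reach the encoder through binarization, simulator and blind unit", {
  bits <- make_training_bits(14)
  batch <- bits$data$train[1:4, ]
  est <- pointspv:::encoder_input_state(bits$encoder, batch$patch)
  sf <- pointspv:::precompute_sighted(bits$sighted, batch$patch_nobg)
  r <- pointspv:::pipeline_batch(bits$encoder, bits$blind, bits$sim, est, sf,
                                 as.integer(batch$label) + 1L, gamma = 0.75)
  expect_gt(pointspv:::grad_norm(r$enc_grads[[1]]), 0)
  expect_true(all(is.finite(unlist(r$enc_grads))))
})

test_that("training loops are deterministic, validated, and record the loss identity", {
  bits <- make_training_bits(15)
  cfg <- loss_config(epochs = 2, batch_size = 4, rng_seed = 3)
  f1 <- train_pointspv(bits$data, bits$encoder, bits$backbone,
                       sim_config = bits$sim, config = cfg)
  f2 <- train_pointspv(bits$data, bits$encoder, bits$backbone,
                       sim_config = bits$sim, config = cfg)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(spv_params(f1$encoder), spv_params(f2$encoder))
  expect_identical(tidy(f1)$epoch, 1:2)
  expect_true(all(abs(tidy(f1)$L -
                        (0.75 * tidy(f1)$L_P + 0.25 * tidy(f1)$L_CE)) < 1e-9))

  # epochs = 0: initialized units back, empty records
  f0 <- train_pointspv(bits$data, bits$encoder, bits$backbone,
                       sim_config = bits$sim,
                       config = loss_config(epochs = 0, rng_seed = 3))
  expect_identical(nrow(tidy(f0)), 0L)
  expect_identical(spv_params(f0$final_encoder), spv_params(bits$encoder))

  expect_error(train_pointspv(list(train = bits$data$train[0, ],
                                   val = bits$data$val),
                              bits$encoder, bits$backbone,
                              sim_config = bits$sim, config = cfg),
               "nonempty")
  expect_error(train_pointspv(bits$data, bits$encoder, bits$backbone,
                              sim_config = simulator_config(),
                              config = cfg),
               "frame size")
})

test_that("accuracy evaluation counts argmax-correct phosphene classifications", {
  bits <- make_training_bits(16)
  fit <- structure(list(encoder = bits$encoder, blind = bits$blind,
                        sim_config = bits$sim),
                   class = "pointspv_fit")
  patches <- bits$data$val
  acc <- evaluate_accuracy(fit, patches)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  expect_identical(evaluate_accuracy(fit, patches), acc)  # deterministic

  # all-correct toy case: labels set to whatever the unit predicts
  preds <- vapply(patches$patch, function(p) {
    which.max(classify(bits$blind,
                       simulate_phosphenes(encode(bits$encoder, p),
                                           bits$sim))) - 1L
  }, integer(1))
  patches$label <- preds
  expect_identical(evaluate_accuracy(fit, patches), 1)

  # random labels on many random maps: near chance for two classes
  n <- 240
  correct <- withr::with_seed(8, {
    vapply(seq_len(n), function(i) {
      map <- matrix(rbinom(64, 1, 0.4), 8, 8)
      lab <- sample(0:1, 1)
      (which.max(classify(bits$blind,
                          simulate_phosphenes(map, bits$sim))) - 1L) == lab
    }, logical(1))
  })
  expect_gt(mean(correct), 0.35)
  expect_lt(mean(correct), 0.65)
  expect_error(evaluate_accuracy(fit, patches[0, ]), "nonempty")
})
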