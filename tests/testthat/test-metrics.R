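test_that("coverage obeys its limit laws and matches brute force", {
  expect_identical(stimulus_coverage(NULL, c(64, 64)), 0)

  # a fixation at every pixel of a 64x64 image: exactly full coverage
  all_px <- expand.grid(y = 0:63, x = 0:63)
  expect_identical(stimulus_coverage(all_px, c(64, 64)), 1)

  # single central fixation on 101x101 vs the double-loop oracle
  fx <- matrix(c(50, 50), 1, dimnames = list(NULL, c("y", "x")))
  expect_equal(stimulus_coverage(fx, c(101, 101), sigma = 50),
               brute_coverage(fx, 101, 101, sigma = 50),
               tolerance = 1e-9)
  # and for several off-center multi-fixation sets at another sigma
  for (i in 1:3) {
    f <- withr::with_seed(i, cbind(y = runif(3, 0, 40), x = runif(3, 0, 60)))
    expect_equal(stimulus_coverage(f, c(41, 61), sigma = 12),
                 brute_coverage(f, 41, 61, sigma = 12),
                 tolerance = 1e-9)
  }
  expect_error(stimulus_coverage(cbind(y = 200, x = 0), c(64, 64)), "bounds")
})

test_that("coverage is bounded, monotone in fixations, and duplicate-invariant", {
  shape <- c(48, 64)
  fx <- withr::with_seed(4, cbind(y = runif(6, 0, 47), x = runif(6, 0, 63)))
  cov_prev <- 0
  for (k in 1:6) {
    ck <- stimulus_coverage(fx[1:k, , drop = FALSE], shape, sigma = 10)
    expect_gte(ck, cov_prev)        # adding a fixation never decreases it
    expect_gte(ck, 0)
    expect_lte(ck, 1)
    cov_prev <- ck
  }
  dup <- rbind(fx, fx[1, ])
  expect_identical(unclass(coverage_heatmap(dup, shape, 10)),
                   unclass(coverage_heatmap(fx, shape, 10)))
})

make_trials <- function(n_participants = 4, n_trials = 6, seed = 1) {
  withr::with_seed(seed, {
    g <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
                     method = c("canny", "pointspv"),
                     trial = seq_len(n_trials), stringsAsFactors = FALSE)
    tibble::tibble(
      participant_id = g$participant_id, method = g$method,
      block = ifelse(g$method == "pointspv", 1L, 2L),
      stimulus_id = sprintf("stim%02d", g$trial),
      truth = sample(c("cat", "dog"), nrow(g), replace = TRUE),
      response = ifelse(runif(nrow(g)) < 0.8, truth,
                        ifelse(truth == "cat", "dog", "cat")),
      reaction_time = runif(nrow(g), 2, 12),
      n_saccades = rpois(nrow(g), 20),
      fixations = lapply(seq_len(nrow(g)), function(i)
        tibble::tibble(y = runif(3, 0, 47), x = runif(3, 0, 63))))
  })
}

test_that("block metrics aggregate per participant and method", {
  tr <- tibble::tibble(
    participant_id = "p1", method = "pointspv", block = 1L,
    stimulus_id = sprintf("s%d", 1:10),
    truth = rep("cat", 10),
    response = c(rep("cat", 9), "dog"),
    reaction_time = c(2, 4, rep(3, 8)),
    n_saccades = rep(10L, 10))
  bm <- block_metrics(tr)
  expect_identical(nrow(bm), 1L)
  expect_identical(bm$accuracy, 0.9)
  expect_identical(bm$mean_rt, 3)
  expect_identical(bm$mean_saccades, 10)
  expect_error(block_metrics(tr[0, ]), "at least one")
})

test_that("block metrics match an independently coded aggregation", {
  tr <- make_trials(n_participants = 20, n_trials = 5, seed = 9)
  bm <- block_metrics(tr, image_shape = c(48, 64), sigma = 10)
  # spreadsheet-style oracle: explicit loops over cells
  for (i in sample(nrow(bm), 6)) {
    p <- bm$participant_id[i]
    m <- bm$method[i]
    rows <- tr[tr$participant_id == p & tr$method == m, ]
    expect_equal(bm$accuracy[i], sum(rows$response == rows$truth) / nrow(rows))
    expect_equal(bm$mean_rt[i], sum(rows$reaction_time) / nrow(rows))
    expect_equal(bm$mean_saccades[i], sum(rows$n_saccades) / nrow(rows))
    covs <- vapply(rows$fixations, function(f)
      brute_coverage(as.matrix(f)[, c("y", "x")], 48, 64, 10), numeric(1))
    expect_equal(bm$mean_coverage[i], mean(covs), tolerance = 1e-9)
  }
  # an absent cell is reported as missing, flagged by n_trials = 0
  bm2 <- block_metrics(tr[!(tr$participant_id == "p01" &
                              tr$method == "canny"), ])
  row <- bm2[bm2$participant_id == "p01" & bm2$method == "canny", ]
  expect_identical(row$n_trials, 0L)
  expect_true(is.na(row$accuracy))
})

test_that("group fixation heatmaps average per-participant max-composed maps", {
  tr <- make_trials(n_participants = 2, n_trials = 2, seed = 5)
  one <- tr[tr$participant_id == "p01" & tr$method == "pointspv", ]
  hm1 <- fixation_heatmap(one, c(48, 64), sigma = 10)
  manual <- coverage_heatmap(dplyr::bind_rows(one$fixations), c(48, 64), 10)
  expect_equal(unclass(hm1), unclass(manual))

  # two participants with disjoint fixation regions: averaged peaks at 0.5
  tr2 <- tibble::tibble(
    participant_id = c("a", "b"), method = "pointspv",
    fixations = list(tibble::tibble(y = 5, x = 5),
                     tibble::tibble(y = 40, x = 55)))
  hm2 <- fixation_heatmap(tr2, c(48, 64), sigma = 2)
  expect_equal(hm2[6, 6], 0.5, tolerance = 1e-6)
  expect_equal(hm2[41, 56], 0.5, tolerance = 1e-6)
  expect_true(all(hm2 >= 0 & hm2 <= 1))
  expect_error(fixation_heatmap(tr2[0, ], c(48, 64)), "no trials")
})

test_that("rm_anova is the paired within-subject F test", {
  same <- c(1, 2, 3, 4)
  r0 <- rm_anova(same, same)
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p.value, 1)

  a20 <- withr::with_seed(2, rnorm(20))
  b20 <- withr::with_seed(3, rnorm(20))
  r20 <- rm_anova(a20, b20)
  expect_identical(r20$num_df, 1L)
  expect_identical(r20$den_df, 19L)

  for (i in 1:100) {
    n <- withr::with_seed(i, sample(3:30, 1))
    a <- withr::with_seed(i + 100, rnorm(n))
    b <- withr::with_seed(i + 300, rnorm(n, mean = 0.3))
    r <- rm_anova(a, b)
    t <- stats::t.test(a, b, paired = TRUE)
    expect_gte(r$statistic, 0)
    expect_equal(r$statistic, unname(t$statistic)^2, tolerance = 1e-9)
    expect_equal(r$p.value, t$p.value, tolerance = 1e-9)
  }
  expect_error(rm_anova(1:3, 1:4), "paired")
  expect_error(rm_anova(1, 2), "at least 2")
})

test_that("compare_methods runs one paired test per metric", {
  tr <- make_trials(n_participants = 8, n_trials = 4, seed = 7)
  bm <- block_metrics(tr, image_shape = c(48, 64), sigma = 10)
  cm <- compare_methods(bm, adjust = TRUE)
  expect_setequal(cm$metric,
                  c("accuracy", "mean_rt", "mean_saccades", "mean_coverage"))
  expect_true(all(cm$den_df == 7L))
  expect_true(all(cm$p.holm >= cm$p.value - 1e-12))
  wide_rt <- tidyr::pivot_wider(bm[, c("participant_id", "method", "mean_rt")],
                                names_from = "method", values_from = "mean_rt")
  tt <- stats::t.test(wide_rt$canny, wide_rt$pointspv, paired = TRUE)
  expect_equal(cm$statistic[cm$metric == "mean_rt"],
               unname(tt$statistic)^2, tolerance = 1e-9)
})
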