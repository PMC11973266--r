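# Behavioral metrics: per-participant block summaries, the Gaussian
# stimulus-coverage statistic, group fixation heatmaps, and the
# repeated-measures ANOVA used to compare representation methods.

#' Fixation coverage heatmap
#'
#' Models each viewing point as an unnormalized two-dimensional Gaussian
#' with peak value 1 (`k(p; f) = exp(-||p - f||^2 / (2 sigma^2))`) and
#' composes overlapping fixations by taking the per-pixel maximum.  The
#' peak-1 kernel is what allows the derived coverage statistic to reach
#' exactly 100% when every pixel is fixated; a density-normalized
#' kernel could not.
#'
#' @param fixations Fixation centers: a two-column matrix or data frame
#'   with columns `y`, `x` (0-based pixel coordinates, inside the
#'   image).
#' @param image_shape Integer vector `c(H, W)`.
#' @param sigma Gaussian standard deviation in pixels (default 50).
#' @return An `spv_coverage_heatmap`: H x W matrix in \[0, 1\], zero
#'   where no fixation has influence.
#' @export
coverage_heatmap <- function(fixations, image_shape, sigma = 50) {
  H <- as.integer(image_shape[1])
  W <- as.integer(image_shape[2])
  fx <- fixation_matrix(fixations)
  if (nrow(fx) > 0 &&
      (any(fx[, "y"] < 0 | fx[, "y"] > H - 1) ||
       any(fx[, "x"] < 0 | fx[, "x"] > W - 1))) {
    stop("fixations must lie within the image bounds")
  }
  hm <- matrix(0, H, W)
  if (nrow(fx) == 0L) {
    return(structure(hm, class = c("spv_coverage_heatmap", "matrix"),
                     sigma = sigma))
  }
  ys <- 0:(H - 1)
  xs <- 0:(W - 1)
  for (i in seq_len(nrow(fx))) {
    ky <- exp(-(ys - fx[i, "y"])^2 / (2 * sigma^2))
    kx <- exp(-(xs - fx[i, "x"])^2 / (2 * sigma^2))
    hm <- pmax(hm, outer(ky, kx))
  }
  structure(hm, class = c("spv_coverage_heatmap", "matrix"), sigma = sigma)
}

fixation_matrix <- function(fixations) {
  if (is.null(fixations) ||
      (is.data.frame(fixations) && nrow(fixations) == 0L) ||
      (is.matrix(fixations) && nrow(fixations) == 0L) ||
      (!is.data.frame(fixations) && !is.matrix(fixations) &&
       length(fixations) == 0L)) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  }
  if (is.data.frame(fixations)) {
    m <- cbind(y = fixations$y, x = fixations$x)
  } else if (is.matrix(fixations)) {
    m <- fixations
    if (is.null(colnames(m))) colnames(m) <- c("y", "x")
  } else {
    m <- matrix(fixations, ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("y", "x")))
  }
  m[, c("y", "x"), drop = FALSE]
}

#' Stimulus coverage statistic
#'
#' Sum of the coverage heatmap ([coverage_heatmap()]: peak-1 Gaussians,
#' per-pixel maximum) over all pixels, normalized by the number of
#' pixels.  Ranges continuously from 0 (no fixations) to 1, where 1
#' means every pixel of the image is fully encompassed by at least one
#' viewing point.
#'
#' @inheritParams coverage_heatmap
#' @return Numeric scalar in \[0, 1\].
#' @export
stimulus_coverage <- function(fixations, image_shape, sigma = 50) {
  hm <- coverage_heatmap(fixations, image_shape, sigma)
  sum(hm) / length(hm)
}

#' Per-participant block metrics
#'
#' Aggregates trial records into the four performance metrics, averaged
#' over all stimuli presented to a participant under each method:
#' accuracy (fraction of correct responses), mean reaction time, mean
#' saccade count, and (if fixation lists and an image shape are
#' supplied) mean stimulus coverage.
#'
#' @param trials A tibble with one row per trial: columns
#'   `participant_id`, `method`, `response`, `truth`, `reaction_time`,
#'   `n_saccades`, and optionally `block` and a list-column `fixations`
#'   (each element a data frame with `y`, `x`).
#' @param image_shape Optional `c(H, W)`; required for coverage.
#' @param sigma Coverage kernel width in pixels.
#' @return A tibble with one row per (participant, method) cell:
#'   `accuracy`, `mean_rt`, `mean_saccades`, `mean_coverage`, `n_trials`.
#'   Cells absent from the data appear with `NA` metrics and
#'   `n_trials = 0`.
#' @export
block_metrics <- function(trials, image_shape = NULL, sigma = 50) {
  if (nrow(trials) == 0L) stop("`trials` must contain at least one trial")
  trials <- dplyr::mutate(
    trials,
    correct = .data$response == .data$truth,
    coverage = if (!is.null(image_shape) && "fixations" %in% names(trials)) {
      purrr::map_dbl(.data$fixations, stimulus_coverage,
                     image_shape = image_shape, sigma = sigma)
    } else NA_real_)
  out <- trials |>
    dplyr::group_by(.data$participant_id, .data$method) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      mean_rt = mean(.data$reaction_time),
      mean_saccades = mean(.data$n_saccades),
      mean_coverage = mean(.data$coverage),
      n_trials = dplyr::n(),
      .groups = "drop")
  out <- tidyr::complete(out, .data$participant_id, .data$method,
                         fill = list(n_trials = 0L))
  out
}

#' Group-average fixation heatmap
#'
#' Computes each participant's fixation heatmap (max composition of
#' peak-1 Gaussians over all of that participant's fixations in the
#' selected trials) and averages the heatmaps pixelwise across
#' participants, as used for condition-wise stimulus exploration maps.
#'
#' @param trials Trial tibble (see [block_metrics()]) with a
#'   `fixations` list-column; filter it to one block/method/stimulus
#'   group before calling, or use the `...` filter expressions.
#' @param image_shape `c(H, W)` of the stimulus.
#' @param sigma Kernel width in pixels.
#' @param ... Optional `dplyr::filter()` expressions applied to
#'   `trials` first (e.g. `method == "pointspv"`, `block == 1`).
#' @return An `spv_coverage_heatmap` matrix in \[0, 1\].
#' @export
fixation_heatmap <- function(trials, image_shape, sigma = 50, ...) {
  sel <- dplyr::filter(trials, ...)
  if (nrow(sel) == 0L) stop("no trials in the requested group")
  per_participant <- sel |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(function(df, key) {
      fx <- dplyr::bind_rows(df$fixations)
      unclass(coverage_heatmap(fx, image_shape, sigma))
    })
  avg <- Reduce(`+`, per_participant) / length(per_participant)
  structure(avg, class = c("spv_coverage_heatmap", "matrix"), sigma = sigma)
}

#' Repeated-measures ANOVA for two within-subject conditions
#'
#' One within factor with two levels, matched by participant: the
#' classical repeated-measures ANOVA on `(1, n - 1)` degrees of
#' freedom, fitted via `stats::aov` with a participant error stratum.
#' For this design the F statistic equals the squared paired t
#' statistic.  Degenerate input with zero variance everywhere
#' (identical vectors) yields `F = 0`, `p = 1`.
#'
#' @param values_a,values_b Per-participant means under condition A and
#'   B, matched by position; equal lengths, `n >= 2`.
#' @return A one-row tibble: `statistic` (F), `num_df` (1), `den_df`
#'   (n - 1), `p.value`.
#' @export
rm_anova <- function(values_a, values_b) {
  n <- length(values_a)
  if (length(values_b) != n) stop("condition vectors must be paired (equal length)")
  if (n < 2L) stop("need at least 2 participants")
  d <- data.frame(
    value = c(values_a, values_b),
    method = factor(rep(c("a", "b"), each = n)),
    participant = factor(rep(seq_len(n), 2)))
  if (all(values_a == values_b)) {
    return(tibble::tibble(statistic = 0, num_df = 1L, den_df = n - 1L,
                          p.value = 1))
  }
  fit <- stats::aov(value ~ method + Error(participant / method), data = d)
  tab <- summary(fit)[["Error: participant:method"]][[1]]
  F <- tab["method", "F value"]
  tibble::tibble(statistic = F, num_df = 1L, den_df = n - 1L,
                 p.value = stats::pf(F, 1, n - 1, lower.tail = FALSE))
}

#' Compare the two representation methods on every metric
#'
#' Convenience wrapper: pivots a [block_metrics()] table to paired
#' per-participant vectors and runs [rm_anova()] for each metric.
#' Raw p-values are reported; Holm-adjusted ones can be added since the
#' four tests are run on the same participants.
#'
#' @param metrics A [block_metrics()] result with exactly two methods.
#' @param adjust Add a `p.holm` column (default `FALSE`, matching the
#'   convention of reporting the four tests uncorrected).
#' @return A tibble with one row per metric: `metric`, `statistic`,
#'   `num_df`, `den_df`, `p.value` (and optionally `p.holm`).
#' @export
compare_methods <- function(metrics, adjust = FALSE) {
  methods <- sort(unique(metrics$method))
  if (length(methods) != 2L) stop("`metrics` must contain exactly two methods")
  cols <- c("accuracy", "mean_rt", "mean_saccades", "mean_coverage")
  cols <- cols[vapply(cols, function(cl) !all(is.na(metrics[[cl]])), logical(1))]
  out <- purrr::map_dfr(cols, function(cl) {
    wide <- tidyr::pivot_wider(metrics[, c("participant_id", "method", cl)],
                               names_from = "method",
                               values_from = tidyr::all_of(cl))
    ok <- stats::complete.cases(wide[, methods])
    r <- rm_anova(wide[[methods[1]]][ok], wide[[methods[2]]][ok])
    dplyr::mutate(r, metric = cl, .before = 1)
  })
  if (adjust) out$p.holm <- stats::p.adjust(out$p.value, "holm")
  out
}
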